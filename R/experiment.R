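#' Experiment configuration
#'
#' Bundles parameter overrides, scale factors and the master seed of a
#' full experiment. The full-scale profile of the study is 18 networks,
#' 1000 presentations per pattern pair, 9000 Phase II ignitions and 2000
#' measurement episodes; the default desk-scale profile (3 networks, 250
#' presentations, 1500 ignitions, 300 episodes) preserves the protocol's
#' shape at workstation runtimes.
#'
#' @param n_networks number of independent networks ("subjects").
#' @param reps_per_pair Phase I presentations per pattern pair.
#' @param stop_ignitions Phase II termination count (per twin).
#' @param n_measure_episodes ignition episodes per measurement.
#' @param n_pairs,cells_per_pattern pattern repertoire shape.
#' @param seed master seed; every stage derives named sub-streams from it.
#' @param output_dir where [run_experiment()] writes its outputs.
#' @param pattern_mode `"disjoint"` or `"overlap"` (see
#'   [generate_pattern_pairs()]).
#' @param params parameter overrides as a named list (applied on top of
#'   [model_params()] defaults).
#' @return A list of class `"canet_config"`.
#' @export
experiment_config <- function(n_networks = 3L, reps_per_pair = 250L,
                              stop_ignitions = 1500L, n_measure_episodes = 300L,
                              n_pairs = 12L, cells_per_pattern = 19L,
                              seed = 1L, output_dir = "canet_out",
                              pattern_mode = "disjoint", params = list()) {
  cfg <- list(n_networks = as.integer(n_networks),
              reps_per_pair = as.integer(reps_per_pair),
              stop_ignitions = as.integer(stop_ignitions),
              n_measure_episodes = as.integer(n_measure_episodes),
              n_pairs = as.integer(n_pairs),
              cells_per_pattern = as.integer(cells_per_pattern),
              seed = as.integer(seed), output_dir = output_dir,
              pattern_mode = pattern_mode, params = params)
  if (any(c(cfg$n_networks, cfg$reps_per_pair, cfg$stop_ignitions,
            cfg$n_measure_episodes) < 1L)) stop("scale factors must be >= 1")
  structure(cfg, class = "canet_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns a `"canet_config"`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(experiment_config, y)
}

#' @rdname read_config
#' @param config a `"canet_config"`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full two-phase experiment end to end
#'
#' For each network seed: initialize -> Phase I training -> identify
#' circuits -> Pre-reward spontaneous measurement -> rank and split into
#' balanced groups -> twin Phase II (Group A rewarded in one twin, Group
#' B in the other) -> Post-reward identification and measurement of both
#' twins. Then pools the co-activation rates across networks, excludes
#' outlier networks by the interquartile-range rule, computes the tidy
#' metrics table, runs the repeated-measures ANOVA battery on frequency,
#' duration and size, and writes tables, figures and a provenance record
#' (config hash, seed, package version) to the output directory.
#'
#' @param config a [experiment_config()].
#' @param progress print stage messages.
#' @return A list with `metrics` (all networks), `kept_metrics` (after
#'   outlier exclusion), `coactivations`, `exclusion`, `stats`, and
#'   `files`.
#' @export
run_experiment <- function(config = experiment_config(), progress = TRUE) {
  stopifnot(inherits(config, "canet_config"))
  par <- do.call(model_params, config$params)
  all_metrics <- list(); coact <- list()
  say <- function(...) if (progress) message(...)

  for (i in seq_len(config$n_networks)) {
    net_seed <- derive_seed(config$seed, paste0("network_", i))
    say("network ", i, "/", config$n_networks, " (seed ", net_seed, ")")
    pairs <- generate_pattern_pairs(config$n_pairs, config$cells_per_pattern,
                                    mode = config$pattern_mode, seed = net_seed)
    net <- init_network(par, seed = net_seed)
    say("  phase I: ", config$reps_per_pair, " reps/pair")
    run_phase1(net, pairs, reps_per_pair = config$reps_per_pair, seed = net_seed)
    circuits <- identify_cas(net, pairs, seed = net_seed)
    say("  pre-reward measurement")
    pre_log <- measure_spontaneous(net_copy(net), circuits,
                                   n_episodes = config$n_measure_episodes,
                                   seed = net_seed, record_activity = FALSE,
                                   partial = TRUE)
    freq <- tabulate(pre_log$events$ca_id, nbins = length(circuits))
    ranked <- rank_cas(freq, vapply(circuits, `[[`, 0, "size"))
    assignment <- split_groups(ranked)
    say("  twin phase II: ", config$stop_ignitions, " ignitions per twin")
    twins <- twin_experiment(net, circuits, assignment,
                             stop_ignitions = config$stop_ignitions,
                             seeds = c(derive_seed(net_seed, "twin_a"),
                                       derive_seed(net_seed, "twin_b")),
                             partial = TRUE)

    m <- list(compute_metrics(pre_log, circuits, assignment, "Pre-reward", i))
    rates <- c(pre = coactivation_rate(pre_log))
    for (tw in c("a_rewarded", "b_rewarded")) {
      post_net <- twins[[tw]]$net
      post_circ <- identify_cas(post_net, pairs,
                                seed = derive_seed(net_seed, paste0("identify_", tw)))
      post_log <- measure_spontaneous(net_copy(post_net), post_circ,
                                      n_episodes = config$n_measure_episodes,
                                      seed = derive_seed(net_seed, paste0("measure_", tw)),
                                      record_activity = FALSE, partial = TRUE)
      rewarded <- if (tw == "a_rewarded") assignment$group_a else assignment$group_b
      mm <- compute_metrics(post_log, post_circ, assignment, "Post", i)
      mm$condition <- ifelse(mm$ca_id %in% rewarded, "Rewarded", "Unrewarded")
      mm$twin <- tw
      m[[length(m) + 1L]] <- mm
      rates[[tw]] <- coactivation_rate(post_log)
    }
    all_metrics[[i]] <- dplyr::bind_rows(m)
    coact[[i]] <- data.frame(network = i, pre = rates[["pre"]],
                             a_rewarded = rates[["a_rewarded"]],
                             b_rewarded = rates[["b_rewarded"]])
  }

  metrics <- dplyr::bind_rows(all_metrics)
  coactivations <- do.call(rbind, coact)
  exclusion <- if (nrow(coactivations) >= 4) exclude_outliers(coactivations)
               else list(kept = coactivations$network, excluded = integer(), fences = NULL)
  kept <- metrics[metrics$network %in% exclusion$kept, , drop = FALSE]

  stats <- list()
  per_cell <- kept |>
    dplyr::group_by(.data$network, .data$group, .data$condition) |>
    dplyr::summarise(frequency = mean(.data$frequency),
                     duration = mean(.data$mean_duration, na.rm = TRUE),
                     size = mean(.data$size), .groups = "drop")
  n_kept <- length(unique(kept$network))
  if (n_kept >= 2 && all(table(per_cell$network) == 6)) {
    for (dv in c("frequency", "duration", "size")) {
      d <- data.frame(subject = per_cell$network, group = per_cell$group,
                      reward = factor(per_cell$condition,
                                      levels = c("Pre-reward", "Rewarded", "Unrewarded")),
                      value = per_cell[[dv]])
      stats[[paste0("rm_anova_", dv)]] <- tryCatch(rm_anova_2x3(d),
                                                   error = function(e) conditionMessage(e))
    }
  }

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- report(kept, stats, config$output_dir)
  prov <- list(config = unclass(config), config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("canet")),
               excluded_networks = exclusion$excluded)
  pf <- file.path(config$output_dir, "provenance.json")
  jsonlite::write_json(prov, pf, auto_unbox = TRUE, digits = NA, null = "null")
  cf <- file.path(config$output_dir, "coactivations.csv")
  write.csv(coactivations, cf, row.names = FALSE)

  list(metrics = metrics, kept_metrics = kept, coactivations = coactivations,
       exclusion = exclusion, stats = stats, files = c(files, pf, cf))
}
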