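#' Generate random motor-haptic pattern pairs
#'
#' Each "action" is a pair of activity patterns: a set of
#' `cells_per_pattern` excitatory cells in primary motor cortex (M1) and a
#' matching set in primary somatosensory cortex (S1), representing a
#' finger/hand motor command and the haptic feedback it produces. In the
#' default disjoint mode no cell takes part in two patterns of the same
#' area, guaranteeing input-specific assemblies; `mode = "overlap"` draws
#' each pattern independently.
#'
#' @param n_pairs number of pattern pairs (default 12).
#' @param cells_per_pattern cells per area per pattern (default 19).
#' @param mode `"disjoint"` (default) or `"overlap"`.
#' @param seed optional seed (sub-stream `"patterns"`); `NULL` uses the
#'   current RNG stream.
#' @return A list of `n_pairs` pattern pairs, each a list with `id`,
#'   `m1_cells` and `s1_cells` (local cell indices, 1..625).
#' @examples
#' pp <- generate_pattern_pairs(seed = 1)
#' length(pp)                 # 12
#' length(pp[[1]]$m1_cells)   # 19
#' @export
generate_pattern_pairs <- function(n_pairs = 12L, cells_per_pattern = 19L,
                                   mode = c("disjoint", "overlap"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(derive_seed(seed, "patterns"))
  need <- n_pairs * cells_per_pattern
  if (mode == "disjoint" && need > CELLS_PER_AREA)
    stop("disjoint mode capacity exceeded: ", need, " > ", CELLS_PER_AREA, " cells")
  draw <- function() {
    if (mode == "disjoint") {
      cells <- sample.int(CELLS_PER_AREA, need)
      split(cells, rep(seq_len(n_pairs), each = cells_per_pattern))
    } else {
      lapply(seq_len(n_pairs), function(i) sample.int(CELLS_PER_AREA, cells_per_pattern))
    }
  }
  m1 <- draw(); s1 <- draw()
  lapply(seq_len(n_pairs), function(i) {
    list(id = i, m1_cells = as.integer(sort(m1[[i]])), s1_cells = as.integer(sort(s1[[i]])))
  })
}

pattern_stim <- function(pair) {
  c(pair$m1_cells + (area_index("M1") - 1L) * CELLS_PER_AREA,
    pair$s1_cells + (area_index("S1") - 1L) * CELLS_PER_AREA)
}

#' Present one pattern pair to the network
#'
#' Clamps the pair's M1 and S1 cells with the stimulation amplitude for
#' `clamp_steps` (default 16) simulation steps, with plasticity applied
#' each step iff `learn`, then runs an unstimulated inter-stimulus
#' interval until every area's activity has returned to baseline (all
#' areas below `baseline_tol` summed spikes for `isi_quiet_steps`
#' consecutive steps, hard-capped at `isi_max_steps`).
#'
#' @param net a `"canet_network"`, advanced in place.
#' @param pair a pattern pair from [generate_pattern_pairs()].
#' @param learn apply plasticity (reward is never applied here; Phase I is
#'   reward-free).
#' @param clamp_steps stimulation duration in steps.
#' @param record passed through to [run_engine()] for the clamp window.
#' @return A list with the engine results of the `clamp` and `isi`
#'   segments.
#' @export
present_pattern <- function(net, pair, learn = TRUE, clamp_steps = 16L,
                            record = character()) {
  stim <- pattern_stim(pair)
  clamp <- run_engine(net, mode = "fixed", max_steps = clamp_steps,
                      stim = stim, learn = learn, record = record)
  # plasticity during the decay interval is optional (learn_in_isi):
  # associative learning acts on the stimulus-driven window, while the
  # interval's role is to let activity return to baseline
  isi <- run_engine(net, mode = "isi",
                    learn = learn && isTRUE(net$par$learn_in_isi))
  list(clamp = clamp, isi = isi)
}

#' Phase I: associative training on the pattern-pair repertoire
#'
#' Presents each pattern pair `reps_per_pair` times (order fully
#' randomized across the whole sequence), with purely Hebbian ABS learning
#' (the reward signal stays at 0 throughout). Lightweight weight-summary
#' snapshots are taken every `snapshot_every` presentations.
#'
#' @param net a freshly initialized `"canet_network"`, trained in place.
#' @param pairs pattern pairs from [generate_pattern_pairs()].
#' @param reps_per_pair presentations per pair (1000 at full scale).
#' @param snapshot_every snapshot cadence in presentations (`Inf` = none).
#' @param seed optional seed for presentation order and noise (sub-stream
#'   `"noise_phase1"`).
#' @param progress print a progress line every 500 presentations.
#' @return A list of class `"canet_phase_log"`: presentation `order`,
#'   per-pair presentation counts, total `steps`, and `snapshots`
#'   (a data.frame of step, presentation, mean/sd weight).
#' @export
run_phase1 <- function(net, pairs, reps_per_pair = 1000L, snapshot_every = 600L,
                       seed = NULL, progress = FALSE) {
  stopifnot(inherits(net, "canet_network"))
  if (!is.null(seed)) set.seed(derive_seed(seed, "noise_phase1"))
  sched <- sample(rep(seq_along(pairs), times = reps_per_pair))
  steps <- 0L
  snaps <- list()
  for (k in seq_along(sched)) {
    res <- present_pattern(net, pairs[[sched[k]]], learn = TRUE)
    steps <- steps + res$clamp$steps + res$isi$steps
    if (is.finite(snapshot_every) && k %% snapshot_every == 0L) {
      snaps[[length(snaps) + 1L]] <- data.frame(
        presentation = k, step = net$t,
        mean_w = mean(net$conn$ee$w), sd_w = sd(net$conn$ee$w))
    }
    if (progress && k %% 500L == 0L)
      message("phase1: ", k, "/", length(sched), " presentations")
  }
  structure(list(order = sched,
                 counts = tabulate(sched, nbins = length(pairs)),
                 steps = steps,
                 snapshots = if (length(snaps)) do.call(rbind, snaps) else NULL),
            class = "canet_phase_log")
}

#' Measure spontaneous cell-assembly dynamics
#'
#' With learning frozen and no external input, runs the noise-driven
#' network until `n_episodes` complete ignition episodes have occurred,
#' recording every circuit's instantaneous activity (fraction of member
#' cells whose fast rate estimate exceeds the activity floor). Weights are
#' untouched.
#'
#' @param net a `"canet_network"`, advanced in place (weights unchanged).
#' @param circuits assembly circuits from [identify_cas()].
#' @param n_episodes episodes to record (2000 at full scale).
#' @param seed optional seed (sub-stream `"noise_measure"`).
#' @param max_steps stagnation budget; if the target is not reached within
#'   it an error is raised rather than looping silently.
#' @param record_activity keep the per-step activity matrix.
#' @param partial if `TRUE`, a run that exhausts `max_steps` before the
#'   episode target returns whatever was recorded (with a warning) instead
#'   of erroring; the spontaneous regime can be sparse at reduced training
#'   scales.
#' @return An ignition log (see [ignition_log()]).
#' @export
measure_spontaneous <- function(net, circuits, n_episodes = 2000L, seed = NULL,
                                max_steps = 600L * n_episodes + 20000L,
                                record_activity = TRUE, partial = FALSE) {
  stopifnot(length(circuits) > 0)
  if (!is.null(seed)) set.seed(derive_seed(seed, "noise_measure"))
  rec <- if (record_activity) "activity" else character()
  res <- run_engine(net, mode = "episodes", max_steps = max_steps,
                    learn = FALSE, circuits = circuits,
                    n_target = n_episodes, record = rec)
  if (!res$reached) {
    msg <- paste0("stagnation: only ", res$episodes, "/", n_episodes,
                  " ignition episodes occurred within ", max_steps, " steps")
    if (!partial) stop(msg)
    warning(msg)
  }
  ignition_log(res, n_cas = length(circuits))
}

#' Rank assemblies by spontaneous ignition likelihood
#'
#' Descending ignition frequency; exact frequency ties are broken by
#' descending circuit size, remaining ties by ascending id (deterministic).
#'
#' @param ignition_frequencies one count per assembly.
#' @param ca_sizes one size (total member cells) per assembly.
#' @param ids assembly ids (default `seq_along`).
#' @return Integer vector of ids, highest rank first.
#' @examples
#' rank_cas(c(5, 9, 9), c(40, 60, 55))  # 2, 3, 1
#' @export
rank_cas <- function(ignition_frequencies, ca_sizes, ids = seq_along(ignition_frequencies)) {
  stopifnot(length(ignition_frequencies) == length(ca_sizes),
            length(ids) == length(ca_sizes))
  ids[order(-ignition_frequencies, -ca_sizes, ids)]
}

#' Split ranked assemblies into two reward-balanced groups
#'
#' Assigns the 12 ranked assemblies to two disjoint groups of 6 using the
#' rank-interleaving pattern A, B, B, A, B, A, A, B, A, B, B, A (ranks 1
#' through 12), which balances the groups' total spontaneous ignition
#' probability: each block of four ranks contributes symmetrically.
#'
#' @param ranked integer vector of 12 assembly ids, highest ignition rank
#'   first (from [rank_cas()]).
#' @return A list with `group_a` and `group_b` (6 ids each, disjoint).
#' @examples
#' split_groups(1:12)$group_a  # ranks 1, 4, 6, 7, 9, 12
#' @export
split_groups <- function(ranked) {
  if (length(ranked) != 12L || anyDuplicated(ranked))
    stop("expected 12 distinct ranked assembly ids")
  a_ranks <- c(1L, 4L, 6L, 7L, 9L, 12L)
  list(group_a = ranked[a_ranks], group_b = ranked[-a_ranks])
}

#' Phase II: reward-gated learning driven by spontaneous ignitions
#'
#' Runs the network with no external input, learning enabled, and the
#' global reward signal switched to 1 whenever any assembly of the
#' rewarded group is at or above the ignition threshold (and back to 0 as
#' soon as all rewarded assemblies fall below it). Terminates once
#' `stop_ignitions` ignition onsets have occurred across all assemblies.
#' Membership used for reward gating is the end-of-Phase-I identification;
#' circuits are re-identified only at the post-reward measurement point.
#'
#' @param net a `"canet_network"` (end-of-Phase-I state), advanced in place.
#' @param circuits assembly circuits from [identify_cas()].
#' @param rewarded_ids positions in `circuits` whose ignition triggers
#'   reward.
#' @param stop_ignitions total ignition count terminating the phase (9000
#'   at full scale).
#' @param snapshot_every snapshot cadence in ignitions.
#' @param seed optional seed (sub-stream `"noise_phase2"`).
#' @param max_steps stagnation budget.
#' @param partial if `TRUE`, exhausting `max_steps` before `stop_ignitions`
#'   returns the partial log with a warning instead of erroring.
#' @return A list of class `"canet_phase_log"` with `ignitions`, `steps`,
#'   LTP/LTD event counts split by reward state (`ltp_r0`, `ltp_r1`,
#'   `ltd_r0`, `ltd_r1`), `reward_steps` (steps with R = 1), the event
#'   table, and `snapshots`.
#' @export
run_phase2 <- function(net, circuits, rewarded_ids, stop_ignitions = 9000L,
                       snapshot_every = 100L, seed = NULL,
                       max_steps = 600L * stop_ignitions + 20000L,
                       partial = FALSE) {
  stopifnot(inherits(net, "canet_network"), length(rewarded_ids) > 0)
  if (!is.null(seed)) set.seed(derive_seed(seed, "noise_phase2"))
  done <- 0L; steps <- 0L
  ltp <- c(r0 = 0, r1 = 0); ltd <- c(r0 = 0, r1 = 0); rew_steps <- 0
  ev <- list(); snaps <- list()
  while (done < stop_ignitions) {
    chunk <- min(snapshot_every, stop_ignitions - done)
    res <- run_engine(net, mode = "ignitions", max_steps = max_steps - steps,
                      learn = TRUE, circuits = circuits, rewarded = rewarded_ids,
                      n_target = chunk)
    ev[[length(ev) + 1L]] <- data.frame(ca_id = res$ev_ca,
                                        start = res$ev_start + steps,
                                        end = res$ev_end + steps)
    done <- done + res$ignitions
    steps <- steps + res$steps
    ltp <- ltp + c(res$ltp_r0, res$ltp_r1)
    ltd <- ltd + c(res$ltd_r0, res$ltd_r1)
    rew_steps <- rew_steps + res$reward_steps
    snaps[[length(snaps) + 1L]] <- data.frame(
      ignitions = done, step = net$t,
      mean_w = mean(net$conn$ee$w), sd_w = sd(net$conn$ee$w))
    if (!res$reached) {
      msg <- paste0("stagnation: only ", done, "/", stop_ignitions,
                    " ignitions occurred within ", max_steps, " steps")
      if (!partial) stop(msg)
      warning(msg)
      break
    }
  }
  structure(list(ignitions = done, steps = steps,
                 ltp_r0 = ltp[["r0"]], ltp_r1 = ltp[["r1"]],
                 ltd_r0 = ltd[["r0"]], ltd_r1 = ltd[["r1"]],
                 reward_steps = rew_steps,
                 events = do.call(rbind, ev),
                 snapshots = do.call(rbind, snaps)),
            class = "canet_phase_log")
}

#' The twin-network Phase II experiment
#'
#' Creates two identical copies of the end-of-Phase-I network and runs
#' Phase II on each under complementary reward assignments -- Group A
#' rewarded in one twin, Group B in the other -- with independent noise
#' streams. This orthogonal design lets every assembly group serve as both
#' treatment and control.
#'
#' @param net the end-of-Phase-I `"canet_network"` (left untouched).
#' @param circuits assembly circuits from [identify_cas()].
#' @param assignment group assignment from [split_groups()].
#' @param stop_ignitions per-twin termination count.
#' @param seeds integer vector of 2 noise seeds (one per twin).
#' @param ... passed to [run_phase2()].
#' @return A list with elements `a_rewarded` and `b_rewarded`, each
#'   holding the twin's trained `net` and its Phase II `log`.
#' @export
twin_experiment <- function(net, circuits, assignment, stop_ignitions = 9000L,
                            seeds = c(1L, 2L), ...) {
  stopifnot(length(seeds) == 2L)
  run_twin <- function(rewarded_ids, seed) {
    twin <- net_copy(net)
    log <- run_phase2(twin, circuits, rewarded_ids,
                      stop_ignitions = stop_ignitions, seed = seed, ...)
    list(net = twin, log = log)
  }
  list(a_rewarded = run_twin(assignment$group_a, seeds[1]),
       b_rewarded = run_twin(assignment$group_b, seeds[2]))
}
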