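#' Per-area responsiveness threshold for assembly identification
#'
#' A cell counts as responsive to an input pattern if its peak slow rate
#' estimate during the presentation reaches `gamma` times the maximum
#' response in its area to that input (separately per input and per
#' area). If the whole area stayed silent (maximum 0) the area
#' contributes no members.
#'
#' @param responses peak time-averaged responses of one area's excitatory
#'   cells during one presentation.
#' @param gamma responsiveness fraction in \[0, 1\] (default 0.5).
#' @return The scalar threshold `gamma * max(responses)`.
#' @examples
#' responsiveness_threshold(c(0.1, 0.4, 0.2), 0.5)  # 0.2
#' @export
responsiveness_threshold <- function(responses, gamma = 0.5) {
  if (length(responses) == 0) stop("empty area: no responses")
  gamma * max(responses)
}

#' Identify cell-assembly circuits by single-presentation responsiveness
#'
#' With learning frozen, presents each pattern pair once (16-step clamp,
#' preceded by an unstimulated settling interval), records every
#' excitatory cell's peak slow rate estimate during the window, and
#' thresholds per input and per area at `gamma` times the area maximum.
#' All cells at or above threshold form the circuit specific to that
#' input. Works on a copy: the passed network's weights and state are
#' left untouched.
#'
#' @param net a trained `"canet_network"`.
#' @param pairs the pattern pairs used in training.
#' @param seed optional seed (sub-stream `"noise_identify"`).
#' @param clamp_steps presentation length in steps.
#' @return A list of circuits, one per pattern: each a list with
#'   `pattern_id`, `members` (global excitatory indices), `members_by_area`
#'   (list of local indices per area), and `size`.
#' @export
identify_cas <- function(net, pairs, seed = NULL, clamp_steps = 16L) {
  stopifnot(inherits(net, "canet_network"))
  if (!is.null(seed)) set.seed(derive_seed(seed, "noise_identify"))
  gamma <- net$par$gamma
  rf <- net$par$response_floor
  if (is.null(rf)) rf <- model_params()$response_floor
  probe <- net_copy(net)
  lapply(pairs, function(pair) {
    run_engine(probe, mode = "isi", learn = FALSE)
    om0 <- probe$omega_E + 0  # force a copy: the engine mutates in place
    res <- run_engine(probe, mode = "fixed", max_steps = clamp_steps,
                      stim = pattern_stim(pair), learn = FALSE,
                      record = "peak_omega_e")
    # stimulus-attributable response: baseline-corrected peak of the slow
    # rate estimate, so cells that merely happened to be noise-active at
    # stimulus onset do not register as responsive
    peaks <- pmax(0, res$peak_omega_e - om0)
    members <- integer()
    by_area <- vector("list", 6L)
    names(by_area) <- AREA_NAMES
    for (a in seq_len(6L)) {
      idx <- (a - 1L) * CELLS_PER_AREA + seq_len(CELLS_PER_AREA)
      r <- peaks[idx]
      mx <- max(r)
      # an area contributes members only when its maximal stimulus-locked
      # response is distinguishable from baseline fluctuation: at least the
      # rate increase of a cell firing throughout half the window
      # (response_floor); a silent or noise-level area adds none
      if (mx > 0 && mx >= rf) {
        thr <- responsiveness_threshold(r, gamma)
        loc <- which(r >= thr)
        by_area[[a]] <- loc
        members <- c(members, idx[loc])
      } else {
        by_area[[a]] <- integer()
      }
    }
    list(pattern_id = pair$id, members = members,
         members_by_area = by_area, size = length(members))
  })
}

#' Instantaneous assembly activity from a firing snapshot
#'
#' The fraction of a circuit's member cells currently active, pooled
#' across all areas.
#'
#' @param firing_snapshot logical/0-1 vector over all excitatory cells
#'   (`TRUE` = active), or an integer vector of active global indices.
#' @param circuit one circuit from [identify_cas()].
#' @return Fraction in \[0, 1\].
#' @export
ca_activity <- function(firing_snapshot, circuit) {
  if (circuit$size == 0) stop("circuit has no members")
  if (is.logical(firing_snapshot) || all(firing_snapshot %in% c(0, 1))) {
    mean(firing_snapshot[circuit$members] > 0)
  } else {
    mean(circuit$members %in% firing_snapshot)
  }
}

#' Detect ignition events in one activity series
#'
#' An event opens at the first step the activity reaches the threshold
#' (inclusive, "reached 50%") and closes at the first step it drops below
#' (strict); an event still open at the end of the series is closed at the
#' series end. Events of one assembly never overlap.
#'
#' @param activity_series numeric vector of activities in \[0, 1\].
#' @param threshold ignition threshold (default 0.5).
#' @return A data.frame with `start`, `end` (0-based step offsets within
#'   the series) and `duration = end - start`.
#' @examples
#' detect_ignitions(c(0, .6, .7, .4))       # start 1, end 3, duration 2
#' detect_ignitions(c(.5, .4, .5, .4))      # two events of duration 1
#' @export
detect_ignitions <- function(activity_series, threshold = 0.5) {
  if (any(activity_series < 0 | activity_series > 1))
    stop("activity values outside [0, 1]")
  ab <- activity_series >= threshold
  if (!any(ab)) return(data.frame(start = integer(), end = integer(), duration = integer()))
  r <- rle(ab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  s <- starts[on] - 1L
  e <- ends[on]  # first below-threshold step (0-based) or series end
  data.frame(start = s, end = e, duration = e - s)
}

#' Merge per-assembly events into ignition episodes
#'
#' An episode is a maximal union of temporally overlapping or abutting
#' ignition events across assemblies: it begins when any assembly crosses
#' the threshold and ends when all have dropped below it. An episode is a
#' co-activation if at least two distinct assemblies are at or above
#' threshold at the same step (i.e. their half-open event intervals
#' overlap).
#'
#' @param events data.frame with `ca_id`, `start`, `end` (half-open
#'   \[start, end) step intervals).
#' @return A data.frame with `start`, `end`, `n_events`, `ca_ids`
#'   (comma-separated), and logical `coactive`.
#' @export
segment_episodes <- function(events) {
  if (nrow(events) == 0)
    return(data.frame(start = integer(), end = integer(), n_events = integer(),
                      ca_ids = character(), coactive = logical()))
  ev <- events[order(events$start, events$end), , drop = FALSE]
  out <- list()
  cur_s <- ev$start[1]; cur_e <- ev$end[1]
  grp <- list(1L)
  for (i in seq_len(nrow(ev))[-1]) {
    if (ev$start[i] <= cur_e) {  # overlapping or abutting
      cur_e <- max(cur_e, ev$end[i])
      grp[[length(grp)]] <- c(grp[[length(grp)]], i)
    } else {
      out[[length(out) + 1L]] <- list(s = cur_s, e = cur_e, idx = grp[[length(grp)]])
      cur_s <- ev$start[i]; cur_e <- ev$end[i]
      grp[[length(grp) + 1L]] <- i
    }
  }
  out[[length(out) + 1L]] <- list(s = cur_s, e = cur_e, idx = grp[[length(grp)]])
  do.call(rbind, lapply(out, function(ep) {
    sub <- ev[ep$idx, , drop = FALSE]
    co <- FALSE
    if (nrow(sub) > 1) {
      for (i in seq_len(nrow(sub) - 1)) {
        for (j in (i + 1):nrow(sub)) {
          if (sub$ca_id[i] != sub$ca_id[j] &&
              max(sub$start[i], sub$start[j]) < min(sub$end[i], sub$end[j])) {
            co <- TRUE
          }
        }
      }
    }
    data.frame(start = ep$s, end = ep$e, n_events = nrow(sub),
               ca_ids = paste(sort(unique(sub$ca_id)), collapse = ","),
               coactive = co)
  }))
}

#' Assemble an ignition log from an engine result
#'
#' @param res result of [run_engine()] with assembly tracking.
#' @param n_cas number of assemblies tracked.
#' @return A list of class `"canet_ignition_log"`: `events` (data.frame
#'   `ca_id`, `start`, `end`, `duration`), `episodes` (from
#'   [segment_episodes()]), optional `activity` matrix (steps x
#'   assemblies), `steps`, and counts.
#' @export
ignition_log <- function(res, n_cas) {
  events <- data.frame(ca_id = res$ev_ca, start = res$ev_start, end = res$ev_end)
  events <- events[order(events$start, events$ca_id), , drop = FALSE]
  rownames(events) <- NULL
  events$duration <- events$end - events$start
  structure(list(events = events, episodes = segment_episodes(events),
                 activity = res$activity, steps = res$steps,
                 n_cas = n_cas, ignitions = res$ignitions,
                 episodes_n = res$episodes),
            class = "canet_ignition_log")
}

#' Co-activation rate of an ignition log
#'
#' Percentage of ignition episodes containing a co-activation.
#'
#' @param log a `"canet_ignition_log"`.
#' @return Percentage in \[0, 100\].
#' @export
coactivation_rate <- function(log) {
  if (nrow(log$episodes) == 0) return(0)
  100 * mean(log$episodes$coactive)
}

#' Exclude outlier networks by the interquartile-range rule
#'
#' Given one co-activation count (or percentage) per network and
#' condition, a network is flagged if any of its condition columns
#' exceeds that column's upper Tukey fence, Q3 + 1.5 IQR (quartiles by
#' the default type-7 rule). Networks with unusually many co-activations
#' can carry spurious reward effects and are dropped from the analysis.
#'
#' @param coactivations data.frame or matrix, one row per network and one
#'   column per condition; an optional `network` column labels the rows.
#' @return A list with `kept` and `excluded` network labels and the
#'   per-column `fences`.
#' @examples
#' x <- data.frame(network = 1:6, pre = c(1, 2, 1, 30, 2, 1))
#' exclude_outliers(x)$excluded  # 4
#' @export
exclude_outliers <- function(coactivations) {
  df <- as.data.frame(coactivations)
  labels <- if ("network" %in% names(df)) df$network else seq_len(nrow(df))
  vals <- df[, setdiff(names(df), "network"), drop = FALSE]
  if (nrow(vals) < 4) stop("need at least 4 networks to define quartiles")
  fences <- vapply(vals, function(col) {
    q <- quantile(col, c(0.25, 0.75), names = FALSE)
    q[2] + 1.5 * (q[2] - q[1])
  }, numeric(1))
  flagged <- rep(FALSE, nrow(vals))
  for (j in seq_along(vals)) flagged <- flagged | vals[[j]] > fences[j]
  list(kept = labels[!flagged], excluded = labels[flagged], fences = fences)
}

#' Per-assembly and per-group ignition metrics
#'
#' Computes each assembly's ignition frequency (number of its events lying
#' in episodes free of co-activations), mean ignition duration over those
#' events, and size, then labels each assembly with its reward group.
#' Episodes containing a co-activation are excluded entirely before
#' counting, so frequencies under exclusion can only shrink.
#'
#' @param log a `"canet_ignition_log"`.
#' @param circuits the circuits the log tracked (sizes are taken from
#'   here).
#' @param assignment group assignment from [split_groups()] (ids are
#'   positions in `circuits`).
#' @param condition condition label, e.g. `"Pre-reward"`, `"Rewarded"`,
#'   `"Unrewarded"`.
#' @param network network ("subject") label.
#' @return A [tibble][tibble::tibble] with columns `network`, `condition`,
#'   `group`, `ca_id`, `frequency`, `mean_duration`, `size`.
#' @export
compute_metrics <- function(log, circuits, assignment, condition = "Pre-reward",
                            network = 1L) {
  clean <- log$episodes[!log$episodes$coactive, , drop = FALSE]
  keep <- rep(FALSE, nrow(log$events))
  if (nrow(clean) > 0 && nrow(log$events) > 0) {
    for (i in seq_len(nrow(clean)))
      keep <- keep | (log$events$start >= clean$start[i] & log$events$end <= clean$end[i])
  }
  ev <- log$events[keep, , drop = FALSE]
  rows <- lapply(seq_along(circuits), function(ca) {
    e <- ev[ev$ca_id == ca, , drop = FALSE]
    tibble::tibble(
      network = network, condition = condition,
      group = if (ca %in% assignment$group_a) "A" else "B",
      ca_id = ca,
      frequency = nrow(e),
      mean_duration = if (nrow(e)) mean(e$duration) else NA_real_,
      size = circuits[[ca]]$size)
  })
  dplyr::bind_rows(rows)
}
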