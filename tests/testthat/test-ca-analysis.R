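test_that("responsiveness threshold is the gamma fraction of the area maximum", {
  expect_equal(responsiveness_threshold(c(0.1, 0.4, 0.25), 0.5), 0.2)
  expect_equal(responsiveness_threshold(rep(0, 10), 0.5), 0)   # silent area
  expect_error(responsiveness_threshold(numeric(0), 0.5), "empty")
  r <- c(0.1, 0.3, 0.3, 0.2)
  expect_equal(sum(r >= responsiveness_threshold(r, 1)), 2)    # gamma = 1: maxima only
})

test_that("assembly activity is the active-member fraction", {
  circuit <- list(members = c(1L, 3L, 5L, 7L), size = 4L)
  snap <- rep(FALSE, 10)
  expect_equal(ca_activity(snap, circuit), 0)
  snap[c(1, 3, 5, 7)] <- TRUE
  expect_equal(ca_activity(snap, circuit), 1)
  snap[c(5, 7)] <- FALSE
  expect_equal(ca_activity(snap, circuit), 0.5)
  expect_error(ca_activity(snap, list(members = integer(), size = 0L)), "no members")
})

test_that("ignition detection applies inclusive onset and strict offset", {
  ev <- detect_ignitions(c(0, .6, .7, .4))
  expect_equal(ev, data.frame(start = 1L, end = 3L, duration = 2L))
  expect_equal(nrow(detect_ignitions(rep(0, 50))), 0)
  ev2 <- detect_ignitions(c(.5, .4, .5, .4))
  expect_equal(ev2$duration, c(1L, 1L))
  expect_equal(ev2$start, c(0L, 2L))
  # open event closes at the series end
  ev3 <- detect_ignitions(c(0, .9, .9))
  expect_equal(ev3$end, 3L)
  expect_error(detect_ignitions(c(0, 1.2)), "outside")
})

test_that("episode segmentation merges overlapping and abutting events", {
  ev <- data.frame(ca_id = c(1L, 2L), start = c(10L, 15L), end = c(20L, 25L))
  ep <- segment_episodes(ev)
  expect_equal(nrow(ep), 1)
  expect_equal(c(ep$start, ep$end), c(10L, 25L))
  expect_true(ep$coactive)
  # disjoint single-assembly events: two clean episodes
  ev2 <- data.frame(ca_id = c(1L, 2L), start = c(0L, 30L), end = c(5L, 40L))
  ep2 <- segment_episodes(ev2)
  expect_equal(nrow(ep2), 2)
  expect_false(any(ep2$coactive))
  # abutting events of different assemblies merge without co-activation
  ev3 <- data.frame(ca_id = c(1L, 2L), start = c(0L, 5L), end = c(5L, 9L))
  ep3 <- segment_episodes(ev3)
  expect_equal(nrow(ep3), 1)
  expect_false(ep3$coactive)
})

test_that("segmentation matches the brute-force timeline oracle on random series", {
  set.seed(123)
  for (rep in 1:1000) {
    n_ca <- sample(1:4, 1)
    horizon <- sample(10:40, 1)
    series <- replicate(n_ca, random_activity_series(horizon), simplify = FALSE)
    events <- do.call(rbind, lapply(seq_len(n_ca), function(ca) {
      ev <- detect_ignitions(series[[ca]])
      if (nrow(ev)) cbind(ca_id = ca, ev) else NULL
    }))
    if (is.null(events) || nrow(events) == 0) next
    got <- segment_episodes(events)
    want <- episode_oracle(events, horizon)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$coactive, want$coactive)
  }
})

test_that("the upper-fence IQR rule reproduces the reference exclusion set", {
  tab <- read.csv(system.file("extdata", "coactivation_example.csv", package = "canet"))
  out <- exclude_outliers(tab)
  expect_setequal(out$excluded, c(3, 7, 15))
  expect_length(out$kept, 15)
  # all-equal counts: IQR zero, nothing above the fence
  same <- data.frame(network = 1:6, a = rep(2, 6))
  expect_length(exclude_outliers(same)$excluded, 0)
  # a single extreme network is excluded
  one <- data.frame(network = 1:8, a = c(1, 1.2, 0.9, 1.1, 10, 1, 1.05, 0.95))
  expect_equal(exclude_outliers(one)$excluded, 5)
  expect_error(exclude_outliers(data.frame(a = 1:3)), "at least 4")
})

test_that("rank-interleaved groups balance total ignition frequency for
           near-equal assemblies", {
  # frozen network with implanted assemblies of comparable size: the
  # interleaved split should equalize the groups' total spontaneous
  # ignition counts to within the larger group's Poisson sd
  sys <- implant_assemblies(sizes = 44L + (0:11) %% 4L * 4L, strength = 1.2, seed = 9)
  set.seed(19)
  invisible(run_free(sys$net, 300))
  res <- run_engine(sys$net, "fixed", 30000L, circuits = sys$circuits)
  counts <- tabulate(res$ev_ca, 12)
  sizes <- vapply(sys$circuits, `[[`, 0L, "size")
  assignment <- split_groups(rank_cas(counts, sizes))
  fa <- sum(counts[assignment$group_a]); fb <- sum(counts[assignment$group_b])
  # the interleaved split keeps the groups' totals close (here: within 10%)
  # and far closer than a naive top-half/bottom-half split
  expect_lt(abs(fa - fb), 0.1 * (fa + fb))
  ranked <- rank_cas(counts, sizes)
  naive <- abs(sum(counts[ranked[1:6]]) - sum(counts[ranked[7:12]]))
  expect_lt(abs(fa - fb), naive)
})

test_that("metrics exclude co-activation episodes and keep clean bookkeeping", {
  circuits <- lapply(1:12, function(i) list(pattern_id = i, members = 1:10, size = 10L))
  assignment <- list(group_a = 1:6, group_b = 7:12)
  # one clean event of duration 7 for assembly 5
  log <- list(events = data.frame(ca_id = 5L, start = 3L, end = 10L, duration = 7L))
  log$episodes <- segment_episodes(log$events)
  m <- compute_metrics(log, circuits, assignment, "Pre-reward", network = 1)
  expect_equal(nrow(m), 12)
  expect_equal(m$frequency[m$ca_id == 5], 1)
  expect_equal(m$mean_duration[m$ca_id == 5], 7)
  expect_equal(sum(m$frequency), 1)
  expect_equal(sort(unique(m$group)), c("A", "B"))
  # a log whose only episode is a co-activation yields all-zero frequencies
  log2 <- list(events = data.frame(ca_id = c(1L, 2L), start = c(0L, 2L),
                                   end = c(5L, 6L), duration = c(5L, 4L)))
  log2$episodes <- segment_episodes(log2$events)
  m2 <- compute_metrics(log2, circuits, assignment, "Pre-reward", network = 1)
  expect_true(all(m2$frequency == 0))
  # exclusion can only reduce or preserve frequencies
  log3 <- list(events = data.frame(ca_id = c(1L, 1L, 2L, 3L),
                                   start = c(0L, 10L, 11L, 30L),
                                   end = c(5L, 14L, 15L, 33L),
                                   duration = c(5L, 4L, 4L, 3L)))
  log3$episodes <- segment_episodes(log3$events)
  m3 <- compute_metrics(log3, circuits, assignment, "Pre-reward", network = 1)
  raw <- tabulate(log3$events$ca_id, 12)
  expect_true(all(m3$frequency <= raw))
  expect_equal(m3$frequency[1:3], c(1, 0, 1))
})
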