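test_that("architecture graph has exactly the documented twelve reciprocal links", {
  g <- area_graph()
  expect_length(g$nodes, 6L)
  expect_equal(nrow(g$edges), 12L)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_equal(anyDuplicated(key(g$edges$from, g$edges$to)), 0L)
  expected <- c("PF PM", "M1 PM", "M1 PF", "PA SA", "S1 SA", "PA S1",
                "M1 S1", "M1 SA", "PM S1", "PM SA", "PA PM", "PA PF")
  expect_setequal(key(g$edges$from, g$edges$to), expected)
  # documented absences stay absent
  expect_false("M1 PA" %in% key(g$edges$from, g$edges$to))
  expect_false("PF S1" %in% key(g$edges$from, g$edges$to))
})

test_that("PA's neighbours are the somatosensory areas plus premotor and prefrontal", {
  expect_setequal(area_neighbors("PA"), c("SA", "S1", "PM", "PF"))
})

test_that("sampled projections respect the neighbourhood clip and weight range", {
  p <- model_params()
  set.seed(1)
  s <- sample_projection("M1", "PM", "exc", p)
  h <- (p$n_exc_neighborhood - 1) / 2
  dr <- abs((s$pre - 1) %/% 25 - (s$post - 1) %/% 25)
  dc <- abs((s$pre - 1) %% 25 - (s$post - 1) %% 25)
  expect_true(all(dr <= h & dc <= h))
  expect_true(all(s$w >= 0 & s$w <= p$w_init_max))
  # within-area projections exclude self-synapses
  set.seed(2)
  s2 <- sample_projection("M1", "M1", "exc", p)
  expect_false(any(s2$pre == s2$post))
  # mirror-symmetric offsets get equal kernel probability
  off <- canet:::kernel_offsets(19, p$sigma_exc, p$p0_exc)
  expect_equal(off$p[off$dr == 3 & off$dc == -2], off$p[off$dr == -3 & off$dc == 2])
})

test_that("inhibitory weights are fixed at 1 and the column pairing is deterministic", {
  p <- model_params()
  set.seed(4)
  s <- sample_projection("M1", "M1", "inh", p)
  h <- (p$n_inh_neighborhood - 1) / 2
  dr <- abs((s$pre - 1) %/% 25 - (s$post - 1) %/% 25)
  dc <- abs((s$pre - 1) %% 25 - (s$post - 1) %% 25)
  expect_true(all(dr <= h & dc <= h))
  expect_true(all(s$w == 1))
  pair <- sample_projection("M1", "M1", "pair", p)
  expect_equal(pair$pre, seq_len(625))
  expect_equal(pair$post, seq_len(625))
  expect_true(all(pair$w == p$w_ei))
})

test_that("realized link fraction matches the analytic kernel average", {
  # Monte-Carlo vs analytic mean of the clipped Gaussian kernel over all
  # (pre, post) candidate pairs of one projection, 625 pre cells
  p <- model_params()
  set.seed(11)
  s <- sample_projection("M1", "PM", "exc", p)
  off <- canet:::kernel_offsets(p$n_exc_neighborhood, p$sigma_exc, p$p0_exc)
  r <- (0:624) %/% 25; cc <- (0:624) %% 25
  expected <- 0
  for (k in seq_len(nrow(off))) {
    valid <- sum(r + off$dr[k] >= 0 & r + off$dr[k] < 25 &
                 cc + off$dc[k] >= 0 & cc + off$dc[k] < 25)
    expected <- expected + valid * off$p[k]
  }
  expect_lt(abs(nrow(s) - expected) / expected, 0.01)
})

test_that("initialized network is reproducible, sparse, and structurally sound", {
  net1 <- fixture_net()
  net2 <- init_network(model_params(), seed = 42)
  expect_identical(net1$conn, net2$conn)
  ee <- net1$conn$ee
  # no synapse outside the architecture graph's edges
  g <- area_graph()
  allowed <- paste(g$edges$from, g$edges$to)
  allowed <- c(allowed, paste(g$edges$to, g$edges$from), paste(AREA_NAMES, AREA_NAMES))
  links <- unique(paste(AREA_NAMES[area_of(ee$pre)], AREA_NAMES[area_of(ee$post)]))
  expect_true(all(links %in% allowed))
  expect_setequal(links, allowed)  # every documented projection realized
  # sparsity: strictly below half of all candidate pairs per projection
  proj <- paste(area_of(ee$pre), area_of(ee$post))
  expect_true(all(table(proj) / 625^2 < 0.5))
  # no self links, no duplicates, weights within the initial range
  expect_false(any(ee$pre == ee$post))
  expect_equal(anyDuplicated(paste(ee$pre, ee$post)), 0L)
  expect_true(all(ee$w >= 0 & ee$w <= model_params()$w_init_max))
  # between flag consistent with areas
  expect_equal(ee$between, area_of(ee$pre) != area_of(ee$post))
})

test_that("border cells have fewer candidate partners, monotone toward corners", {
  p <- model_params()
  h <- (p$n_exc_neighborhood - 1) / 2
  cand <- function(r, c) {
    sum(outer(max(0, r - h):min(24, r + h) >= 0, max(0, c - h):min(24, c + h) >= 0))
  }
  mid <- cand(12, 12); edge <- cand(12, 0); corner <- cand(0, 0)
  expect_gt(mid, edge)
  expect_gt(edge, corner)
  # monotone along the diagonal toward the corner
  diag_counts <- vapply(0:12, function(d) cand(d, d), numeric(1))
  expect_true(all(diff(diag_counts) >= 0))
})

test_that("network copies are deep and snapshots round-trip bit-exactly", {
  net <- init_network(model_params(), seed = 3)
  twin <- net_copy(net)
  twin$V_e[1] <- 99
  expect_identical(net$V_e[1], 0)
  twin2 <- net_copy(net)
  set.seed(5); invisible(run_free(twin2, 3))
  expect_identical(net$t, 0L)  # engine run on the copy left the original alone
  f <- tempfile(fileext = ".rds")
  save_network(net, f)
  back <- load_network(f)
  for (nm in c("V_e", "V_i", "omega", "omega_E", "omega_G", "phi_e", "t"))
    expect_identical(get(nm, net), get(nm, back))
  expect_identical(net$conn, back$conn)
  unlink(f)
})
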