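test_that("net input composes baseline, weighted drive and inhibition", {
  net <- net_copy(fixture_net())
  p <- net$par
  # quiescent network: only the baseline survives
  expect_equal(net_input(1L, net), p$Vb)
  expect_equal(net_input(1L, net, external_drive = 3), p$Vb + 3)
  # single within-area presynaptic spike through w = 0.1 at k_rec = 500 -> 50
  ee <- net$conn$ee
  k <- which(!ee$between)[1]
  net$conn$ee$w[k] <- 0.1
  net$phi_e[ee$pre[k]] <- 1L
  expect_equal(net_input(ee$post[k], net), 50)
  net$phi_e[ee$pre[k]] <- 0L
  # global inhibition alone: omega_G = 1 at k_G = 95 -> -95
  net$omega_G[area_of(7L)] <- 1
  expect_equal(net_input(7L, net), -95)
  expect_error(net_input(0L, net), "unknown cell")
  expect_error(net_input(N_EXC + 1L, net), "unknown cell")
  net$conn$ee$w[k] <- -0.1
  expect_error(net_input(ee$post[k], net), "negative")
})

test_that("membrane updates follow the Euler decay law", {
  p <- model_params()
  expect_equal(update_membrane(0, 0, p, 0, tau = 2.5, k2 = 0), 0)   # fixed point
  expect_equal(update_membrane(1, 0, p, 0, tau = 2.5, k2 = 0), 0.8) # one-step decay
  # closed-form geometric decay over n noise-free steps
  V <- 3.7
  for (i in 1:100) V <- update_membrane(V, 0, p, 0, tau = p$tau_exc, k2 = 0)
  expect_equal(V, 3.7 * (1 - p$dt / p$tau_exc)^100, tolerance = 1e-9)
  # noise forced to zero when k2 = 0 even if a sample is passed
  expect_equal(update_membrane(1, 0, p, 0.5, tau = 5, k2 = 0), 0.9)
  expect_error(update_membrane(1, Inf, p), "non-finite")
})

test_that("excitatory output is binary with strict threshold and adaptation penalty", {
  p <- model_params()
  expect_equal(excitatory_output(0.20, 0, p), 1L)
  expect_equal(excitatory_output(0.18, 0, p), 0L)  # boundary excluded
  expect_equal(excitatory_output(0.60, 0.05, p), 1L)  # 0.60 - 0.35 > 0.18
  expect_equal(excitatory_output(0.60, 0.06, p), 0L)  # 0.60 - 0.42 = 0.18, strict
  out <- excitatory_output(rnorm(100), runif(100), p)
  expect_true(all(out %in% c(0L, 1L)))
})

test_that("inhibitory output rectifies at zero", {
  expect_equal(inhibitory_output(-0.3), 0)
  expect_equal(inhibitory_output(0), 0)
  expect_equal(inhibitory_output(0.47), 0.47)
  expect_true(all(inhibitory_output(rnorm(100)) >= 0))
})

test_that("rate estimates are convex low-pass filters staying in [0, 1]", {
  p <- model_params()
  est <- update_rate_estimates(0, 0, 1, p)
  expect_equal(est$omega, 0.05)                   # dt/tau_A = 0.05
  expect_equal(est$omega_E, 0.5 / 30)
  expect_equal(update_rate_estimates(0, 0, 0, p)$omega_E, 0)  # fixed point
  om <- 0; omE <- 0
  for (i in 1:3000) {
    e <- update_rate_estimates(om, omE, 1, p); om <- e$omega; omE <- e$omega_E
    expect_true(om >= 0 && om <= 1 && omE >= 0 && omE <= 1)
  }
  expect_equal(om, 1, tolerance = 1e-6)           # converges to the constant input
  expect_equal(omE, 1, tolerance = 1e-6)
})

test_that("global inhibition tracks the area's summed firing", {
  p <- model_params()
  expect_equal(update_global_inhibition(0, 0, p), 0)
  expect_equal(update_global_inhibition(0, 100, p), 100 / 24)  # dt/tau_S = 1/24
  g <- 0
  for (i in 1:1000) g <- update_global_inhibition(g, 57, p)
  expect_equal(g, 57, tolerance = 1e-6)
  expect_error(update_global_inhibition(0, -1, p), "negative")
})

test_that("a quiescent noise-free network stays quiescent and a clamped cell spikes", {
  par <- model_params(k2_exc = 0)
  net <- init_network(par, seed = 5)
  res <- run_free(net, 10)
  expect_true(all(net$V_e == 0) && all(net$phi_e == 0L) && all(net$omega_G == 0))
  expect_equal(net$t, 10L)
  # a single clamped cell fires within 16 steps under default parameters
  res <- run_engine(net, "fixed", 16, stim = 100L)
  expect_equal(net$phi_e[100L], 1L)
  expect_gt(net$omega_E[100L], 0)
})

test_that("trajectories are reproducible from the seed", {
  par <- model_params()
  run_once <- function() {
    net <- init_network(par, seed = 8)
    set.seed(derive_seed(8, "noise"))
    invisible(run_free(net, 40))
    list(V = net$V_e, phi = net$phi_e, omG = net$omega_G)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a, b)
})

test_that("compiled stepper and pure-R reference stepper produce the same trajectory", {
  par <- model_params()
  net_c <- init_network(par, seed = 13)
  net_r <- net_copy(net_c)
  # identical noise stream: both consume one uniform per excitatory cell
  # per step in cell order
  set.seed(1001)
  invisible(run_free(net_c, 25))
  set.seed(1001)
  mats <- step_matrices(net_r)
  for (i in 1:25) step_network(net_r, mats = mats)  # weights frozen: mats valid
  expect_equal(net_c$V_e, net_r$V_e, tolerance = 1e-9)
  expect_identical(net_c$phi_e, net_r$phi_e)
  expect_equal(net_c$V_i, net_r$V_i, tolerance = 1e-9)
  expect_equal(net_c$omega, net_r$omega, tolerance = 1e-9)
  expect_equal(net_c$omega_E, net_r$omega_E, tolerance = 1e-9)
  expect_equal(net_c$omega_G, net_r$omega_G, tolerance = 1e-9)
  # one further step with stimulation and learning on both paths
  set.seed(77)
  invisible(run_engine(net_c, "fixed", 1, stim = c(3L, 700L), learn = TRUE))
  set.seed(77)
  step_network(net_r, stim = c(3L, 700L), learn = TRUE, mats = mats)
  expect_equal(net_c$V_e, net_r$V_e, tolerance = 1e-9)
  expect_identical(net_c$phi_e, net_r$phi_e)
  expect_equal(net_c$conn$ee$w, net_r$conn$ee$w, tolerance = 1e-12)
})

test_that("global inhibition keeps free-running activity within physiological bounds", {
  net <- net_copy(fixture_net())
  set.seed(21)
  res <- run_free(net, 10000, record = "spikes")
  rate <- rowSums(res$area_spikes) / N_EXC
  windows <- colMeans(matrix(rate, nrow = 500))  # 500-step windows
  expect_true(all(windows < 0.5))
})
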