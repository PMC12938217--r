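#' Model parameters
#'
#' Constructs the full parameter set of the network model. The defaults are
#' the standard operating point of the model: leaky integrate-and-fire
#' excitatory cells (membrane time constant 2.5 in arbitrary units), graded
#' inhibitory cells (time constant 5), slow area-level global inhibition
#' (time constant 12), uniform membrane noise with amplitude
#' `k2_exc = N * sqrt(48)` (N = 15; inhibitory cells are noise-free,
#' `k2_inh = 0`), input gains of 500 for between-area, within-area and local
#' inhibitory projections, a global-inhibition gain of 95, firing threshold
#' 0.18, adaptation strength 7, rate-filter time constants 10 (adaptation
#' filter) and 30 (plasticity filter), ABS plasticity thresholds
#' `theta_pre = 0.05`, `theta_minus = 0.14`, LTP threshold range
#' \[0.15, 0.20\], base learning rate 0.001 with reward multiplier 0.5,
#' Euler step 0.5, stimulation amplitude 500, excitatory/inhibitory
#' projection neighbourhoods of 19 and 5 grid cells, and a cell-assembly
#' responsiveness fraction `gamma = 0.5`.
#'
#' A few quantities the model needs are genuinely open choices rather than
#' fixed constants, and are exposed here with calibrated defaults: the
#' Gaussian connection-kernel peak `p0_exc` (0.5) and width `sigma_exc`
#' (9.5 grid units); the synaptic weight ceiling `w_cap` (0.8); the
#' column-pairing drive of the inhibitory layer `w_ei` (1); whether the
#' clamp drive and the noise term pass through the `k1` input scaling
#' (`drive_through_k1`, `noise_through_k1`; both `FALSE`: the drive enters
#' the membrane equation directly and the noise amplitude is unscaled);
#' whether plasticity also applies during the inter-stimulus interval
#' (`learn_in_isi`, `FALSE`); the per-cell activity floor used when
#' counting active assembly members (`activity_floor = 0.04` on the fast
#' rate estimate); the minimal per-area peak response for assembly
#' membership (`response_floor = 0.125`, the rate increase of a cell
#' firing through half the presentation window); the ignition threshold
#' (0.5 = 50% of members active); and the inter-stimulus-interval
#' criterion (all areas below `baseline_tol` summed spikes for
#' `isi_quiet_steps` consecutive steps, capped at `isi_max_steps`). See
#' the methods vignette for the rationale behind each.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list of class `"canet_params"`.
#' @examples
#' p <- model_params()
#' p$thresh
#' model_params(dw_base = 0)$dw_base
#' @export
model_params <- function(...) {
  p <- list(
    # membrane / integration
    tau_exc   = 2.5,
    tau_inh   = 5,
    tau_S     = 12,
    k1        = 0.01,
    N         = 15,
    k2_exc    = 15 * sqrt(48),
    k2_inh    = 0,
    Vb        = 0,
    k_ffb     = 500,
    k_rec     = 500,
    k_inh     = 500,
    k_G       = 95,
    thresh    = 0.18,
    alpha     = 7,
    tau_A     = 10,
    tau_Favg  = 30,
    dt        = 0.5,
    # plasticity
    dw_base        = 0.001,
    dw_multi       = 0.5,
    theta_pre      = 0.05,
    theta_minus    = 0.14,
    theta_plus_min = 0.15,
    theta_plus_max = 0.20,
    w_cap          = 0.8,
    # stimulation / topology
    amplitude          = 500,
    n_exc_neighborhood = 19L,
    n_inh_neighborhood = 5L,
    p0_exc             = 0.5,
    sigma_exc          = 9.5,
    p0_inh             = 1,
    sigma_inh          = 5 / 4,
    w_init_max         = 0.1,
    w_ei               = 1,
    noise_through_k1   = FALSE,
    drive_through_k1   = FALSE,
    # assembly analysis
    gamma              = 0.5,
    activity_floor     = 0.04,
    response_floor     = 0.125,
    ignition_threshold = 0.5,
    # inter-stimulus interval
    learn_in_isi   = FALSE,
    baseline_tol   = 50,
    isi_quiet_steps = 10L,
    isi_max_steps   = 100L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
    if ("N" %in% names(over) && !("k2_exc" %in% names(over))) {
      p$k2_exc <- p$N * sqrt(48)
    }
  }
  validate_params(p)
  structure(p, class = "canet_params")
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the parameter set: positive time
#' constants and Euler step, `gamma` in \[0, 1\], an ordered LTP threshold
#' range, LTD threshold below the maximal LTP threshold, and a nonnegative
#' learning rate.
#'
#' @param p a parameter list as produced by [model_params()].
#' @return `p`, invisibly; errors if any invariant is violated.
#' @export
validate_params <- function(p) {
  taus <- c(p$tau_exc, p$tau_inh, p$tau_S, p$tau_A, p$tau_Favg)
  if (any(!is.finite(taus)) || any(taus <= 0)) stop("all time constants must be > 0")
  if (!is.finite(p$dt) || p$dt <= 0) stop("dt must be > 0")
  if (p$gamma < 0 || p$gamma > 1) stop("gamma must lie in [0, 1]")
  if (p$theta_plus_min > p$theta_plus_max) stop("theta_plus_min must be <= theta_plus_max")
  if (p$theta_minus >= p$theta_plus_max) stop("theta_minus must be < theta_plus_max")
  if (p$dw_base < 0) stop("dw_base must be >= 0")
  if (p$w_cap <= 0) stop("w_cap must be > 0")
  nn <- c(p$n_exc_neighborhood, p$n_inh_neighborhood)
  if (any(nn < 1) || any(nn %% 2 == 0)) stop("neighborhood sizes must be odd and >= 1")
  if (any(nn > 2L * GRID_SIZE - 1L)) stop("neighborhood larger than grid")
  invisible(p)
}

#' Derive a named sub-stream seed from a master seed
#'
#' A single master seed is expanded into independent, named sub-streams
#' (connectivity, patterns, per-phase noise, ...) so that individual stages
#' of an experiment can be replayed in isolation. The derivation is a fixed
#' multiplicative hash; the result is always a valid 32-bit seed.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @return An integer in \[1, 2^31 - 2\].
#' @examples
#' derive_seed(1, "connectivity")
#' derive_seed(1, "noise_phase1")
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.character(stream), length(stream) == 1L, length(master) == 1L)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  s <- (as.numeric(master) %% 2147483647) * 48271 %% 2147483647
  out <- (s + h * 69621) %% 2147483647
  as.integer(if (out < 1) out + 1 else out)
}
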