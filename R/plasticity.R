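#' Reward-modulated learning rate
#'
#' The weight change applied per plasticity event is
#' \eqn{\Delta w = \Delta w_{base}\,(1 + \Delta w_{multi}\,R)}: the base
#' learning rate, boosted by 50% (default multiplier) whenever the global
#' dopamine-like reward signal is on. With `dw_multi = 0` or `R = 0` the
#' rule reduces to plain ABS learning.
#'
#' @param R reward signal, 0 or 1 (vectorized).
#' @param params a [model_params()] list.
#' @return The effective learning rate(s).
#' @examples
#' effective_delta_w(0, model_params())   # 0.001
#' effective_delta_w(1, model_params())   # 0.0015
#' @export
effective_delta_w <- function(R, params) {
  params$dw_base * (1 + params$dw_multi * R)
}

#' Reward-modulated LTP threshold
#'
#' The postsynaptic depolarization required for potentiation is
#' \eqn{\theta_+ = \theta_{+max} - (\theta_{+max} - \theta_{+min})\,R}:
#' reward lowers the LTP threshold from its maximum (0.20) to its minimum
#' (0.15), enlarging the potentiation regime. With
#' `theta_plus_min == theta_plus_max` the threshold is constant for all R.
#'
#' @inheritParams effective_delta_w
#' @return The effective LTP threshold(s).
#' @export
effective_ltp_threshold <- function(R, params) {
  if (params$theta_plus_min > params$theta_plus_max)
    stop("theta_plus_min must be <= theta_plus_max")
  params$theta_plus_max - (params$theta_plus_max - params$theta_plus_min) * R
}

#' ABS plasticity branch for given pre/post state
#'
#' The Artola-Broecher-Singer rule: given sufficient presynaptic activity
#' (`omega_E_pre >= theta_pre`), the direction of change is set by the
#' postsynaptic membrane potential relative to two thresholds -- LTP at or
#' above `theta_plus`, LTD between `theta_minus` and `theta_plus`. A
#' strongly depolarized postsynaptic cell paired with a silent presynaptic
#' cell also depresses (heterosynaptic LTD). Otherwise no change.
#'
#' @param omega_E_pre presynaptic slow rate estimate(s).
#' @param V_post postsynaptic membrane potential(s).
#' @param theta_plus effective LTP threshold (see
#'   [effective_ltp_threshold()]).
#' @param params a [model_params()] list.
#' @return Character vector in `c("LTP", "LTD", "none")`.
#' @examples
#' p <- model_params()
#' plasticity_case(0.06, 0.25, 0.20, p)  # "LTP"
#' plasticity_case(0.06, 0.16, 0.20, p)  # "LTD"
#' plasticity_case(0.01, 0.10, 0.20, p)  # "none"
#' @export
plasticity_case <- function(omega_E_pre, V_post, theta_plus, params) {
  pre_on <- omega_E_pre >= params$theta_pre
  ltp <- pre_on & V_post >= theta_plus
  ltd <- (pre_on & V_post >= params$theta_minus & V_post < theta_plus) |
    (!pre_on & V_post >= theta_plus)
  out <- rep("none", length(ltp))
  out[ltd] <- "LTD"
  out[ltp] <- "LTP"
  out
}

#' Apply one step of ABS plasticity to every eligible synapse
#'
#' Reference implementation of the per-step weight update: every
#' excitatory-to-excitatory synapse whose pre- OR postsynaptic cell spiked
#' this step is updated by plus/minus the effective learning rate
#' according to [plasticity_case()], then clipped to \[0, `w_cap`\].
#' Synapses with neither side spiking, and all inhibitory links, are
#' untouched. The compiled stepper applies the identical rule; this
#' R-level version backs the single-step API and the cross-check tests.
#'
#' @param net a `"canet_network"` whose current-step outputs are in place.
#' @param R_signal reward signal, 0 or 1.
#' @return A summary list (`n_ltp`, `n_ltd`) invisibly; weights are
#'   updated in place.
#' @export
apply_plasticity <- function(net, R_signal = 0) {
  stopifnot(inherits(net, "canet_network"), R_signal %in% c(0, 1))
  p <- net$par
  ee <- net$conn$ee
  gate <- net$phi_e[ee$pre] == 1L | net$phi_e[ee$post] == 1L
  if (!any(gate)) return(invisible(list(n_ltp = 0L, n_ltd = 0L)))
  idx <- which(gate)
  dir <- plasticity_case(net$omega_E[ee$pre[idx]], net$V_e[ee$post[idx]],
                         effective_ltp_threshold(R_signal, p), p)
  dw <- effective_delta_w(R_signal, p)
  w <- ee$w
  w[idx[dir == "LTP"]] <- pmin(w[idx[dir == "LTP"]] + dw, p$w_cap)
  w[idx[dir == "LTD"]] <- pmax(w[idx[dir == "LTD"]] - dw, 0)
  net$conn$ee$w <- w
  invisible(list(n_ltp = sum(dir == "LTP"), n_ltd = sum(dir == "LTD")))
}
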