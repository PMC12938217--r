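#' Advance a network with the compiled stepper
#'
#' Low-level driver around the compiled synchronous Euler stepper. All
#' phase runners ([run_phase1()], [measure_spontaneous()], [run_phase2()],
#' ...) are built on this. The network is advanced in place.
#'
#' @param net a `"canet_network"`.
#' @param mode stop mode: `"fixed"` (run `max_steps` steps), `"episodes"`
#'   (stop after `n_target` completed ignition episodes), `"ignitions"`
#'   (stop after `n_target` ignition onsets across all assemblies), or
#'   `"isi"` (inter-stimulus interval: stop once every area's summed
#'   excitatory output has stayed below `baseline_tol` for
#'   `isi_quiet_steps` consecutive steps).
#' @param max_steps hard step budget for this call.
#' @param stim integer vector of global excitatory cell indices to drive
#'   with `stim_amp` (empty = no stimulation).
#' @param stim_amp external drive amplitude.
#' @param learn logical; apply the ABS plasticity rule each step.
#' @param dw_base,dw_multi learning rate and reward multiplier for this run
#'   (default: the network's parameters).
#' @param circuits optional list of [CACircuit][identify_cas] objects whose
#'   activity is tracked for ignition detection and reward gating.
#' @param rewarded integer ids (positions in `circuits`) whose ignition
#'   switches the global reward signal on; empty = reward never applied.
#' @param n_target target count for `"episodes"` / `"ignitions"` modes.
#' @param record character subset of
#'   `c("activity", "reward", "spikes", "peak_omega_e")`.
#' @return A list with `steps`, `reached`, `ignitions`, `episodes`, the
#'   event table columns (`ev_ca`, `ev_start`, `ev_end`; step offsets
#'   0-based relative to the start of this call), LTP/LTD counts split by
#'   reward state, and any requested recordings.
#' @export
run_engine <- function(net, mode = c("fixed", "episodes", "ignitions", "isi"),
                       max_steps = 1000L, stim = integer(), stim_amp = NULL,
                       learn = FALSE, dw_base = NULL, dw_multi = NULL,
                       circuits = list(), rewarded = integer(),
                       n_target = 0L, record = character()) {
  stopifnot(inherits(net, "canet_network"))
  mode <- match.arg(mode)
  p <- net$par
  if (is.null(stim_amp)) stim_amp <- p$amplitude
  if (is.null(dw_base)) dw_base <- p$dw_base
  if (is.null(dw_multi)) dw_multi <- p$dw_multi
  if (length(stim)) {
    stim <- as.integer(stim)
    if (any(stim < 1L | stim > N_EXC)) stop("stimulus cell index out of range")
  }
  members <- lapply(circuits, function(ca) as.integer(ca$members))
  ctl <- list(
    mode = match(mode, c("fixed", "episodes", "ignitions", "isi")) - 1L,
    max_steps = as.integer(max_steps),
    n_target = as.integer(n_target),
    learn = isTRUE(learn),
    dw_base = as.numeric(dw_base),
    dw_multi = as.numeric(dw_multi),
    stim = stim,
    stim_amp = as.numeric(stim_amp),
    ca_members = members,
    rewarded = as.integer(rewarded),
    record_activity = "activity" %in% record,
    record_reward = "reward" %in% record,
    record_spikes = "spikes" %in% record,
    record_peak_omega_e = "peak_omega_e" %in% record,
    quiet_steps = as.integer(p$isi_quiet_steps)
  )
  if (mode == "isi") ctl$max_steps <- as.integer(p$isi_max_steps)
  sim_run_cpp(net, ctl)
}

#' Run the network freely under noise
#'
#' Convenience wrapper: no stimulation, learning off unless requested.
#'
#' @inheritParams run_engine
#' @param n_steps number of steps.
#' @param ... passed to [run_engine()].
#' @export
run_free <- function(net, n_steps, ...) {
  run_engine(net, mode = "fixed", max_steps = n_steps, ...)
}
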