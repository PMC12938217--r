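#' Net postsynaptic input of one excitatory cell
#'
#' The membrane drive of excitatory cell `x` in area `A` is
#' \deqn{V_{in}(x,t) = V_b + k_{ffb}\sum_{y \notin A} w_{x,y}\,\phi(y,t)
#'   + k_{rec}\sum_{y \in A} w_{x,y}\,\phi(y,t)
#'   - k_{inh}\sum_{inh} w_{x,inh}\,\phi(inh,t) - k_G\,\omega_G(A,t) + d(x,t)}
#' where the inhibitory sum runs over the local inhibitory cells
#' projecting onto `x` (5 x 5 surround, fixed unlearned weight 1),
#' \eqn{\omega_G} is the area's global-inhibition accumulator, and `d` is
#' the external clamping drive (0 or the stimulation amplitude). Outputs
#' are taken from the network's current state; nothing is mutated.
#'
#' @param cell global excitatory cell index (1..3750).
#' @param net a `"canet_network"`.
#' @param external_drive external drive added to the input (default 0).
#' @return The scalar net input \eqn{V_{in}}.
#' @examples
#' \donttest{
#' net <- init_network(seed = 1)
#' net_input(1L, net)   # quiescent network, Vb = 0 -> 0
#' }
#' @export
net_input <- function(cell, net, external_drive = 0) {
  stopifnot(inherits(net, "canet_network"))
  cell <- as.integer(cell)
  if (length(cell) != 1L || is.na(cell) || cell < 1L || cell > N_EXC)
    stop("unknown cell index")
  p <- net$par
  ee <- net$conn$ee
  ks <- ee$csc_order[seq2(ee$col_ptr[cell] + 1L, ee$col_ptr[cell + 1L])]
  w <- ee$w[ks]
  if (any(w < 0)) stop("negative synaptic weight encountered")
  g <- ifelse(ee$between[ks], p$k_ffb, p$k_rec)
  ie <- net$conn$ie
  js <- which(ie$post == cell)
  a <- area_of(cell)
  p$Vb + sum(g * w * net$phi_e[ee$pre[ks]]) -
    p$k_inh * sum(ie$w[js] * net$phi_i[ie$pre[js]]) -
    p$k_G * net$omega_G[a] + external_drive
}

seq2 <- function(from, to) if (to < from) integer() else seq.int(from, to)

#' One Euler update of a membrane potential
#'
#' \eqn{V' = V + (dt/\tau)(-V + k_1 V_{in} + k_2 \eta)} with \eqn{\eta}
#' uniform on \[-0.5, 0.5\]. Inhibitory cells have `k2 = 0` and the noise
#' sample is forced to zero.
#'
#' @param V current membrane potential (vectorized).
#' @param V_in net input.
#' @param params a [model_params()] list.
#' @param noise_sample uniform noise sample(s) in \[-0.5, 0.5\].
#' @param tau membrane time constant (2.5 excitatory, 5 inhibitory).
#' @param k2 noise gain (`k2_exc` for excitatory, 0 for inhibitory).
#' @return Updated potential(s).
#' @examples
#' p <- model_params()
#' update_membrane(1, 0, p, 0, tau = 2.5, k2 = 0)  # 0.8: decay 1 - dt/tau
#' @export
update_membrane <- function(V, V_in, params, noise_sample = 0,
                            tau = params$tau_exc, k2 = params$k2_exc) {
  if (any(!is.finite(V_in))) stop("non-finite net input")
  if (k2 == 0) noise_sample <- 0
  V + (params$dt / tau) * (-V + params$k1 * V_in + k2 * noise_sample)
}

#' Spike output of excitatory cells
#'
#' An excitatory cell fires iff its membrane potential, reduced by the
#' adaptation term \eqn{\alpha\,\omega}, strictly exceeds the firing
#' threshold. There is no post-spike membrane reset; refractoriness arises
#' solely from adaptation.
#'
#' @param V membrane potential(s).
#' @param omega adaptation-rate estimate(s), in \[0, 1\].
#' @param params a [model_params()] list.
#' @return Integer spike indicator(s) in \{0, 1\}.
#' @export
excitatory_output <- function(V, omega, params) {
  as.integer(V - params$alpha * omega > params$thresh)
}

#' Graded output of inhibitory cells
#'
#' Inhibitory cells output their membrane potential rectified at zero.
#'
#' @param V membrane potential(s).
#' @return `pmax(V, 0)`.
#' @export
inhibitory_output <- function(V) pmax(V, 0)

#' Update the two firing-rate low-pass filters
#'
#' `omega` (time constant `tau_A`) feeds adaptation; `omega_E` (time
#' constant `tau_Favg`, slower) is the presynaptic rate estimate of the
#' plasticity rule. Both are Euler low-pass filters of the just-computed
#' output and start at zero.
#'
#' @param omega,omega_E current estimates.
#' @param phi current output(s).
#' @param params a [model_params()] list.
#' @return A list with updated `omega` and `omega_E`.
#' @export
update_rate_estimates <- function(omega, omega_E, phi, params) {
  list(omega = omega + (params$dt / params$tau_A) * (-omega + phi),
       omega_E = omega_E + (params$dt / params$tau_Favg) * (-omega_E + phi))
}

#' Update an area's global-inhibition accumulator
#'
#' A single slow graded unit per area tracks the area's total excitatory
#' firing and inhibits all its excitatory cells proportionally.
#'
#' @param omega_G current accumulator value.
#' @param total_exc_spikes summed excitatory spikes of the area this step.
#' @param params a [model_params()] list.
#' @return Updated accumulator.
#' @export
update_global_inhibition <- function(omega_G, total_exc_spikes, params) {
  if (any(total_exc_spikes < 0)) stop("negative spike count")
  omega_G + (params$dt / params$tau_S) * (-omega_G + total_exc_spikes)
}

#' One synchronous network step (reference implementation)
#'
#' Readable, pure-R composition of the single-cell operations: all inputs
#' are computed from the previous step's outputs, then membranes, outputs,
#' rate estimates and global inhibition are advanced and (optionally) the
#' plasticity rule applied. This is the reference path used to validate
#' the compiled stepper; it consumes the identical noise stream (one
#' uniform per excitatory cell per step, in cell order) so trajectories
#' are directly comparable. Production runs use [run_engine()].
#'
#' @param net a `"canet_network"`, advanced in place.
#' @param stim integer vector of clamped excitatory cells (global indices).
#' @param stim_amp drive amplitude for the clamped cells.
#' @param learn apply plasticity this step.
#' @param R_signal global reward level, 0 or 1.
#' @param mats optional precomputed matrices from [step_matrices()]
#'   (rebuild after any weight change).
#' @return The network, invisibly.
#' @export
step_network <- function(net, stim = integer(), stim_amp = NULL,
                         learn = FALSE, R_signal = 0, mats = NULL) {
  stopifnot(inherits(net, "canet_network"))
  p <- net$par
  if (is.null(stim_amp)) stim_amp <- p$amplitude
  if (is.null(mats)) mats <- step_matrices(net)
  drive <- numeric(N_EXC)
  if (length(stim)) drive[stim] <- stim_amp

  phi_prev <- as.numeric(net$phi_e)
  Vin_e <- p$Vb + as.numeric(mats$Wg %*% phi_prev) -
    p$k_inh * as.numeric(mats$Wie %*% net$phi_i) -
    p$k_G * net$omega_G[area_of(seq_len(N_EXC))]
  if (p$drive_through_k1) Vin_e <- Vin_e + drive
  Vin_i <- p$k_rec * p$w_ei * phi_prev  # column pairing

  noise <- runif(N_EXC) - 0.5
  ext <- if (p$drive_through_k1) 0 else drive
  k2_eff <- if (isTRUE(p$noise_through_k1)) p$k1 * p$k2_exc else p$k2_exc
  net$V_e <- net$V_e + (p$dt / p$tau_exc) *
    (-net$V_e + p$k1 * Vin_e + k2_eff * noise + ext)
  net$V_i <- update_membrane(net$V_i, Vin_i, p, 0, tau = p$tau_inh, k2 = p$k2_inh)

  net$phi_e <- excitatory_output(net$V_e, net$omega, p)
  net$phi_i <- inhibitory_output(net$V_i)

  est <- update_rate_estimates(net$omega, net$omega_E, net$phi_e, p)
  net$omega <- est$omega
  net$omega_E <- est$omega_E
  tot <- tapply(net$phi_e, area_of(seq_len(N_EXC)), sum)
  net$omega_G <- update_global_inhibition(net$omega_G, as.numeric(tot), p)
  net$R_signal <- R_signal

  if (learn) apply_plasticity(net, R_signal)
  net$t <- net$t + 1L
  invisible(net)
}

#' Precompute the sparse input matrices of the reference stepper
#'
#' `Wg` is the gain-scaled excitatory weight matrix (post x pre; entries
#' `k_rec * w` within-area, `k_ffb * w` between areas); `Wie` the local
#' inhibitory-surround matrix (excitatory post x inhibitory pre, fixed
#' unit weights). Rebuild after any plasticity step.
#'
#' @param net a `"canet_network"`.
#' @return A list with sparse matrices `Wg` and `Wie`.
#' @export
step_matrices <- function(net) {
  ee <- net$conn$ee
  g <- ifelse(ee$between, net$par$k_ffb, net$par$k_rec)
  Wg <- Matrix::sparseMatrix(i = ee$post, j = ee$pre, x = g * ee$w,
                             dims = c(N_EXC, N_EXC))
  ie <- net$conn$ie
  Wie <- Matrix::sparseMatrix(i = ie$post, j = ie$pre, x = ie$w,
                              dims = c(N_EXC, N_EXC))
  list(Wg = Wg, Wie = Wie)
}
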