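#' Population transfer function (F-I curve)
#'
#' Nonlinear current-to-rate transfer r = x / (1 - exp(-d x)) with
#' x = g (I - Ithr). The singularity at I = Ithr is removable: the limit is
#' 1/d, and for |d x| < 1e-6 the first-order expansion 1/d + x/2 is used so
#' the function is numerically C1-continuous across threshold.
#'
#' @param current input current, nA (vectorized).
#' @param gain gain factor g, 1/nC.
#' @param threshold threshold current Ithr, nA.
#' @param shape curve shape constant d, s.
#' @return Firing rate(s), Hz; nonnegative and nondecreasing in `current`.
#' @examples
#' p <- dmf_parameters()
#' transfer_rate(p$IthrE, p$gE, p$IthrE, p$dE)  # 1/dE = 6.25 Hz
#' @export
transfer_rate <- function(current, gain, threshold, shape) {
  stopifnot(gain > 0, shape > 0)
  if (any(!is.finite(current)))
    stop("non-finite input current: numerical blow-up upstream")
  x <- gain * (current - threshold)
  dx <- shape * x
  r <- ifelse(abs(dx) < 1e-6, 1 / shape + x / 2, x / (1 - exp(-dx)))
  as.numeric(r)
}

excitatory_rate <- function(I, p) transfer_rate(I, p$gE, p$IthrE, p$dE)
inhibitory_rate <- function(I, p) transfer_rate(I, p$gI, p$IthrI, p$dI)

#' Synaptic input currents
#'
#' Evaluates the excitatory and inhibitory input currents of every region:
#' \deqn{I^E_n = W_E I_0 + w_+ J_{NMDA} S^E_n + G J_{NMDA} \sum_p C_{np} S^E_p
#'       - J_n S^I_n}
#' \deqn{I^I_n = W_I I_0 + J_{NMDA} S^E_n - S^I_n}
#'
#' @param S_E,S_I synaptic gating vectors, length N.
#' @param con a [connectome()] or square matrix.
#' @param coupling a [coupling_config()].
#' @param params a [dmf_parameters()].
#' @return List with numeric vectors `I_E` and `I_I`, nA.
#' @export
synaptic_currents <- function(S_E, S_I, con, coupling,
                              params = dmf_parameters()) {
  w <- if (inherits(con, "dmf_connectome")) con$weights else as.matrix(con)
  n <- nrow(w)
  if (length(S_E) != n || length(S_I) != n || length(coupling$J) != n)
    stop("dimension mismatch between state, connectome and coupling")
  p <- params
  net <- coupling$G * p$J_NMDA * as.numeric(w %*% S_E)
  I_E <- p$W_E * p$I0 + p$w_plus * p$J_NMDA * S_E + net - coupling$J * S_I
  I_I <- p$W_I * p$I0 + p$J_NMDA * S_E - S_I
  list(I_E = I_E, I_I = I_I)
}

#' Deterministic drift of the gating variables
#'
#' The drift (noise-free) part of the gating SDEs:
#' \deqn{dS^E/dt = -S^E/\tau_{NMDA} + (1 - S^E)\,\gamma\, r^E}
#' \deqn{dS^I/dt = -S^I/\tau_{GABA} + r^I}
#'
#' @param S_E,S_I gating vectors.
#' @param r_E,r_I firing-rate vectors computed from the same state, Hz.
#' @param params a [dmf_parameters()].
#' @return List with vectors `dS_E` and `dS_I`, 1/s.
#' @export
drift <- function(S_E, S_I, r_E, r_I, params = dmf_parameters()) {
  if (length(S_E) != length(r_E) || length(S_I) != length(r_I))
    stop("dimension mismatch between gating and rates")
  p <- params
  list(dS_E = -S_E / p$tau_NMDA + (1 - S_E) * p$gamma_kin * r_E,
       dS_I = -S_I / p$tau_GABA + r_I)
}
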