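#' Dynamic mean-field model parameters
#'
#' Container for the constants of the two-population (excitatory/inhibitory)
#' dynamic mean-field neural mass model. Defaults are the standard values used
#' throughout the whole-brain DMF literature. Time constants are given in
#' milliseconds at construction and stored internally in seconds; all currents
#' are in nA and rates in Hz, so the canonical internal unit system is
#' (s, Hz, nA).
#'
#' @param I0 external (background) current, nA.
#' @param W_E,W_I scaling factors of `I0` for the excitatory and inhibitory
#'   pools (dimensionless).
#' @param w_plus local excitatory recurrence weight (dimensionless).
#' @param J_NMDA excitatory synaptic coupling, nA.
#' @param gE,gI gain factors of the excitatory/inhibitory F-I curves, 1/nC.
#' @param IthrE,IthrI F-I curve thresholds, nA.
#' @param dE,dI F-I curve shape constants around threshold, s.
#' @param gamma_kin excitatory kinetic parameter (dimensionless).
#' @param sigma amplitude of the uncorrelated Gaussian noise injected into
#'   the gating equations, nA. Interpreted by the integrators as a diffusion
#'   amplitude per square-root millisecond (the convention of the standard
#'   numerical implementations of this model): the Euler-Maruyama noise
#'   increment is `sigma * sqrt(dt / 1 ms)`. Under this convention an
#'   uncoupled region with J = 1 settles at its documented working point
#'   (mean excitatory rate near 3.4 Hz, mean gating near 0.179).
#' @param tau_NMDA_ms,tau_GABA_ms NMDA/GABA synaptic time constants, ms
#'   (converted once to seconds and stored as `tau_NMDA`, `tau_GABA`).
#'
#' @return An object of class `dmf_parameters`: a named list with the fields
#'   above, time constants in seconds.
#' @examples
#' p <- dmf_parameters()
#' p$tau_NMDA  # 0.1 s
#' @export
dmf_parameters <- function(I0 = 0.382, W_E = 1, W_I = 0.7, w_plus = 1.4,
                           J_NMDA = 0.15, gE = 310, gI = 615,
                           IthrE = 0.403, IthrI = 0.288,
                           dE = 0.16, dI = 0.087,
                           gamma_kin = 0.641, sigma = 0.01,
                           tau_NMDA_ms = 100, tau_GABA_ms = 10) {
  p <- list(I0 = I0, W_E = W_E, W_I = W_I, w_plus = w_plus, J_NMDA = J_NMDA,
            gE = gE, gI = gI, IthrE = IthrE, IthrI = IthrI, dE = dE, dI = dI,
            gamma_kin = gamma_kin, sigma = sigma,
            tau_NMDA = tau_NMDA_ms / 1000, tau_GABA = tau_GABA_ms / 1000)
  strict <- c("I0", "J_NMDA", "gE", "gI", "IthrE", "IthrI", "dE", "dI",
              "gamma_kin", "sigma", "tau_NMDA", "tau_GABA")
  for (nm in strict)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("'", nm, "' must be a single strictly positive number")
  for (nm in c("W_E", "W_I", "w_plus"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("'", nm, "' must be a single nonnegative number")
  structure(p, class = "dmf_parameters")
}

#' Balloon-Windkessel hemodynamic parameters
#'
#' Constants of the hemodynamic model converting excitatory firing rates into
#' BOLD signals: vasodilatory signal decay `kappa`, autoregulatory feedback
#' `gamma_BW`, transit time `tau_BW`, vessel resistance exponent `alpha_BW`,
#' resting oxygen extraction fraction `rho`, resting venous volume fraction
#' `V0` and the BOLD signal coefficients `k1`, `k2`, `k3`.
#'
#' @param kappa vasodilatory signal decay rate, 1/s.
#' @param gamma_BW autoregulatory feedback rate, 1/s.
#' @param tau_BW hemodynamic transit time, s.
#' @param alpha_BW Grubb vessel resistance exponent (dimensionless).
#' @param rho resting oxygen extraction fraction (dimensionless).
#' @param V0 resting venous blood volume fraction.
#' @param k1,k2,k3 BOLD signal coefficients (`k3` may be negative).
#'
#' @return An object of class `dmf_hemo_parameters`.
#' @export
hemodynamic_parameters <- function(kappa = 0.65, gamma_BW = 0.41,
                                   tau_BW = 0.98, alpha_BW = 0.32,
                                   rho = 0.34, V0 = 0.02,
                                   k1 = 2.77264, k2 = 0.572, k3 = -0.43) {
  p <- list(kappa = kappa, gamma_BW = gamma_BW, tau_BW = tau_BW,
            alpha_BW = alpha_BW, rho = rho, V0 = V0, k1 = k1, k2 = k2, k3 = k3)
  for (nm in setdiff(names(p), "k3"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("'", nm, "' must be a single strictly positive number")
  structure(p, class = "dmf_hemo_parameters")
}

#' Integration configuration
#'
#' Time stepping and sampling for the stochastic integrator. The neural
#' equations advance at `dt_dmf` (Euler-Maruyama); the hemodynamic consumer
#' advances at `dt_bk`, fed with the mean excitatory rate of each `dt_bk`
#' block; BOLD is sampled every `TR`. The first `transient_discard` seconds
#' are dropped from the BOLD output and from all rate summaries. Rate samples
#' stream through a fixed-capacity buffer, so memory use is independent of
#' `duration`.
#'
#' @param duration total simulated time, s.
#' @param dt_dmf neural integration step, s.
#' @param dt_bk hemodynamic integration step, s; must be an integer multiple
#'   of `dt_dmf`.
#' @param transient_discard initial transient to discard, s.
#' @param TR BOLD sampling interval, s; must be an integer multiple of `dt_bk`.
#' @param seed integer seed for the noise stream, or `NULL` to use the current
#'   RNG state.
#' @param buffer_capacity capacity of the producer-consumer rate buffer, in
#'   `dt_bk`-steps per region.
#'
#' @return An object of class `dmf_integration_config`.
#' @export
integration_config <- function(duration, dt_dmf = 1e-4, dt_bk = 1e-3,
                               transient_discard = 10, TR = 2, seed = NULL,
                               buffer_capacity = 10000) {
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0,
            dt_dmf > 0, dt_bk > 0, TR > 0, buffer_capacity >= 1)
  if (abs(dt_bk / dt_dmf - round(dt_bk / dt_dmf)) > 1e-8)
    stop("'dt_bk' must be an integer multiple of 'dt_dmf'")
  if (abs(TR / dt_bk - round(TR / dt_bk)) > 1e-8)
    stop("'TR' must be an integer multiple of 'dt_bk'")
  if (duration <= transient_discard)
    stop("'duration' must exceed 'transient_discard'")
  structure(list(dt_dmf = dt_dmf, dt_bk = dt_bk, duration = duration,
                 transient_discard = transient_discard, TR = TR,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 buffer_capacity = as.integer(buffer_capacity)),
            class = "dmf_integration_config")
}

#' Coupling configuration
#'
#' Global coupling `G` and the per-region inhibitory feedback vector `J`
#' (feedback inhibition control). When `J` is produced by the linear rule
#' [linear_fic()], `alpha` records the excitation-to-inhibition ratio used and
#' `c` the offset.
#'
#' @param G global coupling, dimensionless, >= 0.
#' @param J per-region inhibitory feedback weights, nonnegative vector.
#' @param alpha optional E/I ratio used to generate `J`.
#' @param c offset of the linear rule (the uncoupled value of `J`).
#'
#' @return An object of class `dmf_coupling`.
#' @export
coupling_config <- function(G, J, alpha = NULL, c = 1) {
  stopifnot(is.numeric(G), length(G) == 1L, G >= 0, is.numeric(J))
  if (any(!is.finite(J)) || any(J < 0))
    stop("'J' must be finite and nonnegative")
  structure(list(G = G, J = as.numeric(J), alpha = alpha, c = c),
            class = "dmf_coupling")
}

#' @export
print.dmf_parameters <- function(x, ...) {
  cat("DMF parameters (s, Hz, nA):\n")
  print(unclass(x)[])
  invisible(x)
}
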