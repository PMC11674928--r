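#' Linear feedback-inhibition-control rule
#'
#' Closed-form inhibitory feedback: J_n = alpha * G * beta_n + c, where
#' beta_n is the node strength and alpha the global excitation-to-inhibition
#' ratio. At G = 0 every region gets J_n = c (default 1, the uncoupled
#' value).
#'
#' @param G global coupling, >= 0.
#' @param strengths node strength vector beta (see [node_strength()]),
#'   nonnegative.
#' @param alpha E/I ratio, > 0 (see [analytic_alpha_c()] for the first-order
#'   value, or [fit_alpha()] to regress it from calibrated J vectors).
#' @param c offset, the J of an uncoupled region.
#' @return Numeric vector J of the same length as `strengths`.
#' @examples
#' linear_fic(G = 2, strengths = 10, alpha = 0.75)  # 16
#' @export
linear_fic <- function(G, strengths, alpha, c = 1) {
  if (!is.numeric(G) || length(G) != 1L || G < 0) stop("'G' must be >= 0")
  if (any(strengths < 0)) stop("'strengths' must be nonnegative")
  if (!is.numeric(alpha) || alpha <= 0) stop("'alpha' must be positive")
  alpha * G * strengths + c
}

#' Steady-state expected excitatory gating
#'
#' Closed-form expectation of the excitatory gating variable at a given mean
#' firing rate, obtained from the stationary gating equation under the
#' factorization E[S r] = E[S] E[r]:
#' \deqn{E[S^E] = \gamma\tau_{NMDA} E[r^E] / (1 + \gamma\tau_{NMDA} E[r^E])}
#'
#' @param rate mean excitatory firing rate, Hz, >= 0 (vectorized).
#' @param params a [dmf_parameters()].
#' @return Gating expectation in [0, 1), increasing in `rate`.
#' @examples
#' expected_gating(3.4)  # 0.179
#' @export
expected_gating <- function(rate, params = dmf_parameters()) {
  if (any(rate < 0)) stop("'rate' must be nonnegative")
  gt <- params$gamma_kin * params$tau_NMDA
  gt * rate / (1 + gt * rate)
}

#' Uncoupled fixed-point moments
#'
#' Solves the stationary moment system of a single uncoupled region at a
#' target mean excitatory rate: E[I_E] from inverting the excitatory F-I
#' curve, E[S_E] from [expected_gating()], and the scalar inhibitory fixed
#' point S_I = tau_GABA * F_I(W_I I0 + J_NMDA E[S_E] - S_I) by bracketed
#' bisection (deterministic, residual < 1e-10).
#'
#' @param params a [dmf_parameters()].
#' @param rate_target target mean excitatory rate, Hz.
#' @return An object of class `dmf_moments`: list with `E_rE`, `E_SE`,
#'   `E_SI`, `E_IE`, `E_II`, `E_rI`.
#' @export
solve_uncoupled_moments <- function(params = dmf_parameters(),
                                    rate_target = 3.4) {
  p <- params
  E_SE <- expected_gating(rate_target, p)
  # invert F_E: bracket from below threshold to well above
  f_e <- function(I) excitatory_rate(I, p) - rate_target
  lo <- p$IthrE - 2 / p$gE * (1 / p$dE)  # far below: rate ~ 0
  hi <- p$IthrE + (rate_target + 10) / p$gE
  while (f_e(lo) > 0) lo <- lo - 0.1
  if (f_e(lo) * f_e(hi) > 0) stop("failed to bracket E[I_E]")
  E_IE <- uniroot(f_e, c(lo, hi), tol = 1e-12)$root
  # scalar inhibitory fixed point
  base <- p$W_I * p$I0 + p$J_NMDA * E_SE
  g <- function(S) p$tau_GABA * inhibitory_rate(base - S, p) - S
  if (g(0) < 0) stop("failed to bracket E[S_I]")
  E_SI <- uniroot(g, c(0, 1), tol = 1e-12)$root
  E_II <- base - E_SI
  E_rI <- inhibitory_rate(E_II, p)
  m <- list(E_rE = rate_target, E_SE = E_SE, E_SI = E_SI,
            E_IE = E_IE, E_II = E_II, E_rI = E_rI)
  structure(m, class = "dmf_moments")
}

#' First-order analytic FIC coefficients
#'
#' Computes the linear-rule coefficients from the uncoupled moments:
#' \deqn{\alpha = J_{NMDA} E[S^E] / E[S^I]}
#' \deqn{c = (W_E I_0 + w_+ J_{NMDA} E[S^E] - E[I^E]) / E[S^I]}
#' With default parameters and a 3.4 Hz target this yields alpha = 0.67 and
#' c = 0.97 (2 d.p.); c is commonly rounded to 1 so that uncoupled regions
#' get exactly J = 1.
#'
#' @param moments a [solve_uncoupled_moments()] result.
#' @param params a [dmf_parameters()].
#' @return List with `alpha` and `c`.
#' @export
analytic_alpha_c <- function(moments = solve_uncoupled_moments(params),
                             params = dmf_parameters()) {
  p <- params
  if (moments$E_SI <= 0) stop("E[S_I] must be positive")
  alpha <- p$J_NMDA * moments$E_SE / moments$E_SI
  cc <- (p$W_E * p$I0 + p$w_plus * p$J_NMDA * moments$E_SE - moments$E_IE) /
    moments$E_SI
  list(alpha = alpha, c = cc)
}

#' Iterative FIC calibration
#'
#' Classical calibrator: repeatedly simulates short probe runs and nudges each
#' region's inhibitory weight up or down in proportion to the deviation of its
#' mean excitatory rate from the target, until all regions are within
#' tolerance. Update rule: J_n <- max(J_n + eta * (r_n - target), 0) with the
#' per-iteration rate error clipped to +/- 10 Hz for robustness against
#' transiently hyperexcited probes.
#'
#' @param con a [connectome()].
#' @param G global coupling.
#' @param rate_target target mean excitatory rate, Hz.
#' @param tolerance convergence tolerance on |mean rate - target|, Hz.
#' @param max_outer_iter maximum number of probe iterations.
#' @param seed integer seed; probe i uses seed + i so the calibration is
#'   deterministic.
#' @param eta learning rate, (unit J) per Hz.
#' @param probe_duration,probe_discard probe simulation length and transient
#'   discard, s.
#' @param J_init initial J vector (default: all ones, the uncoupled value, so
#'   any strength dependence of the result emerges from the calibration).
#' @param params a [dmf_parameters()].
#' @return An object of class `dmf_fic`: list with `J`, `converged`,
#'   `iterations`, `max_rate_error` (final max |mean rate - target|), and
#'   `rate_mean` of the last probe. Non-convergence sets `converged = FALSE`
#'   (no error).
#' @export
calibrate_fic_iterative <- function(con, G, rate_target = 3.4,
                                    tolerance = 0.2, max_outer_iter = 150,
                                    seed = 1, eta = 0.05,
                                    probe_duration = 20, probe_discard = 2,
                                    J_init = NULL,
                                    params = dmf_parameters()) {
  stopifnot(inherits(con, "dmf_connectome"), G >= 0)
  n <- nrow(con$weights)
  J <- if (is.null(J_init)) rep(1, n) else J_init
  rate_mean <- rep(NA_real_, n)
  err <- rep(Inf, n)
  it <- 0L
  for (it in seq_len(max_outer_iter)) {
    cfg <- integration_config(duration = probe_duration,
                              transient_discard = probe_discard,
                              TR = 2, seed = seed + it)
    res <- tryCatch(
      simulate_rates(con, coupling_config(G, J), cfg, params = params),
      dmf_divergence_error = function(e) NULL)
    if (is.null(res)) {          # runaway excitation: push inhibition up hard
      J <- J * 1.2 + 0.1
      err <- rep(Inf, n)
      next
    }
    rate_mean <- res$rate_mean
    err <- rate_mean - rate_target
    if (all(abs(err) < tolerance)) {
      return(structure(list(J = J, converged = TRUE, iterations = it,
                            max_rate_error = max(abs(err)),
                            rate_mean = rate_mean), class = "dmf_fic"))
    }
    J <- pmax(J + eta * pmin(pmax(err, -10), 10), 0)
  }
  structure(list(J = J, converged = FALSE, iterations = it,
                 max_rate_error = max(abs(err)), rate_mean = rate_mean),
            class = "dmf_fic")
}

#' Regress the E/I ratio from calibrated inhibitory weights
#'
#' Least-squares slope of (J_n - 1) against G * beta_n, pooled over regions
#' and coupling values, with the intercept constrained to zero (the slope at
#' G = 0 must vanish). `weight_rule = "high_G"` gives 10x weight to points
#' with G above 2.1, emphasizing the near-bifurcation regime.
#'
#' @param J_by_G list of entries `list(G = <scalar>, J = <vector>)`, with at
#'   least two distinct G values.
#' @param strengths node strength vector beta.
#' @param weight_rule `"uniform"` or `"high_G"`.
#' @param high_G_threshold,high_G_weight threshold and weight multiplier for
#'   `"high_G"`.
#' @return The estimated slope alpha (scalar).
#' @examples
#' beta <- c(1, 2, 3)
#' jg <- lapply(c(0.5, 1, 2), function(g)
#'   list(G = g, J = 0.7 * g * beta + 1))
#' fit_alpha(jg, beta)  # 0.7
#' @export
fit_alpha <- function(J_by_G, strengths,
                      weight_rule = c("uniform", "high_G"),
                      high_G_threshold = 2.1, high_G_weight = 10) {
  weight_rule <- match.arg(weight_rule)
  Gs <- vapply(J_by_G, function(e) e$G, numeric(1))
  if (length(unique(Gs)) < 2L)
    stop("need at least two distinct G values")
  x <- unlist(lapply(J_by_G, function(e) e$G * strengths))
  y <- unlist(lapply(J_by_G, function(e) e$J - 1))
  w <- unlist(lapply(J_by_G, function(e)
    rep(if (weight_rule == "high_G" && e$G > high_G_threshold)
      high_G_weight else 1, length(strengths))))
  if (all(x == 0)) stop("degenerate regressor: all G * beta are zero")
  sum(w * x * y) / sum(w * x * x)
}

#' @export
print.dmf_fic <- function(x, ...) {
  cat("FIC calibration:", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iterations; max rate error",
      sprintf("%.3f", x$max_rate_error), "Hz\n")
  invisible(x)
}
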