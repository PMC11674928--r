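#' Run a whole-brain simulation
#'
#' Integrates the coupled gating SDEs with the Euler-Maruyama scheme at
#' `config$dt_dmf`, streams block-mean excitatory rates at `config$dt_bk`
#' through a fixed-capacity buffer into the Balloon-Windkessel consumer, and
#' returns BOLD sampled every `config$TR` after discarding the initial
#' transient. Memory used for rate storage is bounded by
#' `buffer_capacity * N` samples regardless of duration.
#'
#' The initial state is deterministic (S_E = S_I = 0.001, hemodynamics at
#' rest); all randomness enters through the seeded noise stream, so two runs
#' with the same seed are bit-identical. Gating is clamped to [0, 1] after
#' every stochastic step.
#'
#' @param con a [connectome()].
#' @param coupling a [coupling_config()] with `J` of length N.
#' @param config an [integration_config()].
#' @param params a [dmf_parameters()].
#' @param hemo a [hemodynamic_parameters()].
#'
#' @return An object of class `dmf_sim`: list with `bold` (N x T matrix,
#'   T = floor((duration - transient_discard)/TR)), `rate_mean`, `rate_std`,
#'   `se_mean`, `cov_se_re` (per-region post-transient summaries of the
#'   excitatory pool), `max_live_samples` (peak number of rate samples alive
#'   in the buffer), `config`, and `seed`.
#'
#' @section Errors: a non-finite neural state raises a condition of class
#'   `dmf_divergence_error` reporting the step and the largest rate seen;
#'   nonpositive hemodynamic state raises `dmf_hemo_error`.
#'
#' @examples
#' con <- connectome(matrix(0, 1, 1))
#' cfg <- integration_config(duration = 12, transient_discard = 2, seed = 1)
#' sim <- run_simulation(con, coupling_config(G = 0, J = 1), cfg)
#' sim$rate_mean
#' @export
run_simulation <- function(con, coupling, config,
                           params = dmf_parameters(),
                           hemo = hemodynamic_parameters()) {
  stopifnot(inherits(con, "dmf_connectome"),
            inherits(coupling, "dmf_coupling"),
            inherits(config, "dmf_integration_config"))
  n <- nrow(con$weights)
  if (length(coupling$J) != n)
    stop("coupling$J must have one entry per region")
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- dmf_engine(con$weights, coupling$J, coupling$G,
                    unclass(params), unclass(hemo),
                    config$dt_dmf, config$dt_bk, config$duration,
                    config$transient_discard, config$TR,
                    config$buffer_capacity, FALSE)
  .check_divergence(out)
  rownames(out$bold) <- con$labels
  structure(list(bold = out$bold,
                 rate_mean = stats::setNames(out$rate_mean, con$labels),
                 rate_std = stats::setNames(out$rate_std, con$labels),
                 se_mean = stats::setNames(out$se_mean, con$labels),
                 cov_se_re = stats::setNames(out$cov_se_re, con$labels),
                 max_live_samples = out$max_live_samples,
                 buffer_high_water = out$buffer_high_water,
                 config = config, seed = config$seed),
            class = "dmf_sim")
}

.check_divergence <- function(out) {
  if (isTRUE(out$diverged))
    stop(structure(class = c("dmf_divergence_error", "error", "condition"),
                   list(message = sprintf(
                     "neural state diverged at step %d (max rate %.3g Hz)",
                     out$diverge_step, out$diverge_max_rate),
                     call = NULL, step = out$diverge_step,
                     max_rate = out$diverge_max_rate)))
  if (isTRUE(out$hemo_diverged))
    stop(structure(class = c("dmf_hemo_error", "error", "condition"),
                   list(message = sprintf(
                     "hemodynamic state became nonpositive at block %d",
                     out$hemo_block), call = NULL, block = out$hemo_block)))
  invisible(NULL)
}

#' Simulate excitatory firing-rate blocks
#'
#' Runs the neural integrator only and returns the stream of `dt_bk`
#' block-mean excitatory rates (materialized, so intended for short runs)
#' together with the post-transient rate summaries. The noise stream and the
#' state trajectory are identical to [run_simulation()] at the same seed.
#'
#' @inheritParams run_simulation
#' @return List with `rates` (N x n_blocks matrix, Hz, at `dt_bk`
#'   resolution), `rate_mean`, `rate_std`, `se_mean`, `cov_se_re`.
#' @export
simulate_rates <- function(con, coupling, config,
                           params = dmf_parameters(),
                           hemo = hemodynamic_parameters()) {
  stopifnot(inherits(con, "dmf_connectome"),
            inherits(config, "dmf_integration_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- dmf_engine(con$weights, coupling$J, coupling$G,
                    unclass(params), unclass(hemo),
                    config$dt_dmf, config$dt_bk, config$duration,
                    config$transient_discard, config$TR,
                    config$buffer_capacity, TRUE)
  .check_divergence(out)
  list(rates = out$rates, rate_mean = out$rate_mean,
       rate_std = out$rate_std, se_mean = out$se_mean,
       cov_se_re = out$cov_se_re)
}

#' Balloon-Windkessel hemodynamic integration (reference path)
#'
#' Integrates the hemodynamic ODEs over a materialized stream of block-mean
#' excitatory rates and emits BOLD at TR. This is the in-R consumer used to
#' verify the streaming C++ pipeline: for the same rate stream both produce
#' identical BOLD.
#'
#' The system per region (vasodilatory signal s, inflow f, volume v,
#' deoxyhemoglobin q; initial state s = 0, f = v = q = 1):
#' \deqn{ds/dt = 0.5 r^E + 3 - \kappa s - \gamma_{BW}(f - 1), \quad df/dt = s}
#' \deqn{\tau_{BW} dv/dt = f - v^{1/\alpha_{BW}}}
#' \deqn{\tau_{BW} dq/dt = f (1-(1-\rho)^{1/f})/\rho - q v^{1/\alpha_{BW}}/v}
#' \deqn{B = V_0 (k_1 (1-q) + k_2 (1-q/v) + k_3 (1-v))}
#'
#' @param rates N x n_blocks matrix of block-mean excitatory rates at
#'   `config$dt_bk` resolution, Hz.
#' @param config an [integration_config()] (duration must equal
#'   `n_blocks * dt_bk`).
#' @param hemo a [hemodynamic_parameters()].
#' @param return_state also return the final hemodynamic state (for
#'   steady-state checks).
#' @return N x T BOLD matrix, T = floor((duration - transient_discard)/TR);
#'   with `return_state = TRUE`, a list with `bold` and `state` (vectors `s`,
#'   `f`, `v`, `q`).
#' @export
balloon_windkessel <- function(rates, config,
                               hemo = hemodynamic_parameters(),
                               return_state = FALSE) {
  rates <- as.matrix(rates)
  n <- nrow(rates)
  n_blocks <- ncol(rates)
  h <- hemo
  dt <- config$dt_bk
  bk_per_tr <- round(config$TR / dt)
  blk_disc <- round(config$transient_discard / dt)
  T_out <- floor((config$duration - config$transient_discard) / config$TR)
  s <- numeric(n); f <- rep(1, n); v <- rep(1, n); q <- rep(1, n)
  bold <- matrix(0, n, T_out)
  col <- 0L
  inv_a <- 1 / h$alpha_BW
  for (b in seq_len(n_blocks)) {
    r <- rates[, b]
    ds <- 0.5 * r + 3 - h$kappa * s - h$gamma_BW * (f - 1)
    vout <- v^inv_a
    dv <- (f - vout) / h$tau_BW
    ef <- 1 - (1 - h$rho)^(1 / f)
    dq <- (f * ef / h$rho - q * vout / v) / h$tau_BW
    s <- s + dt * ds
    f <- f + dt * s
    v <- v + dt * dv
    q <- q + dt * dq
    if (any(f <= 0 | v <= 0 | q <= 0 |
              !is.finite(f) | !is.finite(v) | !is.finite(q)))
      stop(structure(class = c("dmf_hemo_error", "error", "condition"),
                     list(message = sprintf(
                       "hemodynamic state became nonpositive at block %d", b),
                       call = NULL, block = b)))
    if (b > blk_disc && (b - blk_disc) %% bk_per_tr == 0 && col < T_out) {
      col <- col + 1L
      bold[, col] <- h$V0 * (h$k1 * (1 - q) + h$k2 * (1 - q / v) +
                               h$k3 * (1 - v))
    }
  }
  if (return_state) list(bold = bold, state = list(s = s, f = f, v = v, q = q))
  else bold
}

# Pure-R Euler-Maruyama reference integrator: materializes the full state
# trajectory and block-mean rates. Slow; used only to cross-check the C++
# engine on short runs (identical noise ordering: E draws then I draws).
dmf_reference_rates <- function(con, coupling, config,
                                params = dmf_parameters()) {
  p <- params
  w <- con$weights
  n <- nrow(w)
  dt <- config$dt_dmf
  n_steps <- round(config$duration / dt)
  n_sub <- round(config$dt_bk / dt)
  n_blocks <- n_steps %/% n_sub
  if (!is.null(config$seed)) set.seed(config$seed)
  SE <- rep(0.001, n); SI <- rep(0.001, n)
  sq <- p$sigma * sqrt(dt * 1000)  # sigma per sqrt(ms); see run_simulation()
  GJ <- coupling$G * p$J_NMDA
  rates <- matrix(0, n, n_blocks)
  blk <- numeric(n); ib <- 0L; bi <- 0L
  for (step in seq_len(n_steps) - 1L) {
    IE <- p$W_E * p$I0 + p$w_plus * p$J_NMDA * SE +
      GJ * as.numeric(w %*% SE) - coupling$J * SI
    II <- p$W_I * p$I0 + p$J_NMDA * SE - SI
    rE <- excitatory_rate(IE, p)
    rI <- inhibitory_rate(II, p)
    blk <- blk + rE
    dSE <- -SE / p$tau_NMDA + (1 - SE) * p$gamma_kin * rE
    dSI <- -SI / p$tau_GABA + rI
    SE <- pmin(pmax(SE + dSE * dt + sq * rnorm(n), 0), 1)
    SI <- pmin(pmax(SI + dSI * dt + sq * rnorm(n), 0), 1)
    ib <- ib + 1L
    if (ib == n_sub) {
      bi <- bi + 1L
      rates[, bi] <- blk / n_sub
      blk <- numeric(n); ib <- 0L
    }
  }
  rates
}

#' @export
print.dmf_sim <- function(x, ...) {
  cat("DMF simulation:", nrow(x$bold), "regions x", ncol(x$bold),
      "BOLD samples (TR", x$config$TR, "s)\n")
  cat("  mean excitatory rate:",
      sprintf("%.2f", mean(x$rate_mean)), "Hz (range",
      sprintf("%.2f-%.2f", min(x$rate_mean), max(x$rate_mean)), "Hz)\n")
  invisible(x)
}
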