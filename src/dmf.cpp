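// Euler-Maruyama integrator for the two-population dynamic mean-field model
// with a bounded-memory producer-consumer hand-off to the Balloon-Windkessel
// hemodynamic integrator.
//
// Producer: the DMF SDE advances at dt; every dt_bk/dt steps the mean
// excitatory rate of the block is pushed into a fixed-capacity buffer.
// Consumer: the Balloon-Windkessel ODEs advance one dt_bk step per block and
// emit a BOLD column every TR. The buffer is drained whenever it fills, so
// the number of rate samples alive at any instant is bounded by
// buffer_capacity * N regardless of simulated duration.
//
// Noise: one standard-normal draw per region for the excitatory pool, then
// one per region for the inhibitory pool, every step, via R's norm_rand();
// identical ordering is used by the pure-R reference integrator.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// F-I transfer with removable singularity at current == threshold:
// r = x / (1 - exp(-d x)) with x = g (I - Ithr); near x = 0 use the
// first-order expansion r = 1/d + x/2.
static inline double transfer(double I, double g, double thr, double d) {
  double x = g * (I - thr);
  double dx = d * x;
  if (std::fabs(dx) < 1e-6) return 1.0 / d + 0.5 * x;
  return x / (1.0 - std::exp(-dx));
}

// [[Rcpp::export]]
List dmf_engine(NumericMatrix C, NumericVector J, double G,
                List pars, List hpars,
                double dt, double dt_bk, double duration, double discard,
                double TR, int buffer_capacity, bool keep_rates) {
  const int N = C.nrow();

  // DMF parameters (internal units: s, Hz, nA)
  const double I0    = pars["I0"];
  const double W_E   = pars["W_E"];
  const double W_I   = pars["W_I"];
  const double wplus = pars["w_plus"];
  const double JN    = pars["J_NMDA"];
  const double gE    = pars["gE"],    gI    = pars["gI"];
  const double thrE  = pars["IthrE"], thrI  = pars["IthrI"];
  const double dE    = pars["dE"],    dI    = pars["dI"];
  const double gam   = pars["gamma_kin"];
  const double sigma = pars["sigma"];
  const double tauN  = pars["tau_NMDA"], tauG = pars["tau_GABA"];

  // Balloon-Windkessel parameters
  const double kappa = hpars["kappa"];
  const double gBW   = hpars["gamma_BW"];
  const double tBW   = hpars["tau_BW"];
  const double aBW   = hpars["alpha_BW"];
  const double rho   = hpars["rho"];
  const double V0    = hpars["V0"];
  const double k1    = hpars["k1"], k2 = hpars["k2"], k3 = hpars["k3"];
  const double inv_a = 1.0 / aBW;

  const int n_steps   = (int) std::lround(duration / dt);
  const int n_sub     = (int) std::lround(dt_bk / dt);      // DMF steps per BK block
  const int n_blocks  = n_steps / n_sub;
  const int bk_per_tr = (int) std::lround(TR / dt_bk);
  const int blk_disc  = (int) std::lround(discard / dt_bk); // BK blocks discarded
  const int T_out     = (int) std::floor((duration - discard) / TR);
  // sigma is the diffusion amplitude per sqrt(millisecond) — the convention
  // of the standard numerical implementations of this model, under which the
  // uncoupled region reproduces its documented 3.4 Hz / E[S_E]=0.179 state.
  const double sqdt   = sigma * std::sqrt(dt * 1000.0);

  // state
  std::vector<double> SE(N, 0.001), SI(N, 0.001);
  std::vector<double> dSE(N), dSI(N), rE(N), coup(N);
  // BK state (rest)
  std::vector<double> hs(N, 0.0), hf(N, 1.0), hv(N, 1.0), hq(N, 1.0);

  // post-transient accumulators (per DMF step)
  std::vector<double> s_r(N, 0.0), s_r2(N, 0.0), s_S(N, 0.0), s_Sr(N, 0.0);
  long n_acc = 0;

  // rate-block buffer (N x buffer_capacity), drained when full
  if (buffer_capacity < 1) stop("buffer_capacity must be >= 1");
  std::vector<double> buf((size_t) N * buffer_capacity);
  int buf_fill = 0, buf_high = 0;
  int blocks_done = 0;     // BK blocks consumed so far
  int out_col = 0;

  NumericMatrix bold(N, T_out);
  NumericMatrix rates_out = keep_rates ? NumericMatrix(N, n_blocks)
                                       : NumericMatrix(0, 0);

  const double GJ = G * JN;
  bool diverged = false; int div_step = -1; double div_maxrate = NA_REAL;
  bool hemo_bad = false; int hemo_block = -1;

  std::vector<double> blk(N, 0.0); // running block sum of rE
  int in_blk = 0;

  RNGScope rng;

  for (int step = 0; step < n_steps && !diverged; ++step) {
    const double t = step * dt;

    // coupling term: G * J_NMDA * C %*% SE
    for (int n = 0; n < N; ++n) {
      double acc = 0.0;
      for (int p = 0; p < N; ++p) acc += C(n, p) * SE[p];
      coup[n] = GJ * acc;
    }

    const bool post = (t >= discard);
    double maxr = 0.0;
    for (int n = 0; n < N; ++n) {
      const double IE = W_E * I0 + wplus * JN * SE[n] + coup[n] - J[n] * SI[n];
      const double II = W_I * I0 + JN * SE[n] - SI[n];
      const double re = transfer(IE, gE, thrE, dE);
      const double ri = transfer(II, gI, thrI, dI);
      if (!std::isfinite(re) || !std::isfinite(SE[n])) {
        diverged = true; div_step = step;
      }
      if (re > maxr) maxr = re;
      if (post) {
        s_r[n] += re; s_r2[n] += re * re;
        s_S[n] += SE[n]; s_Sr[n] += SE[n] * re;
      }
      blk[n] += re;
      rE[n] = re;
      dSE[n] = -SE[n] / tauN + (1.0 - SE[n]) * gam * re;
      dSI[n] = -SI[n] / tauG + ri;
    }
    if (diverged) { div_maxrate = maxr; break; }
    if (post) ++n_acc;

    // Euler-Maruyama update; E-pool draws first, then I-pool
    for (int n = 0; n < N; ++n) {
      SE[n] += dSE[n] * dt + sqdt * norm_rand();
      if (SE[n] < 0.0) SE[n] = 0.0; else if (SE[n] > 1.0) SE[n] = 1.0;
    }
    for (int n = 0; n < N; ++n) {
      SI[n] += dSI[n] * dt + sqdt * norm_rand();
      if (SI[n] < 0.0) SI[n] = 0.0; else if (SI[n] > 1.0) SI[n] = 1.0;
    }

    // block boundary: push mean rate into buffer
    if (++in_blk == n_sub) {
      double *dst = &buf[(size_t) N * buf_fill];
      for (int n = 0; n < N; ++n) { dst[n] = blk[n] / n_sub; blk[n] = 0.0; }
      in_blk = 0;
      if (keep_rates) {
        for (int n = 0; n < N; ++n) rates_out(n, blocks_done + buf_fill) = dst[n];
      }
      ++buf_fill;
      if (buf_fill > buf_high) buf_high = buf_fill;

      if (buf_fill == buffer_capacity) {
        // drain: consumer integrates BK over the buffered blocks
        for (int b = 0; b < buf_fill && !hemo_bad; ++b) {
          const double *r = &buf[(size_t) N * b];
          for (int n = 0; n < N; ++n) {
            const double ds = 0.5 * r[n] + 3.0 - kappa * hs[n] - gBW * (hf[n] - 1.0);
            const double vout = std::pow(hv[n], inv_a);
            const double dv = (hf[n] - vout) / tBW;
            const double ef = 1.0 - std::pow(1.0 - rho, 1.0 / hf[n]);
            const double dq = (hf[n] * ef / rho - hq[n] * vout / hv[n]) / tBW;
            hs[n] += dt_bk * ds;
            hf[n] += dt_bk * hs[n];
            hv[n] += dt_bk * dv;
            hq[n] += dt_bk * dq;
            if (hf[n] <= 0.0 || hv[n] <= 0.0 || hq[n] <= 0.0 ||
                !std::isfinite(hf[n]) || !std::isfinite(hv[n]) || !std::isfinite(hq[n])) {
              hemo_bad = true; hemo_block = blocks_done + b;
            }
          }
          const int blk_idx = blocks_done + b + 1; // blocks completed (time blk_idx*dt_bk)
          if (blk_idx > blk_disc && (blk_idx - blk_disc) % bk_per_tr == 0 &&
              out_col < T_out) {
            for (int n = 0; n < N; ++n)
              bold(n, out_col) = V0 * (k1 * (1.0 - hq[n]) +
                                       k2 * (1.0 - hq[n] / hv[n]) +
                                       k3 * (1.0 - hv[n]));
            ++out_col;
          }
        }
        blocks_done += buf_fill;
        buf_fill = 0;
        if (hemo_bad) break;
      }
    }
    if (step % 50000 == 0) Rcpp::checkUserInterrupt();
  }

  // final partial drain
  if (!diverged && !hemo_bad && buf_fill > 0) {
    for (int b = 0; b < buf_fill && !hemo_bad; ++b) {
      const double *r = &buf[(size_t) N * b];
      for (int n = 0; n < N; ++n) {
        const double ds = 0.5 * r[n] + 3.0 - kappa * hs[n] - gBW * (hf[n] - 1.0);
        const double vout = std::pow(hv[n], inv_a);
        const double dv = (hf[n] - vout) / tBW;
        const double ef = 1.0 - std::pow(1.0 - rho, 1.0 / hf[n]);
        const double dq = (hf[n] * ef / rho - hq[n] * vout / hv[n]) / tBW;
        hs[n] += dt_bk * ds;
        hf[n] += dt_bk * hs[n];
        hv[n] += dt_bk * dv;
        hq[n] += dt_bk * dq;
        if (hf[n] <= 0.0 || hv[n] <= 0.0 || hq[n] <= 0.0 ||
                !std::isfinite(hf[n]) || !std::isfinite(hv[n]) || !std::isfinite(hq[n])) {
          hemo_bad = true; hemo_block = blocks_done + b;
        }
      }
      const int blk_idx = blocks_done + b + 1;
      if (blk_idx > blk_disc && (blk_idx - blk_disc) % bk_per_tr == 0 &&
          out_col < T_out) {
        for (int n = 0; n < N; ++n)
          bold(n, out_col) = V0 * (k1 * (1.0 - hq[n]) +
                                   k2 * (1.0 - hq[n] / hv[n]) +
                                   k3 * (1.0 - hv[n]));
        ++out_col;
      }
    }
    blocks_done += buf_fill;
  }

  NumericVector rate_mean(N), rate_std(N), se_mean(N), cov_se_re(N);
  for (int n = 0; n < N; ++n) {
    if (n_acc > 1) {
      const double mr = s_r[n] / n_acc, mS = s_S[n] / n_acc;
      rate_mean[n] = mr;
      rate_std[n]  = std::sqrt(std::max(0.0, s_r2[n] / n_acc - mr * mr));
      se_mean[n]   = mS;
      cov_se_re[n] = s_Sr[n] / n_acc - mS * mr;
    } else {
      rate_mean[n] = rate_std[n] = se_mean[n] = cov_se_re[n] = NA_REAL;
    }
  }

  return List::create(
    _["bold"] = bold,
    _["rate_mean"] = rate_mean,
    _["rate_std"] = rate_std,
    _["se_mean"] = se_mean,
    _["cov_se_re"] = cov_se_re,
    _["rates"] = rates_out,
    _["n_out"] = out_col,
    _["buffer_high_water"] = buf_high,
    _["max_live_samples"] = (double) buf_high * N,
    _["diverged"] = diverged,
    _["diverge_step"] = div_step,
    _["diverge_max_rate"] = div_maxrate,
    _["hemo_diverged"] = hemo_bad,
    _["hemo_block"] = hemo_block);
}
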