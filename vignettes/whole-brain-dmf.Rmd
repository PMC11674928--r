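---
title: "Whole-brain dynamic mean-field modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain dynamic mean-field modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmfsim)
```

## The model

`dmfsim` simulates whole-brain resting-state activity with the two-population
dynamic mean-field (DMF) neural mass model. Each brain region `n` of a
parcellation is reduced to an excitatory (E, NMDA-mediated) and an inhibitory
(I, GABA-A-mediated) population described by a synaptic gating variable
`S` in [0, 1], an input current `I` (nA), and a population firing rate
`r` (Hz). Regions interact only through their excitatory pools, weighted by a
structural connectome `C` and scaled by the global coupling `G`:

    I_E[n] = W_E I0 + w+ J_NMDA S_E[n] + G J_NMDA sum_p C[n,p] S_E[p] - J[n] S_I[n]
    I_I[n] = W_I I0 + J_NMDA S_E[n] - S_I[n]
    r_E[n] = F_E(I_E[n]),  r_I[n] = F_I(I_I[n])
    dS_E[n]/dt = -S_E[n]/tau_NMDA + (1 - S_E[n]) gamma r_E[n] + sigma v[n]
    dS_I[n]/dt = -S_I[n]/tau_GABA + r_I[n] + sigma v[n]

`F(I) = g(I - Ithr) / (1 - exp(-d g (I - Ithr)))` is the population F-I
curve; its singularity at threshold is removable (the limit is `1/d`) and the
implementation switches to the first-order expansion for `|d g (I - Ithr)| <
1e-6`, making the curve numerically C1 across threshold. All constants live
in `dmf_parameters()` with the standard values (e.g. `I0 = 0.382` nA,
`tau_NMDA = 100` ms, `tau_GABA = 10` ms); the internal unit system is
seconds/Hz/nA, with millisecond time constants converted once at
construction.

`J[n]` is the feedback inhibition control (FIC): the inhibitory-to-excitatory
weight of region `n`, tuned so that excitatory rates stay near the
physiological working point of ~3.4 Hz as `G` grows.

Excitatory rates drive the Balloon-Windkessel hemodynamic model
(`hemodynamic_parameters()`): a vasodilatory signal with decay `kappa` and
autoregulatory feedback `gamma_BW` drives blood inflow, which moves venous
volume `v` and deoxyhemoglobin `q`; BOLD is the standard three-term read-out
`B = V0 (k1 (1-q) + k2 (1-q/v) + k3 (1-v))`. The volume equation
`tau_BW dv/dt = f - v^(1/alpha_BW)` is the standard Windkessel form (the
deoxyhemoglobin equation alone does not determine the volume dynamics, which
must evolve for `v` to appear in the read-out). Hemodynamic constants follow
the classical hemodynamic-model literature (`kappa = 0.65 /s`,
`gamma_BW = 0.41 /s`, `tau_BW = 0.98 s`, `alpha_BW = 0.32`, `rho = 0.34`,
`V0 = 0.02`, `k1 = 2.77264`, `k2 = 0.572`, `k3 = -0.43`) and are all
overridable.

## Numerical scheme and the noise convention

The gating SDEs are integrated with Euler-Maruyama at `dt_dmf = 0.1` ms; the
hemodynamic ODEs advance at `dt_bk = 1` ms consuming the mean excitatory rate
of each 1 ms block; BOLD is sampled every `TR = 2` s and the first 10 s are
discarded. The initial state is deterministic (`S_E = S_I = 0.001`,
hemodynamics at rest), so the seed of the noise stream fully determines a
simulation; noise draws are ordered (per step: one standard normal per region
for the E pool, then one per region for the I pool), which keeps runs
bit-reproducible and lets a pure-R reference integrator replay the exact
stream. Gating is clamped to [0, 1] after every stochastic step.

One numerical decision deserves emphasis. The noise amplitude `sigma = 0.01`
nA is, throughout the standard numerical implementations of this model,
applied with time measured in milliseconds, so the Euler-Maruyama increment
is `sigma * sqrt(dt / 1 ms)`. Read naively in SI units the same constant
would produce 31.6 times less noise — and a qualitatively different model:
the uncoupled region would sit at its deterministic fixed point of 3.14 Hz
with `E[S_E] = 0.167` and a gating-rate covariance of 1e-4. Under the
millisecond convention the uncoupled region fluctuates around 3.4 Hz with
`E[S_E] = 0.179` and covariance just below 0.1 — the documented working
point of the model. `dmfsim` therefore interprets `sigma` per square-root
millisecond (see `?dmf_parameters`).

### Bounded-memory producer-consumer integration

Firing rates are produced 1,000 times faster than BOLD is consumed. The C++
integrator therefore streams block-mean rates through a fixed-capacity
buffer (default 10,000 blocks per region) that is drained by the
hemodynamic consumer whenever it fills. The number of rate samples alive at
any instant is bounded by `buffer_capacity * N` regardless of simulated
duration; `run_simulation()` reports the instrumented high-water mark
(`max_live_samples`) so the contract is testable. For short runs the
materializing path (`simulate_rates()` + `balloon_windkessel()`) reproduces
the streamed BOLD exactly at the same seed.

## Feedback inhibition control

Two calibrators are provided.

**Closed form.** At the uncoupled working point the stationary gating
equation, under the factorization `E[S r] = E[S] E[r]` (justified by the
measured covariance < 0.1), gives
`E[S_E] = gamma tau E[r_E] / (1 + gamma tau E[r_E]) = 0.179` at 3.4 Hz.
Inverting the excitatory F-I curve and solving the scalar inhibitory fixed
point (both by bracketed root finding to 1e-10, chosen over damped fixed-point
iteration for determinism) yields the moments from which

    alpha = J_NMDA E[S_E] / E[S_I]          = 0.67
    c     = (W_E I0 + w+ J_NMDA E[S_E] - E[I_E]) / E[S_I] = 0.97

and the linear rule `J[n] = alpha G beta[n] + c` with `beta` the node
strength. `c` is conventionally rounded to 1 so uncoupled regions get
exactly `J = 1`. Node strength defaults to the literal row sum; the
halved convention (each symmetric link counted once) is available as
`node_strength(con, halve = TRUE)` and only rescales `alpha` by 2.

**Iterative.** The classical calibrator nudges each region's `J` by
`eta * (mean rate - target)` after a short probe simulation (defaults:
`eta = 0.05` per Hz, 20 s probes with 2 s discard, tolerance 0.2 Hz, rate
errors clipped at +/-10 Hz, `J` floored at 0, start from the uncoupled value
`J = 1` so any strength dependence emerges from the calibration itself).
These constants are this package's concrete scheme; the update direction and
convergence criterion are the classical ones. Non-convergence is reported,
not thrown. `fit_alpha()` then regresses the pooled region-level points
`(G beta[n], J[n] - 1)` through the origin (the slope must vanish at
`G = 0`), optionally giving 10x weight to points with `G > 2.1`, near the
bifurcation. A second-order refinement of the closed form is deliberately not
implemented: its stability range is narrower than the first-order rule's.

## Observables and model fitting

BOLD (simulated and "empirical" alike — the pipeline is symmetric) is
band-passed at 0.01-0.1 Hz with a zero-phase order-2 Butterworth filter
(odd-reflection padding at each end, sized to absorb the transient of the
slow 0.01 Hz corner). FC is the
Pearson matrix across regions; FCD correlates the vectorized strict upper
triangles of window FCs over 30-sample windows advancing 2 samples (trailing
partial window dropped). The fitting objective is the two-sample
Kolmogorov-Smirnov statistic between pooled FCD value samples. The K-S is
computed on the raw pooled samples — the bin-free reading of comparing FCD
histograms; a binned variant is available (`ks_distance(method =
"binned")`).

`bayes_optimize()` minimizes the stochastic K-S objective over
`G in [0, 3]`, `alpha in [0.6, 0.9]` (a box spanning the stability analysis
range and bracketing the analytic 0.67 and regressed 0.725-0.75 values)
with a Gaussian-process surrogate: Matern-5/2 kernel with a fitted
observation-noise term (hyperparameters by L-BFGS on the marginal
likelihood from three starts), expected-improvement acquisition maximized
over 4,096 random candidates plus an L-BFGS polish. The initial design is a
seeded Latin hypercube (default 10 points); each objective evaluation runs
one fresh-seed 500 s simulation. The evaluation budget is fixed in advance
(no adaptive stopping). For a stochastic objective the best *observed* value
chases lucky draws, so the trace also reports the argmin of the final
surrogate posterior mean (`best_estimated`) together with a spatially
thinned shortlist of ranked posterior-mean minima (`candidates`) —
preferring the estimated over the observed minimum, as is standard when the
objective is noisy.

The pooled-FCD K-S objective has a nearly flat valley trading `G` against
`alpha` (stronger coupling compensated by stronger inhibition changes the
FCD distribution very little): at desk scale the mean objective differs by
less than its seed-to-seed spread along `(1.6, 0.75) - (1.85, 0.78)`. The
unconstrained argmin inside such a valley is essentially arbitrary, but the
upper-`G` end of the valley violates the physiological firing-rate range
that joint fitting is expected to satisfy. `recover_parameters()` therefore
selects the reported optimum under that constraint: it walks the ranked
surrogate minima and reports the first whose fresh verification simulation
keeps all regions within 3-4 Hz (falling back to the unconstrained minimum
if none does). This is constrained model fitting with physiological
plausibility as the feasibility criterion — the same criterion that
motivates inhibition control in the first place.

## Turbulence-like dynamics

Instantaneous phases come from the analytic signal (FFT half-spectrum
doubling) of the band-passed BOLD; 5 samples at each end of the phase series
are dropped against Hilbert edge artifacts. The local Kuramoto order
parameter averages unit phasors under the exponential spatial kernel
`K[n,q] = exp(-lambda r(n,q))` with `lambda = 0.18 /mm` (self-term included,
the literal kernel value at distance 0); the turbulence level `D` is the
population standard deviation of the modulus pooled over regions and time.
Phases use the same 0.01-0.1 Hz band as the rest of the pipeline (some
turbulence work uses 0.008-0.08 Hz; the band is configurable).

`turbulence_grid()` scans a `(G, alpha)` grid, simulating each cell with
*common random numbers*: repetition `k` of every cell uses seed `seed + k`.
With a stochastic `D` whose cell-to-cell differences are comparable to its
seed-to-seed spread at desk scale, common random numbers make the comparison
across cells far more stable, and a reference generated at a grid point with
the same base seed is recovered exactly. With independent seeds, recovery at
the problem sizes used here is accurate to about one grid step in `G` and
only weakly identified in `alpha` — a genuine flatness of the turbulence
landscape at small `N`, not a failure of the grid machinery.

## Synthetic study conditions

All tests and experiments run on generated data; nothing is downloaded.

* **Connectomes** (`make_connectome()`): regions on a sphere, weights
  `exp(-distance/40 mm)` on a random mask (density 0.35), mimicking the
  distance dependence of empirical connectomes; redrawn until connected;
  rescaled to a target mean strength. The test fixtures use mean strength
  0.5, which places the linear-FIC hyperexcitation bifurcation near
  `G ~ 2` (alpha = 0.725) and `G ~ 2.5` (alpha = 0.75) — the working range
  of the empirically normalized connectomes this model is used with. On
  these fixtures the regressed alpha comes out near 0.74, bracketed by the
  published 0.725-0.75 estimates.
* **Coordinates**: the coarse 20-node fixture lives on a 70 mm sphere
  (realistic centroid scale); the 32-node turbulence fixture on a 20 mm
  sphere so that inter-node spacing (~7.5 mm) is comparable to the
  `1/lambda = 5.6` mm kernel range, as it is in the fine parcellations where
  turbulence measures are defined.
* **Cohorts** (`make_surrogate_cohort()`): 13 independent 500 s simulations
  (245 volumes at TR = 2 s) at known `(G*, alpha*) = (1.6, 0.75)` —
  model-generated rather than Gaussian surrogates so that fitting has a
  well-defined ground truth.

What passing these experiments shows — and does not show. The generator
reproduces the *dynamical* regime of the model (bistability, FIC control,
FCD switching) but not empirical tractography biases, subcortical asymmetries,
measurement noise, or head-motion artifacts; recovery of `(G*, alpha*)` on
synthetic cohorts demonstrates internal consistency of the fitting stack, not
goodness of fit to any real cohort. Problem sizes (20-32 regions, 500 s
simulations, 40 optimization evaluations, single-seed turbulence grids) were
chosen as the smallest at which each phenomenon is clearly expressed.

## Degenerate inputs and failure modes

Non-finite neural state raises a typed `dmf_divergence_error` (with step and
peak rate); nonpositive or non-finite hemodynamic state raises
`dmf_hemo_error`. The fitting objective converts divergence into the
worst-case value 1.0 (flagged) so optimization can continue. Zero-variance
regions make FC entries `NA` with a warning, never a silent 0. Note that with
gating clamped to [0, 1] the neural state itself rarely becomes non-finite:
the hyperexcitation regime manifests as mean rates far above 4 Hz, which is
why the stability checks test `rate > 4 Hz or divergence`.

## Known limitations

* The closed-form FIC is first order in the fluctuations; its accuracy
  degrades as `G` approaches the bifurcation, where the nonlinearity of the
  F-I curve matters most.
* At 20-32 regions the FCD pool is small and the K-S objective has a
  seed-to-seed spread of roughly 0.05-0.15 near the optimum; `alpha` is only
  weakly identified on the high side (stronger inhibition paired with the
  same coupling changes the FCD little until instability).
* The hemodynamic constants are fixed defaults, not fitted; BOLD units are
  arbitrary (the pipeline only uses correlations).
* No plastic/time-varying FIC, no phase-based FCD variants, no
  volume-format neuroimaging I/O.
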