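---
title: "Methods: models, estimators and the experiment simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and the experiment simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazefit)
```

## Scope

grazefit covers the complete workflow of numerical-response (NR) and
functional-response (FR) experiments with phagotrophic aquatic protists:
design arithmetic for the dilution series, per-well rate estimation from
cell counts, nonlinear model fitting with small-sample AICc selection,
FR-type discrimination, gross-growth-efficiency consistency checks, and a
simulator that generates whole experiments with realistic noise so every
stage can be validated by parameter recovery. The package deliberately does
*not* implement depletion-corrected instantaneous fitting (Rogers/Lambert
random-predator equations), multispecies responses, bacterial-background
corrections, or temperature-response surfaces.

## The response models

The NR is the threshold saturating model
$$r(P) = r_{max}\,\frac{P - P'}{k_2 + (P - P')}$$
with `rmax` (d⁻¹) the maximum growth rate, `P′` the threshold prey density
where growth is zero (the x-intercept), and `k2` a half-saturation-like
constant on the same axis as `P`. Below the threshold the same expression
continues into negative growth — starvation mortality — and the model is
singular where the denominator crosses zero, which `nr_predict()` rejects.

The FR is the generalized Holling disk equation
$$I(P) = \frac{a P^{\theta}}{1 + a h P^{\theta}}$$
with `a` the space clearance rate (the volume a predator effectively
searches per day; for θ = 1 it is the curve's initial slope), `h` the
handling time in days per prey item (`Imax = 1/h`), and `θ` the Hill
exponent: θ = 1 gives the type II hyperbola, θ = 2 the classical type III
sigmoid, and h = 0 with θ = 1 the linear type I regime. Any θ ≥ 1 is
allowed; type IV (declining ingestion at very high prey) is excluded. The
Michaelis–Menten form `I = Imax·P/(k + P)` is an exact reparameterization
of θ = 1 (`Imax = 1/h`, `k = 1/(ah)`); `fit_fr_mm()` exists so the
equivalence can be verified on data, and the test suite asserts identical
fitted curves and AICc from both forms.

The clearance curve `C(P) = I(P)/P` is the type diagnostic: monotone
decreasing from `a` for θ = 1, unimodal with an interior maximum for θ > 1.
Because `C` equals the proportion of the 1-mL reference volume cleared per
day, plotting the proportion of prey ingested against density and fitting
an OLS quadratic (`discriminate_fr_type()`) separates the types: a
significantly positive linear and significantly negative quadratic term is
the type III signature; a significantly negative linear term with a
non-negative quadratic is type II; anything else is inconclusive. This
diagnostic is the designated tie-break when AICc ranking is within ΔAICc <
2 of indifference.

## From counts to rates

Per-well estimators follow the classical bottle-incubation chain:

* `r = ln(Nt/N0)/t` — exponential change assumed throughout; a zero count
  makes the rate undefined (an error distinct from negative growth, which
  is valid data).
* The logarithmic mean `(Xt − X0)/ln(Xt/X0)` is the time-averaged density
  under exponential change; it is the default "mean" prey axis, and also
  the default for the mean predator density `Rm` (the geometric mean
  `sqrt(R0·Rt)` is available; the difference is below 1% at realistic
  growth rates).
* `g = μ_ctrl − ln(Pt/P0)/t` — grazing against predator-free controls.
  With `μ_ctrl` from a single control's counts this is algebraically the
  classical two-bottle difference. Setting `μ_ctrl = 0` gives the
  *uncorrected* variant that ignores control dynamics. Negative `g`
  (controls declining faster than grazed wells) is biologically
  meaningless but diagnostically crucial, so it is flagged
  (`negative_grazing`), never clamped.
* Controls run at only every second prey level, so `assign_control_mu()`
  extrapolates μ to each well: binned means over log-density (default,
  2 bins), global mean, nearest control, or interpolation in log density.
  Every assignment carries provenance.
* `I = P·g/Rm`, `C = I/P`, `GGE = r·M/I_C` — with GGE computable on a
  carbon basis (allometric models) or a cell-volume basis; the two agree
  within 20% for the default carbon coefficients, and any GGE outside
  (0, 1) is flagged by the pipeline as an NR/FR inconsistency.

Carbon models are stored per organism because prey and predator use
different allometric coefficients (defaults: `0.261·V^0.860` for the
cryptophyte prey, `0.216·V^0.939` for the ciliate predator, pg C with V in
µm³). One printed-value subtlety: the worked threshold biomass
(0.036 mg C L⁻¹ at 1,349 cells mL⁻¹) reproduces exactly only via the
*rounded* per-cell value of 27 pg C; full precision (27.09 pg) gives
0.037. The tests use the printed value for that chain and document it.

## Fitting and model selection

`fit_nr()` and `fit_fr()` use Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with box constraints keeping all parameters in their
valid domains, started from a deterministic multi-start grid: for the FR,
handling-time starts at {0.3, 1, 3}/max(I) crossed with clearance-rate
starts at {0.1, 1, 10} × the median of `I/P^θ` (9 starts per θ; the
free-θ model adds a {1, 2, 3} θ grid). The converged fit with the lowest
RSS wins. Non-convergence from every start is an explicit error naming the
model and the number of starts.

AICc follows the convention of the standard AICc tooling:
`n·ln(RSS/n) + 2k + 2k(k+1)/(n−k−1)` with `k = n_params + 1` counting the
residual variance. A numerically perfect fit (RSS = 0, as in the noiseless
recovery tests) has no finite AICc and reports −Inf — it wins every
comparison. `rank_models()` labels every fit within ΔAICc < 2 of the best
as having "substantial" support and refuses to compare fits whose response
vectors differ (different transform, correction, density axis, or data):
log-scale and raw-scale likelihoods are simply not comparable.

The log-transform option fits least squares on ln I — the usual remedy for
ingestion-rate variance growing with prey density — and requires strictly
positive rates; it refuses anything else, which in practice restricts it
to the uncorrected dataset. In the untransformed objective, negative
ingestion values are retained: they carry the information about the
low-density regime.

`covariate_effects()` runs the two bias screens as ordinary linear models:
prey growth against the diluent (FLW) fraction, separately for controls
and experimental wells (a negative slope means dilution itself depresses
prey growth, breaking the control-transfer assumption), and ingestion
against FLW fraction plus mean predator density (a negative predator
coefficient indicates interference). Screens with constant covariates are
skipped with a notice rather than fitted degenerately.

## The experiment simulator

`simulate_experiment()` deliberately violates the constant-prey assumption
the disk equation makes: each well integrates
$$\frac{dP}{d\tau} = \mu P - f(P)\,(R/R_{ref})^{-w} R,
  \qquad \frac{dR}{d\tau} = r_{NR}(P)\,R$$
with `f` the true FR evaluated at the instantaneous prey density
(`deSolve::ode`, lsoda, rtol 1e-8 / atol 1e-10). Cumulative ingestion and
growth ride along as extra ODE states, so prey mass balance
(`P0 − Pt = ∫fR − ∫μP`) is checkable to 1e-6 relative, and the tests do
check it. The Hassell–Varley multiplier `(R/R_ref)^{-w}` is the minimal
one-parameter interference mechanism (off by default, `w = 0`); the lag
phase is a hard on/off switch during which both derivatives are zero.

Noise enters in the two places it enters real experiments:

* **Pipetting**: realized/target density ratios are log-normal with
  moments matched to 0.65 ± 0.21 (SD) for prey in experimental wells,
  0.72 ± 0.17 in controls, and 1.10 ± 0.12 for the predator — the observed
  noise structure of the motivating well-plate experiment. Log-normal
  because the ratio is strictly positive and right-skewed and only two
  moments are reported.
* **Counting**: raw counts are Poisson in the enumerated volume. Dense
  samples are not enumerated exhaustively: counting stops after
  `max_count_prey` cells (default 400, a realistic chamber workload), with
  the effective counted volume shrinking accordingly, so high-density
  counts keep a few-percent relative error instead of becoming arbitrarily
  precise. This cap matters: without it, simulated experiments are far
  cleaner than real ones and near-indistinguishable FR variants (θ = 1 vs
  θ = 1.2) separate much more sharply than they should. Predator counts
  (low densities, whole 3-mL sediment chamber) are never capped.

Prey intrinsic growth is `μ = μ0 + β_FLW·flw + ε`, `ε ~ N(0, σ_μ)`. The
defaults (`μ0 = 0`, `β_FLW = −0.3` d⁻¹ per unit diluent fraction,
`σ_μ = 0.05` d⁻¹) are a synthetic choice — no quantitative diluent effect
is available, only its significance — selected once to reproduce the
qualitative pathology of interest: in the bundled `demo_plan()` the
controls are inoculated from predator-free culture and therefore receive
systematically more diluent (FLW fractions ≈ 0.87–0.99 vs 0.62–0.74), so
controls decline faster than grazed wells and corrected grazing rates go
negative at low prey density — exactly the failure mode the per-well flags
and the uncorrected variant exist for.

The true NR/FR defaults (`rmax` 0.32 d⁻¹, threshold 1,349 cells mL⁻¹,
θ = 3, `Imax` 667 prey d⁻¹, half-saturation 2×10⁴ cells mL⁻¹) are the
magnitudes of the motivating ciliate–cryptophyte system; `k2` (8,000
cells mL⁻¹) is a plausible synthetic value, since no fitted estimate of it
exists to anchor on.

What the simulator does *not* emulate: individual-level variation in
feeding and growth (encounter stochasticity), bacterial background
dynamics, diurnal rhythms, non-exponential (lag-ramp) transitions, and
physiological state differences between the inoculum and the experimental
wells. Passing recovery tests therefore show that the estimators handle
depletion, pipetting bias and counting error — not that they are robust to
everything a real incubation can do.

## Estimator bias you should expect

Because the simulator integrates true depletion dynamics, the classical
estimators are *not* unbiased even without noise. With the default
predator load, pairing ingestion rates with the initial prey density
leaves a double-digit-percent overestimate of `Imax` at zero noise, while
the logarithmic-mean axis reduces the bias to under a percent — that
contrast is asserted in the test suite and is the quantitative argument
for the log-mean convention. Model-selection behaviour is validated the
same way: a θ = 3 truth is selected by AICc in the large majority of
replicates at moderate noise, while a θ = 1.2 truth under the
log-transformed objective leaves the type II and θ = 1.2 candidates
splitting the wins (neither reaching 80%) — the inconclusive regime that
motivates the proportion-ingested diagnostic, which in turn classifies
clean θ = 1 vs θ = 3 clearance curves with ≥90% accuracy in the suite.

## Numerical choices and degenerate inputs

* Logarithmic mean: the `X0 = Xt` limit returns the common value
  (relative difference below √machine-epsilon switches to the arithmetic
  mean).
* `nlsLM` runs with up to 200 iterations per start; all starts failing is
  an explicit error, never a silent NA.
* Delta-method standard errors for derived quantities
  (`SE(Imax) = SE(h)/h²`); plot confidence bands are pointwise 95%
  delta-method bands from the fit's covariance.
* Volume allocation rounds pipettable volumes to 0.01 mL by default, with
  the diluent absorbing the rounding residual so containers close exactly;
  infeasible targets (inocula exceeding the container) name the offending
  level.
* `rank_models()` breaks AICc ties by model id, making the ranking
  invariant to input order.
* Replicate `i` of a recovery study uses seed `seed + i`; identical seed
  and configuration replay bit-identically, and the simulation config is
  attached to every simulated experiment.

## Problem sizes

The bundled design (`demo_plan()`) is 17 experimental wells plus 9
controls. The test suite's simulation studies use 100 replicates for the
model-instability and type-discrimination properties, 100 for the noisy NR
recovery, and 4 for the zero-noise closure checks; the whole suite runs in
well under a minute on one core. Larger recovery studies
(`recovery_study(n_replicates = 500)`) remain inexpensive — a few minutes
on one core — because each replicate is 26 small ODE solves and a handful
of 2-parameter fits.
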