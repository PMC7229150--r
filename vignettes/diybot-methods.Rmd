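---
title: "Methods: from bioreactor sensor records to a digital proxy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bioreactor sensor records to a digital proxy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diybot)
```

`diybot` turns a uniformly sampled two-channel record of reactor effluent pH
and dissolved oxygen (DO) into a phenomenological dynamical model and a
management verdict. This vignette documents the model behind each stage, the
tunable parameters with their defaults and units, the numerical conventions,
the design choices that were genuinely open, and what the package's green
tests do and do not establish. No empirical number is stated here that the
test suite or `scripts/acceptance.R` does not itself compute.

## The scientific question and the shape of the answer

A membrane-aerated biofilm reactor treating greywater oscillates around a
healthy operating point (pH ≈ 7.3, DO ≈ 178 µM) and is occasionally
displaced by contaminant pulses. If the post-shock dynamics, reconstructed
*from the data alone*, are a **spiral sink** — an equilibrium whose Jacobian
has one negative real eigenvalue and a complex-conjugate pair with negative
real parts (in 2-D, just the damped complex pair) — then the reactor returns
to baseline on its own and corrective intervention is unnecessary. The
pipeline therefore ends in one of three flags: `self_correcting` (sink
classification *and* dynamic correspondence between empirical and model
attractors), `intervention_advised` (all stages passed but the equilibrium
is not a sink), or `indeterminate` (a gate failed, or no equilibrium could
be classified).

## Stage by stage

### Block aggregation

Raw records (field default 100 Hz) are reduced to arithmetic means of
contiguous, non-overlapping blocks (`block_duration`, default 7200 s = two
hours). The trailing partial block is discarded rather than padded: padding
would fabricate data at the record edge. All lags, delays and exponents
downstream are expressed per block.

### Signal isolation by SSA

Each channel is centered and decomposed by singular spectrum analysis:
the `L × (n − L + 1)` Hankel trajectory matrix (window `L`, default
`n/2` — the largest admissible window, the standard choice when the dominant
period is unknown) is factored by SVD. Eigentriples are grouped
automatically: elementary reconstructions whose weighted (w-)correlation
exceeds 0.5 form connected components; components contributing at least 1%
of the total squared singular values become `signal1`, `signal2`, …, the
rest pool into `noise`. Two thresholds are exposed (`ssa_threshold`,
`ssa_min_strength`). Multiple signal groups are allowed so that two
well-separated oscillations are reported as two components rather than
forced into one. *Signal strength* is the percentage of total squared
singular values in a group; the complete partition sums to 100% and the
summed reconstructions reproduce the input to numerical precision (this
identity is asserted in the tests on every fixture). Centering before
decomposition is deliberate: the operating point (pH 7.3, DO 178) otherwise
contributes a trend eigentriple that dwarfs the dynamics of interest; the
mean is added back to the reconstructed signal.

### Gate 1 — nonlinear-stationarity (cross prediction)

The signal is split into `n_segments` (default 4) contiguous equal
segments. **Each segment is z-scored**, then delay-embedded, and every
ordered pair (i, j) is scored by forecasting segment j one step ahead from
k = 3 nearest neighbors in segment i (RMS error in normalized units). The
series is declared nonstationary when any segment's mean error as library
or as target exceeds `stationarity_factor` (default 2) times the grand
mean.

The z-scoring is the load-bearing choice. It makes the test compare
*dynamics up to an affine rescale*, so the error matrix is invariant to
constant shifts, and — critically — a damped oscillation whose amplitude
decays across the record is not flagged for the decay alone. Without this,
every post-shock recovery record (the very regime the package exists to
model) would fail its own gate. The price is that a pure amplitude change
with no change of dynamics is invisible to the gate; what it does catch is
a change in the *shape* of the dynamics, e.g. a frequency shift, which is
what the unit tests assert.

### Gate 2 — surrogate data test

The null hypothesis is a (possibly monotonically transformed) linear
Gaussian process. IAAFT surrogates preserve the signal's amplitude multiset
exactly and its power spectrum approximately (iteration alternates spectral
adjustment and rank remapping, ending on the rank remap; `max_iter` 100,
spectral tolerance 1e−8). The discriminating statistic (default: one-step
simplex prediction error at the embedding parameters selected for the
record; alternative: time-reversal asymmetry) is computed on the original
and on `n_surrogates` (default 99) surrogates; the rank p-value is
`(1 + #{at least as extreme}) / (n_surrogates + 1)`, one-sided in the
direction appropriate to the statistic. Rejection at `level` (default 0.05)
is required for every analyzed channel before any model is fitted.

Two remarks. First, the test's type-I error on stationary linear nulls is
calibrated — the acceptance suite measures it over 500 AR(1) replicates and
requires it inside the exact binomial 95% interval of the nominal 0.05.
Second, on a *transient* (damped) deterministic signal the test has power
beyond strict nonlinearity: surrogates are stationary by construction and
cannot reproduce a decaying deterministic curve, so the gate reads as
"deterministic structure rather than random forcing", which is precisely
its role in the pipeline.

### Embedding parameter selection

The delay `tau` is the first local minimum of average mutual information
(equal-width histogram estimator, `ceiling(log2 n) + 1` bins, lags up to
`n/4`), after 3-point smoothing of the AMI curve — histogram AMI of nearly
periodic series is jagged and unsmoothed local minima land on estimator
noise. Lags whose AMI is indistinguishable from a shuffle baseline
(mean + 2 SD over five seeded permutations) count as minimal, so white
noise deterministically yields `tau = 1`; the fallback is the first lag
with autocorrelation below 1/e.

The dimension `E` maximizes leave-one-out simplex forecast skill **at a
horizon of `tau` samples** over `E = 1..E_max` (default 6), with ties
within `plateau_tol` (0.01) broken toward smaller `E`. A one-sample horizon
was rejected after measurement: for smooth flows it saturates above 0.98
already at `E = 1` (any embedding predicts one sample ahead of a slow
oscillation), which selects a non-injective reconstruction and destroys
cross mapping; forecasting one delay ahead restores discrimination. The
selection runs *before* the gates so that the gate statistics use the same
embedding conventions as the later reconstruction.

In the pipeline both can be pinned (`tau =`, `E =` in `diybot_config`),
matching the field practice of fixing, e.g., a delay of five two-hour
blocks.

### The simplex kernel

One nearest-neighbor forecasting kernel serves dimension selection, the
gate statistic, cross prediction and CCM: `k = E + 1` neighbors, Euclidean
metric, exponential distance weights `w_i = exp(−d_i / d_min)` normalized,
uniform weights over ties when the minimum distance is zero (distances
below `1e−7·(1 + d_max)` count as zero — the squared-form distance
computation leaves ~1e−8 cancellation residue on identical points). A
Theiler window (default `tau · E` samples) excludes temporally adjacent
points from the library so that serial correlation cannot pose as
state-space recurrence; distance ties break toward the earlier time index
for determinism. Skill is the Pearson correlation between predictions and
observations (hence invariant under affine transformation of the target),
reported as `NA` when either side is degenerate.

### Convergent cross mapping

`ccm(x, y, …)` tests "y drives x": the response `x` is embedded and the
driver `y` is cross-mapped from libraries of growing size (default grid: 8
sizes up to the full embedding; 50 random contiguous library draws per
size, seeded). `converged` requires all of: a skill gain of at least
`convergence_margin` (0.1) from the smallest to the largest library, a
positive Kendall trend across sizes, and full-library skill of at least
0.3 — the floor was added after observing that noise-on-noise cross maps
can drift upward by more than the margin while remaining uninformative.
The full-library `sampling = "sequential"` variant is deterministic and is
what the acceptance targets use.

Extended CCM imposes delays `−8..+8` blocks (bracketing the few-period
scale at which false positives were reported in the motivating study) on
the cross-mapped driver. True causality requires the skill peak at a
negative delay (driver leads); a peak at zero or positive delay flags
synchrony to a common force. Peak location uses a near-tie rule: skills
within `peak_tol` (0.005) of the maximum count as tied and resolve toward
the delay closest to zero (exact ties toward the most negative delay). The
rule exists because for deterministic series the driver at *several* delays
is a smooth function of the reconstructed state, so skills tie near 1 and a
raw argmax would manufacture a spurious lead or lag from floating-point
noise; resolving toward zero is conservative against false causality
claims.

Classification per direction: `strong` needs full-library skill > 0.8
*and* convergence *and* a negative-delay peak; `weak` needs skill in
(0.5, 0.8]; anything else is `absent`, and a direction that qualifies on
skill but peaks at a non-negative delay is demoted to `absent` with
`synchrony_suspected`. The pair summary is `bidirectional`,
`unidirectional` or `none`.

### Sparse ODE discovery

States (default: the two SSA signals as a 2-D (pH, DO) state; option
`mixed3d`: the mixed attractor coordinates `[DO(t), DO(t+lag), pH(t)]`) and
centered-difference derivatives feed sequentially thresholded least
squares over a polynomial library of total degree ≤ 2 (the smallest
library expressing damped interaction terms). Each equation is solved on
the column-normalized design with the target scaled by its SD; coefficients
with normalized magnitude below `threshold` (default 0.05 — scale-free
after the normalization) are zeroed and the active set re-solved to a fixed
point; the reported coefficients come from an unpenalized refit on the
final active set in the original scale, so noise-free representable systems
are recovered to solver precision. An exactly rank-deficient active design
aborts with the offending equation and a condition estimate; an
ill-conditioned but full-rank design (unavoidable when quadratic columns
are nearly affine in states that hover near a non-zero operating point)
proceeds.

The 2-D default departs from fitting in the 3-D mixed coordinates: when the
slow dynamics are a single damped mode — exactly what the synthetic record
produces — the three mixed coordinates are coplanar and the degree-2 design
is rank-deficient *by construction*. The 3-D option remains available for
records with genuinely three-dimensional dynamics.

Equilibria come from damped-Newton iteration (analytic Jacobian from the
library's exponent matrix) started from 25 seeded uniform draws plus the
box center, inside a search box that extends the data range by 50% per
side; roots within `1e−6 ×` box scale merge, and only residual norms below
`tol` (1e−8) are reported. Eigenvalue classification at the equilibrium
nearest the data centroid: all real parts negative with a complex pair ⇒
`spiral_sink`; without ⇒ `node_sink`; all positive ⇒ `source`; mixed ⇒
`saddle`; a purely imaginary pair ⇒ `center`; else `other`.

### Lyapunov diagnostics and dynamic correspondence

The maximum Lyapunov exponent is estimated Kantz-style: for up to 400
evenly spaced reference points, neighbors within a radius (default: the 5%
quantile of sampled inter-point distances) and outside the Theiler window
are followed `h = 0..max_periods` steps; the curve is the mean log
neighbor distance versus `h`, and the exponent is the least-squares slope
over the longest window (length ≥ 4) with R² ≥ 0.95 (overridable;
falls back to the best-R² window). Negative slope means converging (sink)
dynamics. *Dynamic correspondence* holds when the empirical attractor's
slope and the slope of the same embedding applied to the integrated model
trajectory agree within `lyap_tol` (default 0.05 per block) or twice their
combined fit SE, whichever is larger.

### Marginal impacts

Two notions are provided. `type = "instantaneous"` evaluates the symbolic
partial derivative ∂(d response/dt)/∂driver along a trajectory — for a
linear model this is the constant Jacobian entry. `type = "propagated"`
integrates the variational equation `Φ' = J(x(t)) Φ` and reports
`∂ x_response(t) / ∂ x_driver(0)`: the effect of an incremental increase in
the driver now on the response later. On a sink the propagated impact
decays to zero as the trajectory approaches equilibrium, which is the
quantity behind "the impact decays as the system re-equilibrates"; the
pipeline reports this type. The report includes the first time index from
which the impact magnitude stays below `tol` through the trajectory end, or
a "not decayed" flag.

## The synthetic stated world

`simulate_sensor_record` emulates, per channel:

| parameter | default | unit | rationale |
|---|---|---|---|
| `baseline_ph`, `baseline_do` | 7.3, 178 | pH, µM | healthy operating point |
| `ph_period`, `do_period` | 2.1, 2.9 | min | fast harmonic oscillations |
| `amp_ph`, `amp_do` | 0.2, 4 | pH, µM | oscillation magnitudes (the ± of the baselines) |
| `sample_rate` | 100 | Hz | field acquisition rate |
| `duration` | 310 | h | several recovery cycles in one record |
| `shock_time` | 10 | h | contamination pulse (`= duration` disables) |
| `shock_mag_ph`, `shock_mag_do` | 0.4, 20 | pH, µM | pulse displacement |
| `damping_rate` | 0.01 | h⁻¹ | envelope e-folds in ~4 days ≈ observed recovery (a few hydraulic retention times) |
| `recovery_period` | 50 | h | slow post-shock cycle visible at block scale |
| `do_lag` | 4 | h | DO slow response trails pH |
| `noise_sd_ph`, `noise_sd_do` | 0.02, 0.5 | pH, µM | additive sensor noise |

The shock is an instantaneous displacement followed by a damped slow
oscillation shared (with a lag) by both channels — so after two-hour
aggregation the record is a noisy 2-D damped spiral: a sink by
construction. The fast minutes-scale oscillations average out of the
blocks; they exist so that the raw record has the documented spectral
content. Several fields (`recovery_period`, shock magnitudes, amplitudes,
`do_lag`) have no externally stated value; they were fixed once at the
values above as what a wastewater-reactor operator would call realistic,
and are not tuned.

What the generator does **not** emulate: mechanistic biofilm or
nanoparticle chemistry, non-Gaussian sensor glitches, drift or
recalibration steps, genuinely nonlinear limit-cycle dynamics, and any
microbiome covariates. A green end-to-end test therefore establishes that
the pipeline correctly recovers *the stated world* — a linear damped spiral
observed through two coupled channels — not that it would classify every
real reactor correctly. Because the two synthetic channels are observables
of one underlying mode, extended CCM correctly reports their relation as
synchrony rather than causality; the causal-classification machinery is
instead validated on coupled logistic maps, where ground truth is
directional by construction (`simulate_coupled_logistic`, the standard CCM
benchmark).

`simulate_spiral_sink` integrates `x' = A(x − x*)` by fixed-step RK4 with
10 internal sub-steps per sample (keeping the trajectory within 1e−6 of the
matrix-exponential closed form, which the tests check against an
independent implementation); observation noise is added after integration
(measurement, not process, noise). The default `A` realizes eigenvalues
{−0.5, −0.1 ± i} through a fixed orthogonal change of basis so every
channel sees all three modes; the coefficients behind the original study
are unpublished, so this matrix is a documented stand-in with the stated
spectrum. `simulate_linear_stochastic` provides the stationary Gaussian AR
null (zero initial conditions, 100-step burn-in).

Tests generate the shock record at 1 Hz rather than 100 Hz purely for
runtime; block means at fixed block duration are statistically identical.

## Numerical conventions and degenerate inputs

- Every generator and every stochastic stage takes a seed; the pipeline
  derives stage seeds from the single config seed, and identical configs
  produce byte-identical JSON reports.
- Embedding rows are `(x_t, x_{t+τ}, …, x_{t+(E−1)τ})`, time-stamped by
  their last coordinate; mixed embeddings stamp rows by their lag-0
  position.
- Constant series are rejected wherever they make a quantity undefined
  (delay selection, surrogates, SSA strength of an all-zero series);
  degenerate skill is reported as `NA`, never silently zero.
- Aggregation requires the block to be an integer multiple of the step
  (relative tolerance 1e−8); the CSV reader enforces uniform spacing to
  1e−6 relative and rejects gaps rather than imputing.
- All-zero SINDy models are flagged `degenerate` with a warning rather than
  an error: a threshold above every true coefficient is a user decision.

## Known limitations

- The stationarity gate is insensitive to pure amplitude drift by design
  (see Gate 1); pair it with out-of-band monitoring if amplitude budgets
  matter operationally.
- The row/column-mean heterogeneity rule dilutes with many segments and can
  miss balanced designs (half the record one regime, half another, with
  `n_segments = 4`); unbalanced segment counts detect such changes.
- Extended CCM cannot resolve direction between two noise-free observables
  of the same smooth flow — skills tie across delays and the result is
  (correctly) synchrony. Directional claims need either noise, distinct
  dynamics, or genuinely lagged coupling.
- The degree-2 polynomial library cannot represent dynamics with higher-order
  or non-polynomial terms; the fit is then the best quadratic shadow, and
  only the equilibrium classification — not the coefficients — should be
  interpreted.
- The package is a proxy, not a twin: no streaming update of the model as
  new data arrive.
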