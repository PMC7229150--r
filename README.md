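# diybot

**Digital proxy modeling of bioreactor sensor dynamics in R.**

Small decentralized wastewater bioreactors are routinely hit by pulses of
chemical contaminants (for example silver nanoparticles washed out of
laundry greywater). The operational question is whether such a shock needs a
human intervention or whether the biofilm community self-corrects. `diybot`
answers that question from nothing but the reactor's real-time pH and
dissolved-oxygen (DO) sensor records: it reconstructs the reactor's
phase-space dynamics from the data, fits a phenomenological ODE model (a
"digital proxy" of the reactor), and classifies the stability of the
recovered dynamics. A stable spiral sink — one negative real eigenvalue plus
a complex-conjugate pair with negative real parts, i.e. damped oscillatory
relaxation back to equilibrium — means the reactor absorbs the shock on its
own.

The pipeline is the standard nonlinear-time-series (empirical dynamic
modeling) tool chain, end to end:

1. **Block aggregation** — 100 Hz sensor records are averaged into two-hour
   analysis blocks.
2. **Singular spectrum analysis (SSA)** — SVD of the Hankel trajectory
   matrix separates structured signal from noise; signal strength is the
   percentage of squared singular values in the signal eigentriples.
3. **Gates** — Schreiber-style nonlinear cross prediction tests that the
   dynamics are stationary across the record; IAAFT surrogate data testing
   checks that the structure is deterministic rather than linear-stochastic.
   A failed gate halts the pipeline with an `indeterminate` report instead
   of fitting an ODE to noise.
4. **Attractor reconstruction** — time-delay embedding (delay from the
   first minimum of average mutual information, dimension from simplex
   forecast skill), including mixed coordinates such as
   `[DO(t), DO(t+5), pH(t)]`.
5. **Convergent cross mapping (CCM)** — detects Y → X causality when Y is
   recoverable from X's reconstructed attractor with skill that converges
   as the library grows (strong above rho = 0.8, weak above 0.5); extended
   (time-delayed) CCM rules out synchrony false-positives by requiring the
   skill peak at a negative delay.
6. **Sparse ODE discovery** — sequentially thresholded least squares on a
   polynomial function library recovers governing equations
   `dx/dt = Theta(x) Xi`; equilibria are located by multi-start Newton
   iteration and classified by the eigenvalues of the analytic Jacobian.
7. **Diagnostics** — maximum Lyapunov exponents (Kantz divergence-curve
   slope) establish dynamic correspondence between the empirical and model
   attractors; marginal impacts (partial derivatives / trajectory
   sensitivities of the fitted ODEs) quantify how a driver variable moves a
   response variable over time.

A synthetic-data module (`simulate_sensor_record`, `simulate_spiral_sink`,
`simulate_coupled_logistic`, `simulate_linear_stochastic`) generates records
with the statistical structure the analysis assumes — baseline pH
7.3 with 2.1-min harmonic oscillation, DO 178 µM with 2.9-min oscillation,
damped spiral-sink shock response, coupled-map causal benchmarks and
linear-stochastic nulls — so every stage is testable without a physical
reactor.

## Worked example

```r
library(diybot)

# a 310 h record @1 Hz: healthy baseline, contamination pulse at t = 10 h,
# damped 50 h recovery cycles (100 Hz is the field default; 1 Hz only
# changes runtime, not the block means)
rec    <- simulate_sensor_record(sensor_sim_config(sample_rate = 1, seed = 2))
report <- run_diybot(rec, diybot_config(seed = 7))
print(report)
#> <diybot_report>
#>   blocks analyzed: 155
#>   causal summary: none
#>   equilibrium class: spiral_sink
#>   management flag: self_correcting

cat(render_equations(report$model), sep = "\n")
#> dpH/dt = +1.114 +0.04428*DO -1.581*pH +6.207e-05*DO^2 -0.01058*pH*DO +0.2688*pH^2
#> dDO/dt = -131.5 -0.2307*DO +26.46*pH +0.003425*DO^2 -0.1996*pH*DO +2.446*pH^2

print(report$equilibrium)
#> <equilibrium_analysis> spiral_sink; eigenvalues: -0.0037+0.2721i, -0.0037-0.2721i
```

What this means: the two-hour-block signals pass both gates (deterministic,
stationary dynamics); the fitted ODE has an equilibrium at the healthy
baselines (pH 7.30, DO 178.3 µM) whose Jacobian eigenvalues are a complex
pair with negative real parts — a spiral sink, damped oscillatory return to
baseline. The empirical and model attractors' Lyapunov exponents agree
(−0.021 vs −0.011 per block, both converging), so the proxy dynamically
corresponds to the data, and the management flag is `self_correcting`: no
intervention needed. The CCM summary is `none` with synchrony suspected
because both sensor channels here are observables of one underlying mode —
extended CCM correctly refuses to call that a causal interaction. Feeding
the pipeline linear AR noise instead halts at the surrogate gate with an
`indeterminate` flag.

Cross-mapping pieces can also be used directly:

```r
sim <- simulate_coupled_logistic(coupled_map_config())  # x drives y
ccm(ut_channel(sim$y, 1), ut_channel(sim$x, 1), E = 2, tau = 1, seed = 1)
#> <ccm_result> y -> x | E=2 tau=1 | rho(max lib)=0.986 | converged
```

## Command line

```sh
inst/cli/diybot simulate sensor --seed 1 --out sensors.csv
inst/cli/diybot run --input sensors.csv --out report_dir/   # exit 2 = gate halt
inst/cli/diybot ccm --input sensors.csv --x pH --y DO
```

(After installation the script lives at `system.file("cli", "diybot",
package = "diybot")`.)

## Scope

The package is a *digital proxy*, not a digital twin: it reconstructs and
diagnoses dynamics from a finished record, with no streaming updates, no
mechanistic biofilm/nanoparticle chemistry, and no microbiome integration.
See `vignettes/diybot-methods.Rmd` for the model assumptions, parameter
choices and known limitations.
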