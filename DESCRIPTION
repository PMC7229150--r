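Package: diybot
Title: Digital Proxy Modeling of Bioreactor Sensor Dynamics
Version: 0.1.0
Authors@R:
    person("DIYBOT", "Developers", email = "diybot@example.org", role = c("aut", "cre"))
Description: Turns real-time bioreactor pH and dissolved-oxygen sensor records
    into a phenomenological dynamical model. Provides block aggregation and
    singular spectrum analysis for signal isolation, nonlinear-stationarity and
    surrogate-data gating, time-delay (and mixed-coordinate) attractor
    reconstruction with simplex-projection forecasting, convergent cross
    mapping (plain and time-delayed) for causal inference between channels,
    sparse ODE discovery by sequentially thresholded least squares on a
    polynomial function library, equilibrium location with eigenvalue
    stability classification, maximum Lyapunov exponent estimation, and
    marginal-impact (partial derivative and trajectory sensitivity) analysis.
    A synthetic sensor-data generator (baseline harmonic oscillation, damped
    spiral-sink shock response, coupled logistic maps, linear stochastic
    nulls) makes every stage verifiable without a physical reactor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
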