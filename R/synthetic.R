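#' Spiral-sink system specification
#'
#' A three-dimensional linear system `x' = A (x - x*)` whose spectrum is a
#' sink with damped rotation: one negative real eigenvalue plus a complex
#' conjugate pair with negative real parts. This is the dynamical regime the
#' bioreactor sensor records exhibit after a contamination pulse, and the
#' workhorse benchmark for attractor reconstruction, cross mapping, sparse
#' ODE recovery and Lyapunov estimation.
#'
#' The default `state_matrix` has eigenvalues {-0.5, -0.1 +/- i} (time in
#' hours-scale block units), expressed in mixed coordinates through a fixed
#' orthogonal change of basis so that every observed channel sees all three
#' modes. The published model coefficients behind the original study are not
#' available; this default is a stand-in with the stated spectrum.
#'
#' @param state_matrix 3x3 coefficient matrix (sink with one real eigenvalue
#'   and one complex pair).
#' @param equilibrium 3-vector equilibrium (pH units, uM O2, auxiliary).
#' @param initial_state 3-vector initial condition.
#' @param step positive time increment per sample.
#' @param n_steps number of samples returned (>= 2), including the initial
#'   state.
#' @param noise_sd additive Gaussian observation noise SD, scalar or
#'   per-channel length-3 vector.
#' @param seed integer RNG seed for the observation noise.
#' @return an object of class `spiral_sink_system`.
#' @export
spiral_sink_system <- function(state_matrix = default_spiral_matrix(),
                               equilibrium = c(7.3, 178, 1),
                               initial_state = equilibrium + c(0.4, 15, 1),
                               step = 0.1, n_steps = 2000,
                               noise_sd = 0, seed = 1L) {
  state_matrix <- as.matrix(state_matrix)
  if (!all(dim(state_matrix) == c(3, 3)))
    stop("state_matrix must be 3x3")
  ev <- eigen(state_matrix, only.values = TRUE)$values
  bad <- which(Re(ev) >= 0)
  if (length(bad))
    stop(sprintf("state_matrix is not a sink: eigenvalue %s has non-negative real part",
                 format(ev[bad[1]], digits = 6)))
  n_real <- sum(abs(Im(ev)) < 1e-10)
  if (n_real != 1)
    stop("spiral sink requires exactly one real eigenvalue and one complex conjugate pair; got ",
         n_real, " real eigenvalue(s)")
  if (step <= 0) stop("step must be positive")
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, 3)
  structure(list(state_matrix = state_matrix,
                 equilibrium = as.numeric(equilibrium),
                 initial_state = as.numeric(initial_state),
                 step = step, n_steps = as.integer(n_steps),
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed),
                 eigenvalues = ev),
            class = "spiral_sink_system")
}

#' Default spiral-sink coefficient matrix
#'
#' Real block form `diag([[-0.1, 1], [-1, -0.1]], -0.5)` conjugated by a
#' fixed orthogonal matrix, so eigenvalues are {-0.5, -0.1 +/- i} and all
#' channels mix all modes.
#' @export
default_spiral_matrix <- function() {
  b <- rbind(c(-0.1, 1, 0),
             c(-1, -0.1, 0),
             c(0, 0, -0.5))
  q <- qr.Q(qr(rbind(c(2, 1, 1), c(1, 2, -1), c(-1, 1, 2))))
  q %*% b %*% t(q)
}

#' Simulate the spiral-sink system
#'
#' Integrates `x' = A (x - x*)` with fixed-step 4th-order Runge-Kutta and
#' adds observation (not process) noise afterwards. With `noise_sd = 0` the
#' trajectory is deterministic and, because the system is linear, matches the
#' matrix-exponential closed form to integrator accuracy.
#'
#' @param system a [spiral_sink_system()].
#' @param substeps internal RK4 sub-steps per output sample (default 10;
#'   keeps the integrator within 1e-6 of the matrix-exponential closed form
#'   at the default step).
#' @return `uniform_ts` with channels `x1, x2, x3` (time unit = that of
#'   `system$step`).
#' @export
simulate_spiral_sink <- function(system, substeps = 10L) {
  stopifnot(inherits(system, "spiral_sink_system"))
  a <- system$state_matrix
  xeq <- system$equilibrium
  h <- system$step / substeps
  n <- system$n_steps
  x <- system$initial_state - xeq
  out <- matrix(0, n, 3)
  out[1, ] <- x
  for (k in 2:n) {
    for (s in seq_len(substeps)) {
      k1 <- a %*% x
      k2 <- a %*% (x + h / 2 * k1)
      k3 <- a %*% (x + h / 2 * k2)
      k4 <- a %*% (x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[k, ] <- x
  }
  out <- sweep(out, 2, xeq, "+")
  if (any(system$noise_sd > 0)) {
    out <- out + with_seed(system$seed, {
      matrix(stats::rnorm(3L * n, 0, rep(system$noise_sd, each = n)), n, 3)
    })
  }
  ts <- uniform_ts(out, step = system$step, channels = c("x1", "x2", "x3"),
                   time_unit = "model time")
  attr(ts, "sim_config") <- list(generator = "spiral_sink",
                                 state_matrix = system$state_matrix,
                                 equilibrium = xeq,
                                 initial_state = system$initial_state,
                                 step = h, n_steps = n,
                                 noise_sd = system$noise_sd,
                                 seed = system$seed)
  ts
}

#' Sensor-record simulation configuration
#'
#' Emulates the statistical structure of the reactor's effluent sensors:
#' baselines pH 7.3 and DO 178 uM with fast harmonic oscillations of periods
#' 2.1 and 2.9 minutes and amplitudes 0.2 pH / 4 uM, sampled at
#' `sample_rate` Hz. A contamination pulse at `shock_time` displaces both
#' channels, which then relax back as a damped slow oscillation (envelope
#' `exp(-damping_rate * t)`, period `recovery_period` hours); the DO response
#' lags the pH response by `do_lag` hours, so the two channels are coupled
#' observables of one damped spiral mode. `shock_time = duration` disables
#' the shock.
#'
#' @param baseline_ph,baseline_do channel baselines (pH units, uM).
#' @param ph_period,do_period fast oscillation periods in minutes.
#' @param amp_ph,amp_do fast oscillation amplitudes.
#' @param sample_rate acquisition rate, Hz.
#' @param duration record length, hours.
#' @param shock_time pulse time, hours, in `[0, duration]`.
#' @param damping_rate post-shock envelope decay, per hour.
#' @param recovery_period post-shock slow oscillation period, hours.
#' @param shock_mag_ph,shock_mag_do pulse displacement per channel.
#' @param do_lag lag of the DO slow response behind pH, hours.
#' @param noise_sd_ph,noise_sd_do additive sensor noise SDs.
#' @param seed integer RNG seed.
#' @export
sensor_sim_config <- function(baseline_ph = 7.3, baseline_do = 178,
                              ph_period = 2.1, do_period = 2.9,
                              amp_ph = 0.2, amp_do = 4,
                              sample_rate = 100,
                              duration = 310, shock_time = 10,
                              damping_rate = 0.01, recovery_period = 50,
                              shock_mag_ph = 0.4, shock_mag_do = 20,
                              do_lag = 4,
                              noise_sd_ph = 0.02, noise_sd_do = 0.5,
                              seed = 1L) {
  if (ph_period <= 0 || do_period <= 0) stop("periods must be positive")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (duration * 60 < max(ph_period, do_period))
    stop(sprintf("duration (%g h) is shorter than one oscillation period (%g min)",
                 duration, max(ph_period, do_period)))
  if (shock_time < 0 || shock_time > duration)
    stop("shock_time must lie in [0, duration]")
  structure(as.list(environment()), class = "sensor_sim_config")
}

#' Simulate a two-channel bioreactor sensor record
#'
#' @param config a [sensor_sim_config()].
#' @return `uniform_ts` with channels `pH` and `DO`, step `1/sample_rate`
#'   seconds.
#' @export
simulate_sensor_record <- function(config) {
  stopifnot(inherits(config, "sensor_sim_config"))
  cf <- config
  n <- floor(cf$duration * 3600 * cf$sample_rate) + 1
  t_h <- (seq_len(n) - 1) / (3600 * cf$sample_rate)   # hours
  t_min <- t_h * 60
  ph <- cf$baseline_ph + cf$amp_ph * cos(2 * pi * t_min / cf$ph_period)
  do <- cf$baseline_do + cf$amp_do * cos(2 * pi * t_min / cf$do_period)
  damped <- function(tp, mag) {
    y <- numeric(length(tp))
    on <- tp >= 0
    y[on] <- mag * exp(-cf$damping_rate * tp[on]) *
      cos(2 * pi * tp[on] / cf$recovery_period)
    y
  }
  if (cf$shock_time < cf$duration) {
    ph <- ph + damped(t_h - cf$shock_time, cf$shock_mag_ph)
    do <- do + damped(t_h - cf$shock_time - cf$do_lag, cf$shock_mag_do)
  }
  if (cf$noise_sd_ph > 0 || cf$noise_sd_do > 0) {
    noise <- with_seed(cf$seed, {
      cbind(stats::rnorm(n, 0, cf$noise_sd_ph),
            stats::rnorm(n, 0, cf$noise_sd_do))
    })
    ph <- ph + noise[, 1]
    do <- do + noise[, 2]
  }
  ts <- uniform_ts(cbind(ph, do), step = 1 / cf$sample_rate,
                   channels = c("pH", "DO"))
  attr(ts, "sim_config") <- c(list(generator = "sensor_record"),
                              unclass(config))
  ts
}

#' Coupled logistic map configuration
#'
#' Canonical benchmark for cross-mapping causality:
#' `x[t+1] = x[t] (r_x - r_x x[t] - beta_xy y[t])`,
#' `y[t+1] = y[t] (r_y - r_y y[t] - beta_yx x[t])`.
#' With `beta_xy = 0` the x map is autonomous and drives y.
#'
#' @param r_x,r_y map growth parameters.
#' @param beta_xy coupling of y onto x (>= 0).
#' @param beta_yx coupling of x onto y (>= 0).
#' @param n kept length; `burn_in` initial steps are discarded first.
#' @param burn_in discarded initial steps (>= 0, < n).
#' @param x0,y0 initial values in (0, 1).
#' @param seed integer seed (kept for provenance; the maps are deterministic
#'   given `x0`, `y0`).
#' @export
coupled_map_config <- function(r_x = 3.8, r_y = 3.5,
                               beta_xy = 0, beta_yx = 0.32,
                               n = 1000, burn_in = 100,
                               x0 = 0.4, y0 = 0.2, seed = 1L) {
  if (!(x0 > 0 && x0 < 1 && y0 > 0 && y0 < 1))
    stop("x0 and y0 must lie in (0, 1)")
  if (!(n > burn_in && burn_in >= 0)) stop("need n > burn_in >= 0")
  if (beta_xy < 0 || beta_yx < 0) stop("coupling strengths must be >= 0")
  structure(as.list(environment()), class = "coupled_map_config")
}

#' Simulate unidirectionally or bidirectionally coupled logistic maps
#'
#' @param config a [coupled_map_config()].
#' @return list with elements `x` and `y`, each a single-channel
#'   `uniform_ts` of length `n - burn_in` (step 1).
#' @export
simulate_coupled_logistic <- function(config) {
  stopifnot(inherits(config, "coupled_map_config"))
  cf <- config
  n_tot <- cf$n
  x <- numeric(n_tot); y <- numeric(n_tot)
  x[1] <- cf$x0; y[1] <- cf$y0
  for (t in seq_len(n_tot - 1)) {
    x[t + 1] <- x[t] * (cf$r_x - cf$r_x * x[t] - cf$beta_xy * y[t])
    y[t + 1] <- y[t] * (cf$r_y - cf$r_y * y[t] - cf$beta_yx * x[t])
    if (x[t + 1] <= 0 || x[t + 1] >= 1 || y[t + 1] <= 0 || y[t + 1] >= 1)
      stop(sprintf("coupled map trajectory escaped (0,1) at step %d (x=%g, y=%g)",
                   t + 1, x[t + 1], y[t + 1]))
  }
  keep <- (cf$burn_in + 1):n_tot
  list(x = uniform_ts(x[keep], 1, "x", time_unit = "steps"),
       y = uniform_ts(y[keep], 1, "y", time_unit = "steps"))
}

#' Simulate a stationary Gaussian autoregressive series
#'
#' Linear-stochastic null model for the surrogate test. Initial conditions
#' are zero; `burn_in` steps are discarded so the kept segment is close to
#' the stationary regime.
#'
#' @param ar_coefficients AR coefficients (roots of the AR polynomial must
#'   lie outside the unit circle).
#' @param noise_sd innovation SD.
#' @param n kept length.
#' @param seed integer RNG seed.
#' @param n_channels number of independent replicate channels (default 1).
#' @param burn_in discarded initial steps (default 100).
#' @return single- or multi-channel `uniform_ts` (step 1).
#' @export
simulate_linear_stochastic <- function(ar_coefficients, noise_sd = 1, n = 500,
                                       seed = 1L, n_channels = 1,
                                       burn_in = 100) {
  p <- length(ar_coefficients)
  if (p > 0) {
    roots <- polyroot(c(1, -ar_coefficients))
    if (any(Mod(roots) <= 1 + 1e-12))
      stop("non-stationary AR coefficients: root inside or on the unit circle (|root| = ",
           format(min(Mod(roots)), digits = 6), ")")
  }
  vals <- with_seed(seed, {
    sapply(seq_len(n_channels), function(j) {
      e <- stats::rnorm(n + burn_in, 0, noise_sd)
      x <- if (p > 0)
        as.numeric(stats::filter(e, ar_coefficients, method = "recursive"))
      else e
      x[(burn_in + 1):(burn_in + n)]
    })
  })
  uniform_ts(vals, 1, paste0("ar", seq_len(n_channels)), time_unit = "steps")
}
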