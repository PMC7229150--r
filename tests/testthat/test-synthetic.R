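test_that("spiral-sink generator matches the matrix-exponential closed form", {
  sys <- spiral_sink_system(noise_sd = 0, n_steps = 500)
  ts <- simulate_spiral_sink(sys)
  dev0 <- sys$initial_state - sys$equilibrium
  scale <- sqrt(sum(dev0^2))
  # closed-form oracle, independent of the RK4 path
  for (k in c(1, 5, 50, 200, 500)) {
    truth <- as.numeric(
      Matrix::expm(sys$state_matrix * (k - 1) * sys$step) %*% dev0) +
      sys$equilibrium
    dev_norm <- max(sqrt(sum((truth - sys$equilibrium)^2)), 1e-12 * scale)
    expect_lt(max(abs(ts$values[k, ] - truth)) / dev_norm, 1e-6)
  }
})

test_that("spiral-sink generator honors its contract", {
  sys <- spiral_sink_system(noise_sd = 0, n_steps = 50)
  # fixed point: start at equilibrium, stay there exactly
  sys_eq <- spiral_sink_system(initial_state = sys$equilibrium,
                               noise_sd = 0, n_steps = 20)
  out <- simulate_spiral_sink(sys_eq)
  expect_equal(out$values,
               matrix(rep(sys$equilibrium, each = 20), 20, 3),
               ignore_attr = TRUE)

  # log-distance to equilibrium decays at ~ the dominant real part (-0.1)
  long <- simulate_spiral_sink(spiral_sink_system(noise_sd = 0, n_steps = 1500))
  d <- sqrt(rowSums(sweep(long$values, 2, sys$equilibrium)^2))
  t_h <- ut_time(long)
  win <- t_h > 30 & t_h < 140          # past the fast -0.5 mode transient
  slope <- unname(coef(lm(log(d[win]) ~ t_h[win]))[2])
  expect_equal(slope, -0.1, tolerance = 0.02)

  # determinism under a fixed seed
  sn <- spiral_sink_system(noise_sd = 0.05, seed = 11, n_steps = 40)
  expect_identical(simulate_spiral_sink(sn)$values,
                   simulate_spiral_sink(sn)$values)

  # non-sink and non-spiral matrices rejected with a diagnostic
  expect_error(spiral_sink_system(state_matrix = diag(c(0.2, -1, -2))),
               "non-negative real part")
  expect_error(spiral_sink_system(state_matrix = diag(c(-1, -2, -3))),
               "complex conjugate pair")
  expect_error(spiral_sink_system(n_steps = 1), "n_steps")
})

test_that("sensor record means, spectrum and damping behave as configured", {
  # noise-free, no shock: channel means equal baselines over whole periods
  # (duration 60.9 min = 29 pH periods = 21 DO periods; 10 Hz keeps both
  # periods an integer number of samples)
  cf <- sensor_sim_config(duration = 60.9 / 60, sample_rate = 10,
                          shock_time = 60.9 / 60,
                          noise_sd_ph = 0, noise_sd_do = 0)
  rec <- simulate_sensor_record(cf)
  n_whole <- 36540                      # floor(duration*3600*rate)
  expect_equal(mean(ut_channel(rec, "pH")[1:n_whole]), 7.3, tolerance = 1e-9)
  expect_equal(mean(ut_channel(rec, "DO")[1:n_whole]), 178, tolerance = 1e-9)

  # dominant spectral peak of the pre-shock pH segment at 1/2.1 min^-1
  ph <- ut_channel(rec, "pH") - 7.3
  pg <- Mod(fft(ph[1:n_whole]))[2:(n_whole / 2)]
  f_peak <- which.max(pg) / (n_whole / 10)   # Hz
  expect_equal(f_peak, 1 / (2.1 * 60), tolerance = 1e-3)

  # post-shock block-level peak amplitudes strictly decreasing
  cfs <- sensor_sim_config(duration = 300, sample_rate = 1, shock_time = 0,
                           do_lag = 0, noise_sd_ph = 0, noise_sd_do = 0)
  blocks <- aggregate_blocks(simulate_sensor_record(cfs), 7200)
  slow <- ut_channel(blocks, "pH") - 7.3
  pk <- which(diff(sign(diff(slow))) == -2) + 1
  pk <- pk[slow[pk] > 1e-4]
  expect_gt(length(pk), 2)
  expect_true(all(diff(slow[pk]) < 0))

  expect_error(sensor_sim_config(duration = 1 / 60), "shorter than one")
  expect_error(sensor_sim_config(shock_time = -1), "shock_time")
})

test_that("coupled logistic maps respect coupling structure", {
  sim <- simulate_coupled_logistic(coupled_map_config(n = 500))
  xv <- ut_channel(sim$x, 1); yv <- ut_channel(sim$y, 1)
  expect_true(all(xv > 0 & xv < 1 & yv > 0 & yv < 1))
  expect_length(xv, 400)

  # uncoupled maps are independent: lag-0 cross-correlation stays small
  # (Monte-Carlo bound over initial conditions)
  ccs <- vapply(1:5, function(s) {
    sim0 <- simulate_coupled_logistic(coupled_map_config(
      beta_yx = 0, n = 1100, x0 = 0.1 + 0.12 * s, y0 = 0.9 - 0.13 * s))
    abs(cor(ut_channel(sim0$x, 1), ut_channel(sim0$y, 1)))
  }, 0)
  expect_true(all(ccs < 0.1))

  # unidirectional coupling: x0 perturbs y's path, y0 never reaches x
  base <- simulate_coupled_logistic(coupled_map_config(n = 300))
  dx0 <- simulate_coupled_logistic(coupled_map_config(n = 300, x0 = 0.41))
  dy0 <- simulate_coupled_logistic(coupled_map_config(n = 300, y0 = 0.21))
  expect_false(isTRUE(all.equal(ut_channel(base$y, 1), ut_channel(dx0$y, 1))))
  expect_identical(ut_channel(base$x, 1), ut_channel(dy0$x, 1))

  # reproducibility and escape detection
  expect_identical(simulate_coupled_logistic(coupled_map_config())$y$values,
                   simulate_coupled_logistic(coupled_map_config())$y$values)
  expect_error(simulate_coupled_logistic(coupled_map_config(r_x = 4.2,
                                                            x0 = 0.5)),
               "escaped .* at step")
  expect_error(coupled_map_config(x0 = 1.2), "\\(0, 1\\)")
  expect_error(coupled_map_config(n = 50, burn_in = 60), "burn_in")
})

test_that("linear stochastic generator is a stationary Gaussian AR process", {
  # zero innovations + zero initial conditions -> all-zero series
  z <- simulate_linear_stochastic(0.5, noise_sd = 0, n = 50, seed = 1)
  expect_equal(ut_channel(z, 1), rep(0, 50))

  # sample lag-1 autocorrelation matches the theoretical ACF of AR(1)
  x <- simulate_linear_stochastic(0.5, n = 20000, seed = 3)
  ac1 <- acf(ut_channel(x, 1), lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(ac1, 0.5, tolerance = 0.02)

  expect_identical(simulate_linear_stochastic(c(0.4, 0.2), n = 100, seed = 9)$values,
                   simulate_linear_stochastic(c(0.4, 0.2), n = 100, seed = 9)$values)
  expect_error(simulate_linear_stochastic(1.0, n = 100), "non-stationary")
  expect_equal(ncol(simulate_linear_stochastic(0.3, n = 60, seed = 1,
                                               n_channels = 2)$values), 2)
})
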