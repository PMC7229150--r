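test_that("delay_embed index arithmetic matches brute force", {
  x <- as.numeric(1:10)
  emb <- delay_embed(x, E = 3, tau = 2)
  expect_equal(nrow(emb$points), 6)
  expect_equal(emb$points[1, ], c(1, 3, 5))
  expect_equal(emb$points[6, ], c(6, 8, 10))
  expect_equal(emb$ref_index, 5:10)

  # E = 1: the series itself
  e1 <- delay_embed(x, 1, 1)
  expect_equal(as.numeric(e1$points), x)

  # projecting onto coordinate 1 recovers the leading samples
  expect_equal(emb$points[, 1], x[1:6])

  # brute-force row construction on random inputs
  set.seed(11)
  for (case in 1:10) {
    n <- sample(20:60, 1); E <- sample(1:4, 1); tau <- sample(1:3, 1)
    if (n <= (E - 1) * tau) next
    y <- rnorm(n)
    em <- delay_embed(y, E, tau)
    m <- n - (E - 1) * tau
    brute <- t(vapply(seq_len(m), function(i) y[i + (0:(E - 1)) * tau],
                      numeric(E)))
    expect_equal(unname(em$points), unname(matrix(brute, nrow = m)))
  }
  expect_error(delay_embed(rnorm(5), 4, 2), "too short")
})

test_that("mixed_embed handles arbitrary channel/lag coordinates", {
  vals <- cbind(DO = rnorm(100), pH = rnorm(100))
  ts <- uniform_ts(vals, 1)
  emb <- mixed_embed(ts, list(c("DO", 0), c("DO", 5), c("pH", 0)))
  expect_equal(nrow(emb$points), 95)          # 100 - 5
  expect_equal(emb$points[1, ], unname(c(vals[1, "DO"], vals[6, "DO"],
                                         vals[1, "pH"])))
  # single zero-lag coordinate is the channel itself
  one <- mixed_embed(ts, list(c("pH", 0)))
  expect_equal(as.numeric(one$points), as.numeric(vals[, "pH"]))
  # permuting coordinates permutes columns, distances unchanged
  emb2 <- mixed_embed(ts, list(c("pH", 0), c("DO", 0), c("DO", 5)))
  expect_equal(emb2$points[, c(2, 3, 1)], emb$points)
  d1 <- dist(emb$points[1:10, ]); d2 <- dist(emb2$points[1:10, ])
  expect_equal(as.numeric(d1), as.numeric(d2))
  expect_error(mixed_embed(ts, list(c("xx", 0))), "unknown channel")
  expect_error(mixed_embed(ts, list(c("pH", 0), c("pH", 150))),
               "infeasible")
})

test_that("select_delay finds the AMI minimum (quarter period), noise gives 1", {
  # sinusoid of period P: AMI minimum near P/4
  tau <- select_delay(sinusoid(600, 40) + 1e-6 * sin(seq_len(600)))
  expect_true(abs(tau - 10) <= 2)
  # white noise: immediately minimal, smallest lag wins
  set.seed(3)
  expect_equal(select_delay(rnorm(500)), 1L)
  # deterministic: same answer on repeated calls
  x <- sinusoid(400, 28)
  expect_identical(select_delay(x), select_delay(x))
  expect_error(select_delay(rnorm(10)), "at least 20")
  expect_error(select_delay(rep(1, 100)), "constant")
})

test_that("select_dimension plateaus at the attractor dimension", {
  # noise-free logistic map: 1-D function, plateau from the start
  E_log <- select_dimension(logistic_map(500, 4, 0.3), tau = 1)
  expect_true(E_log %in% c(1L, 2L))
  expect_gt(max(attr(E_log, "skill"), na.rm = TRUE), 0.99)
  # pure sinusoid: two dimensions suffice
  E_sin <- select_dimension(sinusoid(500, 40), tau = 10)
  expect_equal(as.integer(E_sin), 2L)
  expect_error(select_dimension(rep(2, 100), 1), "constant")
})

test_that("simplex projection obeys its contract", {
  x <- logistic_map(500, 3.9, 0.4)
  emb <- delay_embed(x, 2, 1)
  m <- nrow(emb$points)

  # self-map with self allowed: exact, rho = 1
  res <- simplex_project(emb, emb$points[, 1], spec = neighbor_spec(k = 3),
                         exclude_self = FALSE)
  expect_equal(res$predictions, emb$points[, 1], tolerance = 1e-12)
  expect_equal(res$skill, 1)

  # leave-one-out one-step forecast on a deterministic map: rho > 0.99
  usable <- seq_len(m - 1)
  target <- x[emb$ref_index[usable] + 1]
  res2 <- simplex_project(emb, target, lib_rows = usable, pred_rows = usable,
                          spec = neighbor_spec(k = 3, theiler_window = 1),
                          target_rows = usable)
  expect_gt(res2$skill, 0.99)

  # independent white-noise target: |rho| small
  set.seed(6)
  res3 <- simplex_project(emb, rnorm(m), spec = neighbor_spec(k = 3))
  expect_lt(abs(res3$skill), 0.2)

  # skill is invariant under affine transformation of the target
  res4 <- simplex_project(emb, 3 * target - 7, lib_rows = usable,
                          pred_rows = usable,
                          spec = neighbor_spec(k = 3, theiler_window = 1),
                          target_rows = usable)
  expect_equal(res4$skill, res2$skill, tolerance = 1e-12)

  # degenerate target: skill undefined, reported as NA
  res5 <- simplex_project(emb, rep(1, m), spec = neighbor_spec(k = 3))
  expect_true(is.na(res5$skill))

  # too few admissible neighbors -> error with counts (or NA when asked)
  expect_error(simplex_project(emb, emb$points[, 1], lib_rows = 1:3,
                               spec = neighbor_spec(k = 5)),
               "library too small")
  big_tw <- neighbor_spec(k = 3, theiler_window = m)
  expect_error(simplex_project(emb, emb$points[, 1], spec = big_tw),
               "admissible neighbors")
  res6 <- simplex_project(emb, emb$points[, 1], spec = big_tw,
                          on_insufficient = "na")
  expect_true(all(is.na(res6$predictions)))
})

test_that("max_lyapunov recovers the dominant exponent of a linear sink", {
  ts <- default_sink_record()
  emb <- delay_embed(ut_select(ts, "x1"), E = 3, tau = 17)
  ly <- max_lyapunov(emb, neighbor_spec(theiler_window = 51),
                     max_periods = 30)
  # dominant real part is -0.1 per unit time (analytic oracle)
  expect_lt(ly$slope_per_unit_time, 0)
  expect_equal(ly$slope_per_unit_time, -0.1, tolerance = 0.05)
  expect_true(ly$fit_range[1] >= 0 && ly$fit_range[2] <= 30)
  # deterministic: identical curve on repeated calls
  ly2 <- max_lyapunov(emb, neighbor_spec(theiler_window = 51),
                      max_periods = 30)
  expect_identical(ly$divergence_curve, ly2$divergence_curve)

  # chaotic logistic map (r = 4): positive exponent
  embl <- delay_embed(logistic_map(1200, 4, 0.2), 2, 1)
  lyl <- max_lyapunov(embl, neighbor_spec(theiler_window = 2),
                      radius = 0.005, max_periods = 8)
  expect_gt(lyl$slope, 0)

  # impossible radius rejected with the largest feasible radius
  expect_error(max_lyapunov(embl, neighbor_spec(theiler_window = 2),
                            radius = 1e-12, max_periods = 5),
               "largest feasible radius")
})
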