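# Minimal constructors for classification-rule tests: classify_interaction
# is a pure function of these fields.
fake_ccm <- function(rho, converged, driver = "A", response = "B") {
  structure(list(driver = driver, response = response, rho_max = rho,
                 converged = converged), class = "ccm_result")
}
fake_ext <- function(peak) {
  structure(list(peak_delay = peak, true_causal = peak < 0),
            class = "extended_ccm_result")
}

test_that("ccm self cross-map and independent noise behave as expected", {
  x <- logistic_map(400, 3.9, 0.4)
  m <- 399
  r_self <- ccm(x, x, E = 2, tau = 1, lib_sizes = m, sampling = "sequential")
  expect_gt(r_self$rho_max, 0.999)

  # independent white noise: low skill, no convergence (over several seeds)
  for (s in c(2, 12, 22)) {
    set.seed(s)
    a <- rnorm(500); b <- rnorm(500)
    r <- ccm(a, b, E = 2, tau = 1, n_draws = 10, seed = s)
    expect_lt(abs(r$rho_max), 0.5)
    expect_false(r$converged)
  }
  expect_error(ccm(x, x, E = 2, tau = 1, lib_sizes = c(3, 50)), "E \\+ 2")
  expect_error(ccm(x, x[1:100], E = 2, tau = 1), "share length")
})

test_that("ccm resolves the direction of unidirectional coupling", {
  sim <- simulate_coupled_logistic(coupled_map_config())
  xv <- ut_channel(sim$x, 1); yv <- ut_channel(sim$y, 1)
  # x drives y: embedding y recovers x with convergent skill
  r_true <- ccm(yv, xv, E = 2, tau = 1, seed = 7)
  expect_true(r_true$converged)
  expect_gt(r_true$rho_max, 0.8)
  # y does not drive x: cross-mapping y from x's attractor stays weak
  r_false <- ccm(xv, yv, E = 2, tau = 1, seed = 7)
  expect_lt(r_false$rho_max, 0.5)
  # statistical convergence monotonicity for the true direction
  expect_gt(cor(r_true$lib_sizes, r_true$skill, method = "kendall"), 0)
  # skills always bounded
  expect_true(all(abs(r_true$draws$skill) <= 1 + 1e-12, na.rm = TRUE))

  # full-library sequential CCM is bit-reproducible
  m <- length(xv) - 1
  a1 <- ccm(yv, xv, 2, 1, lib_sizes = m, sampling = "sequential")
  a2 <- ccm(yv, xv, 2, 1, lib_sizes = m, sampling = "sequential")
  expect_identical(a1$skill, a2$skill)
})

test_that("extended ccm separates lagged causality from synchrony", {
  sim <- simulate_coupled_logistic(coupled_map_config())
  xv <- ut_channel(sim$x, 1); yv <- ut_channel(sim$y, 1)
  # y responds to x_{t-1}: testing "x causes y" peaks at a negative delay
  e_true <- extended_ccm(yv, xv, E = 2, tau = 1, delays = -5:5)
  expect_lt(e_true$peak_delay, 0)
  expect_true(e_true$true_causal)
  expect_length(e_true$skill_by_delay, 11)

  # instantaneous copy: peak at 0, synchrony (not true causality)
  e_copy <- extended_ccm(xv, xv, E = 2, tau = 1, delays = -5:5)
  expect_equal(e_copy$peak_delay, 0)
  expect_false(e_copy$true_causal)

  # a stochastic copy behaves the same way
  ar <- ut_channel(simulate_linear_stochastic(0.6, n = 400, seed = 3), 1)
  e_ar <- extended_ccm(ar, ar, E = 2, tau = 1, delays = -5:5)
  expect_equal(e_ar$peak_delay, 0)

  # permuting the delay grid permutes results identically
  e_perm <- extended_ccm(yv, xv, E = 2, tau = 1, delays = c(3, -5, 0, 5, -1))
  sel <- match(e_perm$delays, e_true$delays)
  expect_equal(e_perm$skill_by_delay, e_true$skill_by_delay[sel])

  expect_error(extended_ccm(xv, yv, 2, 1, delays = 0:5), "span negative")
  expect_error(extended_ccm(xv[1:30], yv[1:30], 2, 1, delays = -29:29),
               "feasible range")
})

test_that("classification applies the threshold/convergence/delay rules", {
  # both directions strong and truly causal -> bidirectional
  cl <- classify_interaction(fake_ccm(0.9, TRUE), fake_ccm(0.85, TRUE,
                                                           "B", "A"),
                             fake_ext(-2), fake_ext(-1))
  expect_equal(cl$a_drives_b, "strong")
  expect_equal(cl$summary, "bidirectional")
  expect_false(cl$synchrony_suspected)

  # one strong/true, other absent -> unidirectional
  cl2 <- classify_interaction(fake_ccm(0.9, TRUE), fake_ccm(0.2, FALSE,
                                                            "B", "A"),
                              fake_ext(-2), fake_ext(-1))
  expect_equal(cl2$summary, "unidirectional")
  expect_equal(cl2$b_drives_a, "absent")

  # rho_max 0.85 and converged but peak at +3: demoted, synchrony flagged
  cl3 <- classify_interaction(fake_ccm(0.85, TRUE), fake_ccm(0.2, FALSE,
                                                             "B", "A"),
                              fake_ext(3), fake_ext(-1))
  expect_equal(cl3$a_drives_b, "absent")
  expect_true(cl3$synchrony_suspected)
  expect_equal(cl3$summary, "none")

  # weak band (0.5, 0.8]
  cl4 <- classify_interaction(fake_ccm(0.7, TRUE), fake_ccm(0.4, TRUE,
                                                            "B", "A"),
                              fake_ext(-1), fake_ext(-2))
  expect_equal(cl4$a_drives_b, "weak")
  expect_equal(cl4$summary, "unidirectional")

  # purity: identical inputs give identical labels
  expect_identical(cl3[c("a_drives_b", "b_drives_a", "summary")],
                   classify_interaction(fake_ccm(0.85, TRUE),
                                        fake_ccm(0.2, FALSE, "B", "A"),
                                        fake_ext(3), fake_ext(-1))[
                     c("a_drives_b", "b_drives_a", "summary")])

  # mismatched pair metadata rejected
  expect_error(classify_interaction(fake_ccm(0.9, TRUE),
                                    fake_ccm(0.9, TRUE, "C", "D"),
                                    fake_ext(-1), fake_ext(-1)),
               "mismatched pair")
})
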