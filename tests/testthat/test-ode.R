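test_that("function library enumerates monomials and derivatives", {
  lib <- function_library(c("u", "v"), 2)
  expect_equal(lib$terms[1], "1")
  expect_setequal(lib$terms, c("1", "u", "v", "u^2", "u*v", "v^2"))
  th <- eval_library(lib, rbind(c(2, 3)))
  expect_equal(as.numeric(th[1, match(c("1", "u", "v", "u^2", "u*v", "v^2"),
                                      lib$terms)]),
               c(1, 2, 3, 4, 6, 9))
  # d/du of u*v is v
  dd <- diybot:::eval_library_deriv(lib, rbind(c(2, 3)), 1)
  expect_equal(dd[1, match("u*v", lib$terms)], 3)
  expect_equal(dd[1, match("v^2", lib$terms)], 0)
})

test_that("estimate_derivatives matches analytic derivatives", {
  # linear ramp: interior exact
  t <- seq(0, 10, by = 0.1)
  d <- estimate_derivatives(matrix(3 * t, ncol = 1), step = 0.1)
  expect_equal(as.numeric(d[2:100]), rep(3, 99), tolerance = 1e-10)
  # sin(t): max interior error O(step^2) against cos(t)
  d2 <- estimate_derivatives(matrix(sin(t), ncol = 1), step = 0.1)
  expect_lt(max(abs(d2[2:100] - cos(t)[2:100])), 0.1^2)
  # constant: zero everywhere
  expect_equal(as.numeric(estimate_derivatives(matrix(5, 10, 1), step = 1)),
               rep(0, 10))
  expect_error(estimate_derivatives(matrix(1:4, ncol = 1)), "at least 5")
  expect_error(estimate_derivatives(matrix(1:10, ncol = 1), method = "x"),
               "unknown derivative method")
})

test_that("sindy_fit recovers the spiral-sink system exactly", {
  sys <- spiral_sink_system(noise_sd = 0)
  ts <- simulate_spiral_sink(sys)
  states <- ts$values
  # exact derivatives from the generator (the oracle coefficients)
  derivs <- t(apply(states, 1, function(x)
    sys$state_matrix %*% (x - sys$equilibrium)))
  fit <- sindy_fit(states, derivs)
  lin <- fit$coefficients[c("x1", "x2", "x3"), ]
  expect_lt(max(abs(t(lin) - sys$state_matrix)), 1e-6)
  expect_lt(max(abs(fit$coefficients["1", ] -
                      as.numeric(-sys$state_matrix %*% sys$equilibrium))),
            1e-6)
  quad <- setdiff(rownames(fit$coefficients), c("1", "x1", "x2", "x3"))
  expect_true(all(fit$coefficients[quad, ] == 0))

  # sparsity fixed point: refitting with the returned active set reproduces
  # the same coefficients
  refit <- sindy_fit(states, derivs)
  expect_identical(fit$coefficients, refit$coefficients)

  # duplicated rows leave the least-squares fit unchanged
  fit2 <- sindy_fit(rbind(states, states), rbind(derivs, derivs))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-8)

  # threshold above every coefficient: degenerate all-zero model, flagged
  expect_warning(fit0 <- sindy_fit(states, derivs, threshold = 1e6),
                 "degenerate")
  expect_true(all(fit0$coefficients == 0))
  expect_true(fit0$degenerate)
})

test_that("integrate_model reproduces the closed form and converges at 4th order", {
  sys <- spiral_sink_system(noise_sd = 0)
  ts <- simulate_spiral_sink(sys)
  derivs <- t(apply(ts$values, 1, function(x)
    sys$state_matrix %*% (x - sys$equilibrium)))
  model <- sindy_fit(ts$values, derivs)

  # equilibrium start: constant trajectory
  tr_eq <- integrate_model(model, sys$equilibrium, 0.1, 20)
  expect_equal(tr_eq$values, matrix(rep(sys$equilibrium, each = 20), 20, 3),
               tolerance = 1e-8, ignore_attr = TRUE)

  # trajectory matches the generator closed form over 10 time units
  tr <- integrate_model(model, sys$initial_state, 0.1, 101)
  truth <- t(sapply(0:100, function(k) as.numeric(
    Matrix::expm(sys$state_matrix * k * 0.1) %*%
      (sys$initial_state - sys$equilibrium)) + sys$equilibrium))
  expect_lt(sqrt(mean((tr$values - truth)^2)), 1e-3)

  # step halving: terminal error drops ~16x (4th order)
  err_at <- function(h) {
    n <- round(5 / h) + 1
    trh <- integrate_model(model, sys$initial_state, h, n)
    tru <- as.numeric(Matrix::expm(sys$state_matrix * 5) %*%
                        (sys$initial_state - sys$equilibrium)) +
      sys$equilibrium
    sqrt(sum((trh$values[n, ] - tru)^2))
  }
  ratio <- err_at(0.2) / err_at(0.1)
  expect_gt(ratio, 8)   # consistent with O(step^4)

  # divergence halted with the step index
  bad <- model
  bad$coefficients["x1", 1] <- 5    # unstable direction
  expect_error(integrate_model(bad, sys$initial_state + 10, 0.5, 500),
               "diverged at step")
})

test_that("find_equilibria locates and deduplicates roots", {
  sys <- spiral_sink_system(noise_sd = 0)
  ts <- simulate_spiral_sink(sys)
  derivs <- t(apply(ts$values, 1, function(x)
    sys$state_matrix %*% (x - sys$equilibrium)))
  model <- sindy_fit(ts$values, derivs)
  box <- cbind(sys$equilibrium - 20, sys$equilibrium + 20)
  eqs <- find_equilibria(model, box, n_starts = 10, seed = 2)
  expect_equal(nrow(eqs$equilibria), 1)       # linear model: single root
  expect_equal(as.numeric(eqs$equilibria[1, ]), sys$equilibrium,
               tolerance = 1e-6)

  # 1-D cubic with known roots: all found inside the box, no duplicates
  lib1 <- function_library("x", 3)
  cub <- structure(list(
    library = lib1, state_names = "x",
    coefficients = matrix(c(0, -6, 11, -6), 4, 1,
                          dimnames = list(lib1$terms, "x"))),
    class = "ode_model")
  # rhs = -6x + 11x^2 - 6x^3 = -x(6 - 11x + 6x^2) -> roots 0 only (complex
  # pair otherwise); use (x-0)(x-1)(x-2) = x^3 - 3x^2 + 2x instead, negated
  cub$coefficients[, 1] <- c(0, -2, 3, -1)    # -(x^3 - 3x^2 + 2x)
  eqs2 <- find_equilibria(cub, rbind(c(-1, 3)), n_starts = 40, seed = 3)
  roots <- sort(as.numeric(eqs2$equilibria))
  expect_equal(roots, c(0, 1, 2), tolerance = 1e-6)
})

test_that("eigenvalue classification implements the spiral-sink rule", {
  expect_equal(classify_eigenvalues(c(-0.5, complex(real = -0.1, imaginary = 1),
                                      complex(real = -0.1, imaginary = -1))),
               "spiral_sink")
  expect_equal(classify_eigenvalues(c(-1, -1, -1)), "node_sink")
  expect_equal(classify_eigenvalues(c(1, -1, -2)), "saddle")
  expect_equal(classify_eigenvalues(c(1, 2, 3)), "source")
  expect_equal(classify_eigenvalues(complex(real = c(0, 0),
                                            imaginary = c(1, -1))), "center")

  # full analysis at a model equilibrium
  sys <- spiral_sink_system(noise_sd = 0)
  ts <- simulate_spiral_sink(sys)
  derivs <- t(apply(ts$values, 1, function(x)
    sys$state_matrix %*% (x - sys$equilibrium)))
  model <- sindy_fit(ts$values, derivs)
  ea <- eigen_classify(model, sys$equilibrium)
  expect_equal(ea$classification, "spiral_sink")
  expect_equal(sort(Re(ea$eigenvalues)), sort(Re(eigen(sys$state_matrix)$values)),
               tolerance = 1e-6)
  expect_error(eigen_classify(model, sys$equilibrium + 5), "not an equilibrium")
})

test_that("marginal impacts: constant for linear RHS, decaying sensitivity on a sink", {
  sys <- spiral_sink_system(noise_sd = 0)
  ts <- simulate_spiral_sink(sys)
  derivs <- t(apply(ts$values, 1, function(x)
    sys$state_matrix %*% (x - sys$equilibrium)))
  model <- sindy_fit(ts$values, derivs)
  traj <- integrate_model(model, sys$initial_state, 0.1, 800)

  # instantaneous impact of a linear model is the Jacobian entry, constant
  mi <- marginal_impacts(model, traj, driver = "x1", response = "x2")
  expect_equal(mi$values, rep(sys$state_matrix[2, 1], 800), tolerance = 1e-6)

  # an explicit interaction term c * driver * response gives c * response(t)
  lib2 <- function_library(c("a", "b"), 2)
  co <- matrix(0, lib2$p, 2, dimnames = list(lib2$terms, c("a", "b")))
  co[match("a*b", lib2$terms), "b"] <- 0.3
  toy <- structure(list(library = lib2, state_names = c("a", "b"),
                        coefficients = co), class = "ode_model")
  states <- cbind(a = seq(1, 2, length.out = 10), b = seq(3, 1, length.out = 10))
  mi2 <- marginal_impacts(toy, states, "a", "b", step = 1)
  expect_equal(mi2$values, 0.3 * states[, "b"])

  # propagated sensitivity on a sink decays to zero as the trajectory
  # approaches equilibrium
  mi3 <- marginal_impacts(model, traj, driver = "x1", response = "x2",
                          tol = 1e-3, type = "propagated")
  expect_true(mi3$decayed)
  expect_lt(max(abs(mi3$values[mi3$decayed_to_zero_by:800])), 1e-3)
  expect_gt(max(abs(mi3$values)), 0.1)   # nontrivial early impact
  # oracle: the propagated impact is the matrix-exponential entry
  phi_true <- vapply(0:799, function(k)
    as.numeric(Matrix::expm(sys$state_matrix * k * 0.1))[2], 0)
  expect_equal(mi3$values, phi_true, tolerance = 1e-3)

  expect_error(marginal_impacts(model, traj, "zz", "x1"), "unknown driver")
})
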