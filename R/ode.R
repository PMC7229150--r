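#' Polynomial candidate function library
#'
#' All monomials in the state variables up to `degree` (constant term first,
#' then ordered by total degree and lexicographically). The library knows how
#' to evaluate itself on a state matrix and how to differentiate its terms
#' analytically, which gives exact Jacobians for the fitted models.
#'
#' @param state_names character vector of state variable names.
#' @param degree maximum total degree (default 2).
#' @return object of class `function_library` with the `p x d` exponent
#'   matrix `exponents` (one row per term).
#' @export
function_library <- function(state_names, degree = 2L) {
  d <- length(state_names)
  if (d < 1) stop("need at least one state")
  grids <- rep(list(0:degree), d)
  expo <- as.matrix(do.call(expand.grid, grids))
  expo <- expo[rowSums(expo) <= degree, , drop = FALSE]
  expo <- expo[order(rowSums(expo),
                     apply(expo, 1, paste, collapse = ",")), , drop = FALSE]
  colnames(expo) <- state_names
  rownames(expo) <- NULL
  terms <- apply(expo, 1, function(p) {
    if (all(p == 0)) return("1")
    parts <- mapply(function(nm, pw) {
      if (pw == 0) "" else if (pw == 1) nm else sprintf("%s^%d", nm, pw)
    }, state_names, p)
    paste(parts[parts != ""], collapse = "*")
  })
  structure(list(state_names = state_names, degree = as.integer(degree),
                 exponents = expo, terms = terms, p = nrow(expo)),
            class = "function_library")
}

#' Evaluate a function library on a state matrix
#'
#' @param library a [function_library()].
#' @param states `m x d` state matrix (or a d-vector for a single state).
#' @return `m x p` design matrix.
#' @export
eval_library <- function(library, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  states <- as.matrix(states)
  m <- nrow(states)
  out <- matrix(1, m, library$p)
  for (t in seq_len(library$p)) {
    p <- library$exponents[t, ]
    for (j in which(p > 0)) out[, t] <- out[, t] * states[, j]^p[j]
  }
  colnames(out) <- library$terms
  out
}

# m x p matrix of d(term)/d(state j) evaluated on states.
eval_library_deriv <- function(library, states, j) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  states <- as.matrix(states)
  m <- nrow(states)
  out <- matrix(0, m, library$p)
  for (t in seq_len(library$p)) {
    p <- library$exponents[t, ]
    if (p[j] == 0) next
    val <- rep(p[j], m)
    pd <- p; pd[j] <- pd[j] - 1
    for (jj in which(pd > 0)) val <- val * states[, jj]^pd[jj]
    out[, t] <- val
  }
  out
}

#' Estimate time derivatives of a multichannel record
#'
#' Centered finite differences on interior points, one-sided at the edges.
#' Optionally pre-smooths each channel with the SSA signal reconstruction
#' before differencing (the model is meant to be fit to processed signals,
#' not raw records).
#'
#' @param ts `uniform_ts` or numeric matrix.
#' @param step sampling interval when `ts` is a bare matrix.
#' @param method only `"central"` is provided.
#' @param smoothing `NULL` (none) or `"ssa"`.
#' @param ssa_window window length for the smoothing decomposition.
#' @return matrix of derivative estimates, same shape as the input values.
#' @export
estimate_derivatives <- function(ts, step = NULL, method = "central",
                                 smoothing = NULL, ssa_window = NULL) {
  if (!identical(method, "central"))
    stop("unknown derivative method '", method, "'")
  vals <- if (inherits(ts, "uniform_ts")) ts$values else as.matrix(ts)
  h <- if (inherits(ts, "uniform_ts")) ts$step else step %||% 1
  n <- nrow(vals)
  if (n < 5) stop("need at least 5 samples to estimate derivatives")
  if (identical(smoothing, "ssa")) {
    vals <- apply(vals, 2, function(x) {
      dec <- ssa_group(ssa_decompose(x, ssa_window))
      sig <- grep("^signal", names(dec$groups), value = TRUE)
      rowSums(dec$reconstructed[, sig, drop = FALSE])
    })
  }
  d <- matrix(0, n, ncol(vals))
  d[2:(n - 1), ] <- (vals[3:n, , drop = FALSE] - vals[1:(n - 2), , drop = FALSE]) / (2 * h)
  d[1, ] <- (vals[2, ] - vals[1, ]) / h
  d[n, ] <- (vals[n, ] - vals[n - 1, ]) / h
  colnames(d) <- colnames(vals)
  d
}

#' Sparse ODE discovery by sequentially thresholded least squares
#'
#' Fits `dx/dt = Theta(x) Xi` one equation at a time: solve least squares on
#' the column-normalized design, zero every coefficient whose normalized
#' magnitude falls below `threshold`, re-solve on the surviving (active)
#' terms, and iterate to a fixed point. The returned coefficients come from
#' an un-penalized least-squares refit on the final active set in the
#' original scale, so on noise-free data representable by the library the
#' recovery is exact to solver precision.
#'
#' @param states `m x d` state matrix (or `uniform_ts`).
#' @param derivatives `m x d` matrix of matching time derivatives.
#' @param library a [function_library()]; default degree-2 polynomials in
#'   the state columns.
#' @param threshold sparsification threshold on the normalized coefficients
#'   (default 0.05).
#' @param max_iter maximum threshold/refit iterations (default 25).
#' @param ridge optional ridge penalty used during selection only
#'   (default 0).
#' @return object of class `ode_model`: `coefficients` (`p x d`, one column
#'   per state equation), `active_terms`, `fit_diagnostics` (per-equation
#'   residual RMS), plus the library.
#' @export
sindy_fit <- function(states, derivatives, library = NULL, threshold = 0.05,
                      max_iter = 25L, ridge = 0) {
  if (inherits(states, "uniform_ts")) states <- states$values
  states <- as.matrix(states)
  derivatives <- as.matrix(derivatives)
  if (!all(dim(states) == dim(derivatives)) && nrow(states) != nrow(derivatives))
    stop("states and derivatives must be row-aligned")
  d <- ncol(states)
  nms <- colnames(states) %||% paste0("x", seq_len(d))
  library <- library %||% function_library(nms, 2L)
  theta <- eval_library(library, states)
  m <- nrow(theta); p <- ncol(theta)
  if (p >= m) stop("need more samples than library terms (p < m)")
  cn <- sqrt(colMeans(theta^2))
  cn[cn == 0] <- 1
  theta_n <- sweep(theta, 2, cn, "/")
  coefs <- matrix(0, p, d, dimnames = list(library$terms, nms))
  rms <- numeric(d)
  solve_ls <- function(a, b, lambda) {
    if (lambda > 0) {
      ata <- crossprod(a) + diag(lambda, ncol(a))
      solve(ata, crossprod(a, b))
    } else qr.coef(qr(a), b)
  }
  for (eq in seq_len(d)) {
    y <- derivatives[, eq]
    sy <- stats::sd(y)
    if (sy == 0) sy <- 1
    active <- rep(TRUE, p)
    b_n <- rep(0, p)
    for (it in seq_len(max_iter)) {
      a <- theta_n[, active, drop = FALSE]
      qa <- qr(a)
      if (qa$rank < ncol(a)) {
        kappa <- kappa(a, exact = FALSE)
        stop(sprintf("rank-deficient active design matrix in equation %d ('%s'); condition number ~ %.3g",
                     eq, nms[eq], kappa))
      }
      b <- qr.coef(qa, y / sy)
      if (ridge > 0) b <- solve_ls(a, y / sy, ridge)
      b_new <- rep(0, p)
      b_new[active] <- b
      keep <- abs(b_new) >= threshold
      if (!any(keep)) { active <- keep; b_n <- rep(0, p); break }
      if (identical(keep, active) || it == max_iter) {
        active <- keep; b_n <- b_new * keep; break
      }
      active <- keep
    }
    if (any(active)) {
      # final un-penalized refit in the original scale
      a <- theta[, active, drop = FALSE]
      qa <- qr(a)
      if (qa$rank < ncol(a))
        stop(sprintf("rank-deficient active design matrix in equation %d ('%s'); condition number ~ %.3g",
                     eq, nms[eq], kappa(a, exact = FALSE)))
      coefs[active, eq] <- qr.coef(qa, y)
    }
    rms[eq] <- sqrt(mean((theta %*% coefs[, eq] - y)^2))
  }
  degenerate <- all(coefs == 0)
  if (degenerate)
    warning("all coefficients thresholded to zero: degenerate model")
  structure(list(library = library, coefficients = coefs,
                 state_names = nms,
                 active_terms = apply(coefs != 0, 2, function(a)
                   library$terms[a], simplify = FALSE),
                 fit_diagnostics = stats::setNames(rms, nms),
                 threshold = threshold, ridge = ridge,
                 degenerate = degenerate),
            class = "ode_model")
}

#' Render the fitted equations as text
#' @param model an `ode_model`.
#' @export
render_equations <- function(model) {
  vapply(seq_along(model$state_names), function(eq) {
    co <- model$coefficients[, eq]
    act <- which(co != 0)
    rhs <- if (!length(act)) "0" else paste(
      sprintf("%+.4g*%s", co[act], model$library$terms[act]), collapse = " ")
    rhs <- gsub("\\*1\\b", "", rhs)
    sprintf("d%s/dt = %s", model$state_names[eq], rhs)
  }, "")
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model>\n")
  for (ln in render_equations(x)) cat(" ", ln, "\n")
  invisible(x)
}

# RHS of the fitted model at a state vector (or matrix of states).
model_rhs <- function(model, x) {
  eval_library(model$library, x) %*% model$coefficients
}

# Analytic Jacobian of the model RHS at a single state.
model_jacobian <- function(model, x) {
  d <- length(model$state_names)
  jac <- matrix(0, d, d, dimnames = list(model$state_names, model$state_names))
  for (j in seq_len(d)) {
    jac[, j] <- as.numeric(
      eval_library_deriv(model$library, x, j) %*% model$coefficients)
  }
  jac
}

#' Integrate a fitted ODE model
#'
#' Fixed-step 4th-order Runge-Kutta. Halts with an error (reporting the step
#' index) if the state norm exceeds `max_norm`, which signals a divergent
#' model rather than an integrator failure.
#'
#' @param model an `ode_model`.
#' @param x0 initial state.
#' @param step time step.
#' @param n_steps number of output samples (including `x0`).
#' @param max_norm divergence bound (default 1e6).
#' @return `uniform_ts` with the model states as channels.
#' @export
integrate_model <- function(model, x0, step, n_steps, max_norm = 1e6) {
  d <- length(model$state_names)
  x <- as.numeric(x0)
  if (length(x) != d) stop("x0 must have length ", d)
  out <- matrix(0, n_steps, d)
  out[1, ] <- x
  rhs <- function(v) as.numeric(model_rhs(model, v))
  for (k in 2:n_steps) {
    k1 <- rhs(x)
    k2 <- rhs(x + step / 2 * k1)
    k3 <- rhs(x + step / 2 * k2)
    k4 <- rhs(x + step * k3)
    x <- x + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(x)) || sqrt(sum(x * x)) > max_norm)
      stop("model trajectory diverged at step ", k)
    out[k, ] <- x
  }
  uniform_ts(out, step, model$state_names, time_unit = "model time")
}

#' Locate equilibria of a fitted model
#'
#' Multi-start damped Newton iteration on the model RHS inside a search box;
#' roots closer than `merge_tol` are merged, and only roots with residual
#' norm below `tol` are reported. Finding no root returns an empty set with
#' diagnostics rather than an error.
#'
#' @param model an `ode_model`.
#' @param search_box `d x 2` matrix of (lower, upper) bounds per state.
#' @param n_starts random starts (default 25; the box center is always
#'   included).
#' @param tol residual tolerance (default 1e-8).
#' @param seed RNG seed for the starts.
#' @param merge_tol duplicate-merge radius (default `1e-6 * box scale`).
#' @return list with `equilibria` (matrix, possibly 0 rows) and `diagnostics`.
#' @export
find_equilibria <- function(model, search_box, n_starts = 25L, tol = 1e-8,
                            seed = 1L, merge_tol = NULL) {
  d <- length(model$state_names)
  search_box <- as.matrix(search_box)
  if (!all(dim(search_box) == c(d, 2))) stop("search_box must be d x 2")
  scale <- max(search_box[, 2] - search_box[, 1], 1)
  merge_tol <- merge_tol %||% (1e-6 * scale)
  starts <- with_seed(seed, {
    s <- matrix(stats::runif(n_starts * d, search_box[, 1], search_box[, 2]),
                ncol = d, byrow = TRUE)
    rbind(rowMeans(search_box), s)
  })
  roots <- list(); tried <- 0L; converged <- 0L
  for (r in seq_len(nrow(starts))) {
    x <- starts[r, ]
    tried <- tried + 1L
    ok <- FALSE
    for (it in 1:60) {
      f <- as.numeric(model_rhs(model, x))
      fn <- sqrt(sum(f * f))
      if (fn < tol) { ok <- TRUE; break }
      j <- model_jacobian(model, x)
      dx <- tryCatch(solve(j, -f), error = function(e) NULL)
      if (is.null(dx)) break
      lam <- 1
      repeat {
        xn <- x + lam * dx
        fn2 <- sqrt(sum(as.numeric(model_rhs(model, xn))^2))
        if (fn2 < fn || lam < 1e-6) break
        lam <- lam / 2
      }
      if (sqrt(sum((xn - x)^2)) < 1e-14 * scale) { x <- xn; break }
      x <- xn
    }
    f <- as.numeric(model_rhs(model, x))
    if ((ok || sqrt(sum(f * f)) < tol) && all(is.finite(x))) {
      converged <- converged + 1L
      dup <- any(vapply(roots, function(rt)
        sqrt(sum((rt - x)^2)) < merge_tol, TRUE))
      if (!dup) roots[[length(roots) + 1]] <- x
    }
  }
  eq <- if (length(roots)) do.call(rbind, roots) else
    matrix(numeric(0), 0, d)
  colnames(eq) <- model$state_names
  list(equilibria = eq,
       diagnostics = list(starts = tried, converged = converged,
                          tol = tol, merge_tol = merge_tol))
}

#' Classify an eigenvalue spectrum
#'
#' `spiral_sink` when all real parts are negative and at least one conjugate
#' complex pair is present (for 3-D systems: one negative real eigenvalue
#' plus a complex pair with negative real parts); `node_sink` when all real
#' parts are negative with no complex pair; `source` when all positive;
#' `saddle` for mixed nonzero signs; `center` for a purely imaginary pair;
#' `other` otherwise.
#'
#' @param eigenvalues complex vector.
#' @param tol tolerance for treating a real part / imaginary part as zero.
#' @return one of `"spiral_sink"`, `"node_sink"`, `"saddle"`, `"source"`,
#'   `"center"`, `"other"`.
#' @export
classify_eigenvalues <- function(eigenvalues, tol = 1e-8) {
  re <- Re(eigenvalues); im <- Im(eigenvalues)
  has_pair <- any(abs(im) > tol)
  if (all(re < -tol)) return(if (has_pair) "spiral_sink" else "node_sink")
  if (all(re > tol)) return("source")
  if (any(abs(re) <= tol) && has_pair) return("center")
  if (any(re > tol) && any(re < -tol)) return("saddle")
  "other"
}

#' Eigenvalue stability analysis at an equilibrium
#'
#' Evaluates the analytic Jacobian of the library RHS at the equilibrium and
#' classifies the spectrum per [classify_eigenvalues()].
#'
#' @param model an `ode_model`.
#' @param equilibrium state vector with RHS residual below `residual_tol`.
#' @param residual_tol acceptance tolerance on the equilibrium residual.
#' @return object of class `equilibrium_analysis` with `equilibrium`,
#'   `jacobian`, `eigenvalues`, `classification` and a reciprocal condition
#'   estimate of the eigenproblem.
#' @export
eigen_classify <- function(model, equilibrium, residual_tol = 1e-6) {
  f <- as.numeric(model_rhs(model, equilibrium))
  res <- sqrt(sum(f * f))
  if (res > residual_tol)
    stop(sprintf("point is not an equilibrium: residual norm %.3g > %.3g",
                 res, residual_tol))
  jac <- model_jacobian(model, equilibrium)
  es <- eigen(jac)
  rc <- rcond(jac)
  structure(list(equilibrium = as.numeric(equilibrium), jacobian = jac,
                 eigenvalues = es$values,
                 classification = classify_eigenvalues(es$values),
                 rcond = rc, residual = res),
            class = "equilibrium_analysis")
}

#' @export
print.equilibrium_analysis <- function(x, ...) {
  cat(sprintf("<equilibrium_analysis> %s; eigenvalues: %s\n",
              x$classification,
              paste(format(x$eigenvalues, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Marginal impact of one state on another along a trajectory
#'
#' `type = "instantaneous"` (default) evaluates the symbolic partial
#' derivative of the response equation's RHS with respect to the driver
#' state along the trajectory: the contract quantity, constant for a linear
#' model. `type = "propagated"` integrates the variational equation
#' `Phi' = J(x(t)) Phi`, `Phi(0) = I`, and reports
#' `d x_response(t) / d x_driver(0)` — the effect of an incremental increase
#' in the driver at time zero on the response later, which decays to zero on
#' a sink and is the quantity behind "the impact decays to zero as time
#' progresses".
#'
#' @param model an `ode_model`.
#' @param trajectory `uniform_ts` (e.g. from [integrate_model()]) or state
#'   matrix; `step` needed for the propagated type when a bare matrix is
#'   given.
#' @param driver,response state names.
#' @param tol decay tolerance (default 1e-3).
#' @param type `"instantaneous"` or `"propagated"`.
#' @param step trajectory time step for bare matrices.
#' @return object of class `marginal_impact`: `values` time series,
#'   `decayed_to_zero_by` (first time index from which |impact| stays below
#'   `tol`, or NA with `decayed = FALSE`).
#' @export
marginal_impacts <- function(model, trajectory, driver, response, tol = 1e-3,
                             type = c("instantaneous", "propagated"),
                             step = NULL) {
  type <- match.arg(type)
  if (!driver %in% model$state_names) stop("unknown driver '", driver, "'")
  if (!response %in% model$state_names) stop("unknown response '", response, "'")
  vals <- if (inherits(trajectory, "uniform_ts")) trajectory$values
  else as.matrix(trajectory)
  h <- if (inherits(trajectory, "uniform_ts")) trajectory$step else step %||% 1
  dj <- match(driver, model$state_names)
  ri <- match(response, model$state_names)
  n <- nrow(vals)
  if (type == "instantaneous") {
    imp <- as.numeric(
      eval_library_deriv(model$library, vals, dj) %*% model$coefficients[, ri])
  } else {
    d <- length(model$state_names)
    phi <- diag(d)
    imp <- numeric(n)
    imp[1] <- phi[ri, dj]
    for (k in 2:n) {
      # RK4 on Phi' = J(x(t)) Phi, with J frozen per stage at nearby states
      j1 <- model_jacobian(model, vals[k - 1, ])
      jm <- model_jacobian(model, (vals[k - 1, ] + vals[k, ]) / 2)
      j2 <- model_jacobian(model, vals[k, ])
      k1 <- j1 %*% phi
      k2 <- jm %*% (phi + h / 2 * k1)
      k3 <- jm %*% (phi + h / 2 * k2)
      k4 <- j2 %*% (phi + h * k3)
      phi <- phi + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      imp[k] <- phi[ri, dj]
    }
  }
  below <- abs(imp) < tol
  run <- rev(cumprod(rev(below)))    # 1 where |impact| < tol from here to end
  idx <- if (any(run == 1)) which(run == 1)[1] else NA_integer_
  structure(list(driver = driver, response = response, values = imp,
                 type = type, tol = tol,
                 decayed = !is.na(idx), decayed_to_zero_by = idx,
                 step = h),
            class = "marginal_impact")
}

#' @export
print.marginal_impact <- function(x, ...) {
  cat(sprintf("<marginal_impact> d(d%s/dt)/d%s [%s]: %s\n",
              x$response, x$driver, x$type,
              if (x$decayed)
                sprintf("decays below %g by index %d", x$tol,
                        x$decayed_to_zero_by)
              else "not decayed within the trajectory"))
  invisible(x)
}

#' Serialize an ODE model to JSON
#' @param model an `ode_model`.
#' @param path output path.
#' @export
model_to_json <- function(model, path) {
  jsonlite::write_json(
    list(state_names = model$state_names,
         terms = model$library$terms,
         degree = model$library$degree,
         coefficients = model$coefficients,
         threshold = model$threshold,
         fit_diagnostics = as.list(model$fit_diagnostics),
         equations = render_equations(model)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
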