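#' Nonlinear cross prediction stationarity test
#'
#' Splits the series into `n_segments` contiguous equal segments; each
#' segment is z-scored (so slow amplitude drift does not masquerade as a
#' change of dynamics) and delay-embedded, and every ordered pair `(i, j)`
#' is scored by forecasting segment `j` one step ahead from nearest
#' neighbors in segment `i`'s embedding. Errors are root-mean-square in the
#' normalized units. The series is declared nonstationary when any segment's
#' mean error as a library (row) or as a target (column) exceeds `factor`
#' times the grand mean.
#'
#' @param ts single-channel series.
#' @param n_segments number of segments (default 4).
#' @param E,tau embedding parameters for the segment embeddings.
#' @param k neighbors used by the locally constant predictor (default 3).
#' @param factor heterogeneity threshold (default 2).
#' @return object of class `cross_prediction_result` with the
#'   `n_segments x n_segments` error matrix, the `heterogeneity_score`
#'   (worst row/column mean over grand mean) and the `stationary` verdict.
#' @export
nonlinear_cross_prediction <- function(ts, n_segments = 4L, E = 3L, tau = 1L,
                                       k = 3L, factor = 2) {
  x <- embed_input_vector(ts)
  n <- length(x)
  seg_len <- floor(n / n_segments)
  min_len <- (E - 1) * tau + k + 3
  if (seg_len < min_len)
    stop(sprintf("segments too short for the embedding: need >= %d samples per segment, have %d",
                 min_len, seg_len))
  segs <- lapply(seq_len(n_segments), function(i)
    x[((i - 1) * seg_len + 1):(i * seg_len)])
  segs <- lapply(segs, function(s) {
    sdv <- stats::sd(s)
    if (sdv == 0) stop("constant segment: cross prediction undefined")
    (s - mean(s)) / sdv
  })
  embs <- lapply(segs, function(s) delay_embed(s, E, tau))
  err <- matrix(0, n_segments, n_segments)
  for (i in seq_len(n_segments)) {
    for (j in seq_len(n_segments)) {
      ei <- embs[[i]]; ej <- embs[[j]]
      lib_ok <- which(ei$ref_index + 1 <= ei$source_length)
      prd_ok <- which(ej$ref_index + 1 <= ej$source_length)
      lib_next <- segs[[i]][ei$ref_index[lib_ok] + 1]
      truth <- segs[[j]][ej$ref_index[prd_ok] + 1]
      dm <- cross_dist(ej$points[prd_ok, , drop = FALSE],
                       ei$points[lib_ok, , drop = FALSE])
      preds <- vapply(seq_along(prd_ok), function(r) {
        dvec <- dm[r, ]
        if (i == j) dvec[lib_ok == prd_ok[r]] <- Inf  # exclude self in-sample
        ord <- order(dvec)[seq_len(k)]
        mean(lib_next[ord])
      }, 0)
      err[i, j] <- sqrt(mean((preds - truth)^2))
    }
  }
  grand <- mean(err)
  score <- max(c(rowMeans(err), colMeans(err))) / grand
  structure(list(n_segments = n_segments, error_matrix = err,
                 heterogeneity_score = score, factor = factor,
                 stationary = score <= factor,
                 params = list(E = E, tau = tau, k = k)),
            class = "cross_prediction_result")
}

#' @export
print.cross_prediction_result <- function(x, ...) {
  cat(sprintf("<cross_prediction_result> %d segments, heterogeneity %.3f (threshold %.2f): %s\n",
              x$n_segments, x$heterogeneity_score, x$factor,
              if (x$stationary) "stationary" else "NONSTATIONARY"))
  invisible(x)
}

#' IAAFT surrogate series
#'
#' Iterative amplitude-adjusted Fourier transform surrogates: each surrogate
#' has exactly the original's sorted amplitude distribution and
#' approximately its power spectrum, i.e. it realizes the null hypothesis of
#' a (possibly monotonically transformed) linear Gaussian process. Iteration
#' alternates spectral adjustment and rank remapping, ending on the rank
#' remap so the amplitude multiset is exact.
#'
#' @param ts single-channel series.
#' @param n_surrogates how many surrogates (>= 1).
#' @param seed integer RNG seed; fixed seed gives a reproducible set.
#' @param max_iter maximum IAAFT iterations per surrogate (default 100).
#' @param tol relative spectral-discrepancy change for convergence
#'   (default 1e-8).
#' @return `n x n_surrogates` matrix, one surrogate per column.
#' @export
iaaft_surrogates <- function(ts, n_surrogates = 19L, seed = 1L,
                             max_iter = 100L, tol = 1e-8) {
  x <- embed_input_vector(ts)
  n <- length(x)
  if (n_surrogates < 1) stop("n_surrogates must be >= 1")
  if (stats::sd(x) == 0)
    stop("constant series: phase randomization undefined")
  amp <- Mod(stats::fft(x))
  xs <- sort(x)
  with_seed(seed, {
    vapply(seq_len(n_surrogates), function(s) {
      y <- sample(x)
      prev <- Inf
      for (it in seq_len(max_iter)) {
        f <- stats::fft(y)
        y <- Re(stats::fft(amp * exp(1i * Arg(f)), inverse = TRUE)) / n
        y <- xs[rank(y, ties.method = "first")]
        disc <- sqrt(mean((Mod(stats::fft(y)) - amp)^2)) / sqrt(mean(amp^2))
        if (is.finite(prev) && abs(prev - disc) < tol * max(disc, 1e-300)) break
        prev <- disc
      }
      y
    }, numeric(n))
  })
}

# Registered discriminating statistics. Direction "less": small values
# indicate nonlinear determinism; "abs": two-sided on magnitude.
surrogate_statistics <- function() {
  list(
    prediction_error = list(
      fn = function(x, E, tau) {
        emb <- delay_embed(x, E, tau)
        usable <- which(emb$ref_index + 1 <= emb$source_length)
        target <- x[emb$ref_index[usable] + 1]
        sp <- neighbor_spec(k = E + 1, theiler_window = tau * E)
        res <- simplex_project(emb, target, lib_rows = usable,
                               pred_rows = usable, spec = sp,
                               target_rows = usable)
        sqrt(mean((res$predictions - res$observed)^2)) / stats::sd(x)
      },
      direction = "less"),
    time_asymmetry = list(
      fn = function(x, E, tau) {
        d <- diff(x, lag = tau)
        mean(d^3) / mean(d^2)^1.5
      },
      direction = "abs"))
}

#' Surrogate data test for nonlinear determinism
#'
#' Computes a discriminating statistic on the series and on an ensemble of
#' IAAFT surrogates; the rank-based p-value is
#' `(1 + #(surrogates at least as extreme)) / (n_surrogates + 1)`, one-sided
#' in the direction appropriate to the statistic (smaller prediction error,
#' larger absolute time asymmetry). Rejection at `level` says the apparent
#' structure is unlikely under a linear stochastic null.
#'
#' @param ts single-channel series.
#' @param statistic `"prediction_error"` (one-step simplex forecast error,
#'   the default) or `"time_asymmetry"` (time-reversal asymmetry).
#' @param n_surrogates ensemble size; must be at least `ceiling(1/level)-1`.
#' @param level one-sided test level (default 0.05).
#' @param seed integer RNG seed.
#' @param E,tau embedding parameters for the prediction-error statistic.
#' @param max_iter,tol passed to [iaaft_surrogates()].
#' @return object of class `surrogate_test_result`.
#' @export
surrogate_test <- function(ts, statistic = "prediction_error",
                           n_surrogates = 99L, level = 0.05, seed = 1L,
                           E = 3L, tau = 1L, max_iter = 100L, tol = 1e-8) {
  stats_reg <- surrogate_statistics()
  if (!statistic %in% names(stats_reg))
    stop("unknown statistic '", statistic, "'; registered: ",
         paste(names(stats_reg), collapse = ", "))
  if (n_surrogates < ceiling(1 / level) - 1)
    stop(sprintf("level %g unattainable with %d surrogates (need >= %d)",
                 level, n_surrogates, ceiling(1 / level) - 1))
  x <- embed_input_vector(ts)
  st <- stats_reg[[statistic]]
  observed <- st$fn(x, E, tau)
  surr <- iaaft_surrogates(x, n_surrogates, seed = seed,
                           max_iter = max_iter, tol = tol)
  sv <- apply(surr, 2, st$fn, E = E, tau = tau)
  extreme <- switch(st$direction,
                    less = sum(sv <= observed),
                    abs = sum(abs(sv) >= abs(observed)))
  rank_p <- (1 + extreme) / (n_surrogates + 1)
  structure(list(statistic_name = statistic, observed_value = observed,
                 surrogate_values = sv, n_surrogates = n_surrogates,
                 method = "iaaft", rank_p = rank_p, level = level,
                 reject_linear_null = rank_p <= level),
            class = "surrogate_test_result")
}

#' @export
print.surrogate_test_result <- function(x, ...) {
  cat(sprintf("<surrogate_test_result> %s = %.5g, rank p = %.4f (%d surrogates): %s linear null at %.2g\n",
              x$statistic_name, x$observed_value, x$rank_p, x$n_surrogates,
              if (x$reject_linear_null) "REJECT" else "cannot reject",
              x$level))
  invisible(x)
}
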