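#' Neighbor search specification
#'
#' @param k neighbor count (>= 1).
#' @param theiler_window temporal exclusion radius, in samples: library
#'   points whose time index is within this distance of the prediction
#'   point's are not admissible neighbors (suppresses serially correlated
#'   false neighbors).
#' @export
neighbor_spec <- function(k = 3L, theiler_window = 0L) {
  if (k < 1) stop("k must be >= 1")
  if (theiler_window < 0) stop("theiler_window must be >= 0")
  structure(list(k = as.integer(k), theiler_window = as.integer(theiler_window),
                 metric = "euclidean"), class = "neighbor_spec")
}

#' Time-delay embedding of one channel
#'
#' Rows are `(x_t, x_{t+tau}, ..., x_{t+(E-1) tau})`, for
#' `t = 1 .. n - (E-1) tau`. Row `i` is time-stamped by its last coordinate
#' (`ref_index = i + (E-1) tau`), the "current" time used for forecasting and
#' cross mapping.
#'
#' @param ts `uniform_ts` (single channel or `channel` given) or numeric
#'   vector.
#' @param channel channel to embed when `ts` is multichannel.
#' @param E embedding dimension (>= 1).
#' @param tau delay in samples (>= 1).
#' @return object of class `delay_embedding` with the point matrix, the
#'   `(channel, lag)` coordinate map and the row-to-time-index maps.
#' @export
delay_embed <- function(ts, E, tau = 1L, channel = NULL) {
  x <- embed_input_vector(ts, channel)
  n <- length(x)
  if (E < 1) stop("E must be >= 1")
  if (tau < 1) stop("tau must be >= 1")
  span <- (E - 1) * tau
  if (n <= span)
    stop(sprintf("series too short for embedding: need n > (E-1)*tau = %d, have %d",
                 span, n))
  m <- n - span
  pts <- vapply(0:(E - 1), function(j) x[(1:m) + j * tau], numeric(m))
  pts <- matrix(pts, nrow = m)
  ch <- if (is.null(channel)) "x" else as.character(channel)
  new_embedding(pts,
                coordinates = lapply(0:(E - 1), function(j)
                  list(channel = ch, lag = j * tau)),
                source_length = n,
                step = if (inherits(ts, "uniform_ts")) ts$step else 1,
                start_offset = 0L, series = x)
}

embed_input_vector <- function(ts, channel = NULL) {
  if (inherits(ts, "uniform_ts")) {
    if (is.null(channel)) {
      if (length(ts$channels) != 1)
        stop("multichannel series: name the channel to embed")
      channel <- ts$channels[1]
    }
    ut_channel(ts, channel)
  } else as.numeric(ts)
}

new_embedding <- function(points, coordinates, source_length, step,
                          start_offset, series = NULL) {
  m <- nrow(points)
  lags <- vapply(coordinates, function(co) co$lag, 0)
  # row i's coordinates live at source indices i + start_offset + lag
  structure(list(points = points, coordinates = coordinates,
                 source_length = source_length, step = step,
                 E = length(coordinates),
                 valid_time_index = seq_len(m) + start_offset,
                 ref_index = seq_len(m) + start_offset + max(lags),
                 series = series),
            class = "delay_embedding")
}

#' @export
print.delay_embedding <- function(x, ...) {
  co <- vapply(x$coordinates, function(c.)
    sprintf("%s(t%+d)", c.$channel, c.$lag), "")
  co <- sub("\\+0\\)", ")", sub("t\\+0", "t", co))
  cat(sprintf("<delay_embedding> %d points in %d-D: [%s]\n",
              nrow(x$points), x$E, paste(co, collapse = ", ")))
  invisible(x)
}

#' Mixed-coordinate delay embedding
#'
#' Generalizes [delay_embed()] to an arbitrary list of `(channel, lag)`
#' coordinates; lags may be any integers (in samples/blocks). The attractor
#' coordinates used for the reactor records, `[DO(t), DO(t+5), pH(t)]` on
#' two-hour blocks, are
#' `list(c("DO", 0), c("DO", 5), c("pH", 0))`.
#'
#' @param ts multichannel `uniform_ts`.
#' @param coordinates list of `c(channel, lag)` pairs (or
#'   `list(channel=, lag=)`).
#' @return a `delay_embedding`.
#' @export
mixed_embed <- function(ts, coordinates) {
  stopifnot(inherits(ts, "uniform_ts"))
  coords <- lapply(coordinates, function(co) {
    if (is.list(co)) list(channel = as.character(co$channel),
                          lag = as.integer(co$lag))
    else list(channel = as.character(co[[1]]), lag = as.integer(co[[2]]))
  })
  for (co in coords)
    if (!co$channel %in% ts$channels)
      stop("unknown channel '", co$channel, "'")
  lags <- vapply(coords, function(co) co$lag, 0L)
  n <- ut_n(ts)
  span <- max(lags) - min(lags)
  if (span >= n)
    stop(sprintf("infeasible lags: span %d >= series length %d", span, n))
  m <- n - span
  offset <- -min(lags)        # rows start at source index 1 + offset ... wait
  pts <- vapply(coords, function(co) {
    ts$values[(1:m) + (co$lag - min(lags)), co$channel]
  }, numeric(m))
  pts <- matrix(pts, nrow = m)
  emb <- new_embedding(pts, coords, n, ts$step, start_offset = 0L)
  # re-stamp: row i's coordinate with lag l sits at source index i + l - min(lag);
  # its "current time" (lag 0 position) is i - min(lag)
  emb$valid_time_index <- seq_len(m) - min(lags)
  emb$ref_index <- emb$valid_time_index
  emb
}

#' Export embedded points as a CSV matrix
#' @param embedding a `delay_embedding`.
#' @param path output CSV path.
#' @export
embedding_to_csv <- function(embedding, path) {
  co <- vapply(embedding$coordinates, function(c.)
    sprintf("%s_lag%d", c.$channel, c.$lag), "")
  df <- as.data.frame(embedding$points)
  names(df) <- co
  utils::write.csv(cbind(time_index = embedding$ref_index, df), path,
                   row.names = FALSE)
  invisible(path)
}

# Average mutual information at a given lag, by equal-width binning.
ami_lag <- function(x, lag, bins) {
  n <- length(x) - lag
  a <- x[1:n]; b <- x[(1 + lag):(n + lag)]
  br <- seq(min(x), max(x), length.out = bins + 1)
  br[1] <- br[1] - 1e-9; br[bins + 1] <- br[bins + 1] + 1e-9
  ia <- cut(a, br, labels = FALSE); ib <- cut(b, br, labels = FALSE)
  tab <- table(ia, ib) / n
  px <- rowSums(tab); py <- colSums(tab)
  nzi <- tab > 0
  sum(tab[nzi] * log(tab[nzi] / outer(px, py)[nzi]))
}

#' Choose an embedding delay by average mutual information
#'
#' First strict local minimum of AMI over lags `1..max_lag`. Lags whose AMI
#' is already at the level expected of independent samples (a shuffle
#' baseline, mean + 2 SD over a few seeded permutations) also count as
#' minimal, so white noise yields `tau = 1` deterministically. Falls back to
#' the first lag at which the autocorrelation drops below `1/e`.
#'
#' @param ts single-channel series.
#' @param max_lag largest lag scanned (default `min(n/4, 100)`).
#' @param bins histogram bins for the AMI estimate (default
#'   `ceiling(log2(n)) + 1`).
#' @param seed seed for the shuffle baseline (default 1).
#' @return integer delay.
#' @export
select_delay <- function(ts, max_lag = NULL, bins = NULL, seed = 1L) {
  x <- embed_input_vector(ts)
  n <- length(x)
  if (n < 20) stop("need at least 20 samples to select a delay")
  if (stats::sd(x) == 0) stop("constant series: delay undefined")
  max_lag <- max_lag %||% max(2L, min(floor(n / 4), 100L))
  bins <- bins %||% (ceiling(log2(n)) + 1)
  ami <- vapply(seq_len(max_lag), function(l) ami_lag(x, l, bins), 0)
  # 3-point smoothing tames histogram-estimator jitter before the
  # local-minimum scan (pure periodic series alias badly against bin edges)
  s <- as.numeric(stats::filter(ami, rep(1 / 3, 3)))
  s[1] <- ami[1]; s[max_lag] <- ami[max_lag]
  shuffles <- with_seed(seed, {
    vapply(1:5, function(k) ami_lag(sample(x), 1, bins), 0)
  })
  floor_ami <- mean(shuffles) + 2 * stats::sd(shuffles)
  if (ami[1] <= floor_ami) return(1L)
  for (l in 2:(max_lag - 1)) {
    if (s[l] <= floor_ami) return(as.integer(l))
    if (s[l] < s[l - 1] && s[l] <= s[l + 1]) return(as.integer(l))
  }
  # monotone decreasing AMI throughout: autocorrelation fallback
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  hit <- which(abs(ac) < exp(-1))
  if (length(hit)) return(as.integer(hit[1]))
  stop("no AMI minimum and autocorrelation never drops below 1/e; supply tau explicitly")
}

#' Choose an embedding dimension by simplex forecast skill
#'
#' Scans `E = 1..E_max`, scoring each by leave-one-out simplex forecast
#' skill at a `tau`-step horizon (Pearson correlation); for smooth flows a
#' one-sample horizon saturates at any `E`, so forecasting one delay ahead
#' with a fixed Theiler window (`tau`) makes the scan discriminate. Returns
#' the smallest `E` whose skill is within `plateau_tol` of the best (ties
#' toward parsimony).
#'
#' @param ts single-channel series.
#' @param tau embedding delay (also the forecast horizon).
#' @param E_max largest dimension scanned (>= 2).
#' @param plateau_tol skill tolerance for the plateau rule (default 0.01).
#' @return integer dimension, with attribute `"skill"` giving the scanned
#'   skills.
#' @export
select_dimension <- function(ts, tau, E_max = 6L, plateau_tol = 0.01) {
  x <- embed_input_vector(ts)
  if (E_max < 2) stop("E_max must be >= 2")
  if (stats::sd(x) == 0) stop("constant series: dimension undefined")
  skills <- vapply(seq_len(E_max), function(E) {
    sk <- try(one_step_skill(x, E, tau, theiler = tau, horizon = tau),
              silent = TRUE)
    if (inherits(sk, "try-error")) NA_real_ else sk
  }, 0)
  if (all(is.na(skills))) stop("series too short for any embedding up to E_max")
  best <- max(skills, na.rm = TRUE)
  E <- which(!is.na(skills) & skills >= best - plateau_tol)[1]
  structure(as.integer(E), skill = skills)
}

# Leave-one-out simplex forecast skill of a scalar series at a given horizon.
one_step_skill <- function(x, E, tau, theiler = NULL, horizon = 1L) {
  emb <- delay_embed(x, E, tau)
  m <- nrow(emb$points)
  if (m < E + 4) stop("too few points")
  usable <- which(emb$ref_index + horizon <= emb$source_length)
  target <- x[emb$ref_index[usable] + horizon]
  sp <- neighbor_spec(k = E + 1, theiler_window = theiler %||% (tau * E))
  res <- simplex_project(emb, target_series = target, lib_rows = usable,
                         pred_rows = usable, spec = sp,
                         target_rows = usable)
  res$skill
}

#' Simplex projection: nearest-neighbor forecasting / cross mapping
#'
#' The shared prediction kernel of the pipeline. For each prediction point,
#' finds the `k` nearest library points (Euclidean metric; excluding the
#' point itself and any library point within `theiler_window` time samples),
#' and predicts the target as the exponentially distance-weighted average of
#' the neighbors' target values, `w_i = exp(-d_i / d_min)` normalized; when
#' the minimum distance is zero, weight is spread uniformly over the
#' zero-distance ties. Skill is the Pearson correlation between predictions
#' and observed targets.
#'
#' `target_series` must be aligned with the embedding rows named by
#' `target_rows` (default: all rows, i.e. `target_series[i]` belongs to row
#' `i`). Neighbor ties in distance break toward the earlier time index.
#'
#' @param embedding a `delay_embedding`.
#' @param target_series numeric vector of target values.
#' @param lib_rows embedding row indices forming the library (default all).
#' @param pred_rows embedding row indices to predict (default all).
#' @param spec a [neighbor_spec()]; default `k = E + 1`, Theiler window
#'   `tau * E`-like exclusion must be chosen by the caller (default 0).
#' @param exclude_self drop a library point when it is the prediction point
#'   itself (default TRUE).
#' @param target_rows row indices to which `target_series` entries
#'   correspond (default `seq_along(target_series)`).
#' @param on_insufficient what to do when a prediction point has fewer than
#'   `k` admissible neighbors: `"error"` (default) or `"na"` (skip the
#'   point; cross mapping from small random libraries uses this).
#' @return list with `predictions`, `observed`, `pred_rows`, `skill`
#'   (Pearson rho, `NA` if degenerate) and `n_used`.
#' @export
simplex_project <- function(embedding, target_series, lib_rows = NULL,
                            pred_rows = NULL, spec = NULL,
                            exclude_self = TRUE, target_rows = NULL,
                            on_insufficient = c("error", "na")) {
  on_insufficient <- match.arg(on_insufficient)
  stopifnot(inherits(embedding, "delay_embedding"))
  m <- nrow(embedding$points)
  lib_rows <- sort(lib_rows %||% seq_len(m))
  pred_rows <- pred_rows %||% seq_len(m)
  spec <- spec %||% neighbor_spec(k = embedding$E + 1, theiler_window = 0L)
  target_rows <- target_rows %||% seq_along(target_series)
  tmap <- rep(NA_real_, m)
  tmap[target_rows] <- target_series
  # library rows must have a known target value
  lib_rows <- lib_rows[!is.na(tmap[lib_rows])]
  k <- spec$k
  if (length(lib_rows) < k + exclude_self)
    stop(sprintf("library too small: %d admissible points for k = %d",
                 length(lib_rows), k))
  dm <- cross_dist(embedding$points[pred_rows, , drop = FALSE],
                   embedding$points[lib_rows, , drop = FALSE])
  t_pred <- embedding$ref_index[pred_rows]
  t_lib <- embedding$ref_index[lib_rows]
  preds <- rep(NA_real_, length(pred_rows))
  for (i in seq_along(pred_rows)) {
    dvec <- dm[i, ]
    dt <- abs(t_lib - t_pred[i])
    excl <- dt != 0 & dt <= spec$theiler_window   # dt == 0 is exclude_self's call
    if (exclude_self) excl <- excl | dt == 0
    dvec[excl] <- Inf
    adm <- sum(is.finite(dvec))
    if (adm < k) {
      if (on_insufficient == "na") next
      stop(sprintf("fewer than k = %d admissible neighbors (%d) for prediction row %d",
                   k, adm, pred_rows[i]))
    }
    ord <- order(dvec, t_lib)[seq_len(k)]
    dn <- dvec[ord]
    # distances below numerical noise count as exact matches (squared-form
    # distance computation leaves ~1e-8 residue on identical points)
    zero_tol <- 1e-7 * (1 + max(dn))
    if (dn[1] <= zero_tol) {
      w <- as.numeric(dn <= zero_tol)
    } else {
      w <- exp(-dn / dn[1])
    }
    w <- w / sum(w)
    preds[i] <- sum(w * tmap[lib_rows[ord]])
  }
  obs <- tmap[pred_rows]
  list(predictions = preds, observed = obs, pred_rows = pred_rows,
       skill = safe_cor(preds, obs), n_used = length(lib_rows))
}

#' Maximum Lyapunov exponent from a divergence curve
#'
#' Kantz-style estimate: for each reference point, neighbors within `radius`
#' (outside the Theiler window) are followed for `h = 0..max_periods` steps;
#' the curve is the average over references of the log mean neighbor
#' distance at horizon `h`. The slope of a least-squares line over
#' `fit_range` estimates the maximum Lyapunov exponent per period; negative
#' slope means converging (sink) dynamics. When `fit_range` is `NULL` the
#' longest window of length >= 4 with linear-fit R-squared >= 0.95 is used
#' (falling back to the best R-squared window).
#'
#' @param embedding a `delay_embedding`.
#' @param spec a [neighbor_spec()] (only the Theiler window is used).
#' @param radius neighborhood radius; default the 5% quantile of sampled
#'   inter-point distances.
#' @param max_periods horizon in periods (samples).
#' @param fit_range integer `c(start, end)` horizon window for the slope, or
#'   NULL for automatic selection.
#' @param n_ref maximum number of reference points (evenly spaced; default
#'   400).
#' @return object of class `lyapunov_estimate`: `divergence_curve` (horizons
#'   0..max_periods), `fit_range`, `slope` (per period),
#'   `slope_per_unit_time`, `se`, `r_squared`, `n_ref_used`.
#' @export
max_lyapunov <- function(embedding, spec = neighbor_spec(theiler_window = 0L),
                         radius = NULL, max_periods = 20L, fit_range = NULL,
                         n_ref = 400L) {
  stopifnot(inherits(embedding, "delay_embedding"))
  pts <- embedding$points
  m <- nrow(pts)
  if (m <= max_periods + 2)
    stop("too few embedded points for the requested horizon")
  m_use <- m - max_periods
  refs <- unique(round(seq(1, m_use, length.out = min(n_ref, m_use))))
  dm <- cross_dist(pts[refs, , drop = FALSE], pts[seq_len(m_use), , drop = FALSE])
  if (is.null(radius)) {
    dd <- dm[dm > 0]
    radius <- stats::quantile(dd, 0.05, names = FALSE)
  }
  tw <- spec$theiler_window
  curves <- matrix(NA_real_, length(refs), max_periods + 1)
  used <- 0L
  for (ii in seq_along(refs)) {
    i <- refs[ii]
    nb <- which(dm[ii, ] <= radius & abs(seq_len(m_use) - i) > tw)
    if (!length(nb)) next
    used <- used + 1L
    for (h in 0:max_periods) {
      dif <- pts[nb + h, , drop = FALSE] - matrix(pts[i + h, ], length(nb),
                                                  ncol(pts), byrow = TRUE)
      md <- mean(sqrt(rowSums(dif * dif)))
      curves[ii, h + 1] <- if (md > 0) log(md) else NA_real_
    }
  }
  if (!used)
    stop(sprintf("no reference point has neighbors within radius %g; largest feasible radius is %g",
                 radius, max(apply(dm, 1, function(r) min(r[r > 0])))))
  curve <- colMeans(curves, na.rm = TRUE)
  h_grid <- 0:max_periods
  ok <- is.finite(curve)
  fit_w <- fit_range %||% choose_fit_window(h_grid[ok], curve[ok])
  sel <- h_grid >= fit_w[1] & h_grid <= fit_w[2] & ok
  fit <- stats::lm(curve[sel] ~ h_grid[sel])
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  structure(list(divergence_curve = curve, horizons = h_grid,
                 fit_range = fit_w, slope = slope,
                 slope_per_unit_time = slope / embedding$step,
                 se = sm$coefficients[2, 2], r_squared = sm$r.squared,
                 radius = radius, n_ref_used = used,
                 params = list(E = embedding$E, spec = spec)),
            class = "lyapunov_estimate")
}

choose_fit_window <- function(h, y, min_len = 4L, r2_min = 0.95) {
  best <- NULL; best_len <- -1; best_r2 <- -Inf; best_any <- NULL
  nh <- length(h)
  for (a in seq_len(nh - min_len + 1)) {
    for (b in (a + min_len - 1):nh) {
      xs <- h[a:b]; ys <- y[a:b]
      fit <- stats::lm(ys ~ xs)
      r2 <- summary(fit)$r.squared
      len <- b - a + 1
      if (is.finite(r2)) {
        if (r2 >= r2_min && len > best_len) { best <- c(h[a], h[b]); best_len <- len }
        if (r2 > best_r2) { best_r2 <- r2; best_any <- c(h[a], h[b]) }
      }
    }
  }
  best %||% best_any %||% c(h[1], h[min(length(h), min_len)])
}

#' @export
print.lyapunov_estimate <- function(x, ...) {
  cat(sprintf("<lyapunov_estimate> slope %.4f per period (%.4f per time unit), fit %d..%d, R^2 = %.3f\n",
              x$slope, x$slope_per_unit_time, x$fit_range[1], x$fit_range[2],
              x$r_squared))
  invisible(x)
}
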