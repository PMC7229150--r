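#' Aggregate a record into non-overlapping block means
#'
#' Each output sample is the arithmetic mean of one contiguous block of
#' `block_duration / step` raw samples; a trailing partial block is discarded
#' rather than padded. This is how 100 Hz sensor records become the two-hour
#' analysis blocks on which all downstream state-space work operates.
#'
#' @param ts a `uniform_ts`.
#' @param block_duration block length in the same time unit as `ts$step`;
#'   must be a positive (near-)integer multiple of `step`, >= `step`.
#' @return a `uniform_ts` with step `block_duration`.
#' @export
aggregate_blocks <- function(ts, block_duration) {
  stopifnot(inherits(ts, "uniform_ts"))
  if (block_duration < ts$step)
    stop("block_duration must be >= the sampling step")
  spb <- block_duration / ts$step
  if (abs(spb - round(spb)) > 1e-8 * spb)
    stop("block_duration must be an integer multiple of the sampling step")
  spb <- as.integer(round(spb))
  if (spb == 1L) return(ts)
  n_blocks <- floor(ut_n(ts) / spb)
  if (n_blocks < 2)
    stop("record too short: fewer than 2 complete blocks")
  keep <- seq_len(n_blocks * spb)
  vals <- vapply(seq_len(ncol(ts$values)), function(j) {
    .colMeans(ts$values[keep, j], spb, n_blocks)
  }, numeric(n_blocks))
  uniform_ts(matrix(vals, ncol = ncol(ts$values)), block_duration,
             ts$channels, ts$start_time, ts$time_unit)
}

#' Singular spectrum analysis of a single channel
#'
#' Builds the `L x (n - L + 1)` trajectory (Hankel) matrix of the series and
#' takes its singular value decomposition. All eigentriples are returned
#' ungrouped; use [ssa_group()] to partition them and [ssa_reconstruct()] /
#' [signal_strength()] to extract component series and their share of the
#' total squared norm.
#'
#' @param ts single-channel `uniform_ts` or numeric vector.
#' @param window_length window `L`, with `2 <= L <= n/2`. Default
#'   `floor(n/2)`, the largest admissible window (standard choice when the
#'   dominant period is unknown).
#' @return an object of class `ssa_decomp` with the singular values, the
#'   orthonormal left/right vector families, and (after grouping) the group
#'   partition, reconstructed series and signal strengths.
#' @export
ssa_decompose <- function(ts, window_length = NULL) {
  x <- if (inherits(ts, "uniform_ts")) {
    if (length(ts$channels) != 1)
      stop("ssa_decompose works on a single channel; use ut_select() first")
    ut_channel(ts, 1)
  } else as.numeric(ts)
  n <- length(x)
  l <- window_length %||% floor(n / 2)
  if (l < 2 || l > n / 2)
    stop(sprintf("window_length must satisfy 2 <= L <= n/2 (n = %d, L = %g)", n, l))
  l <- as.integer(l)
  k <- n - l + 1
  traj <- stats::embed(x, l)[, l:1, drop = FALSE]  # k x L, rows are windows
  traj <- t(traj)                                   # L x K Hankel matrix
  sv <- svd(traj)
  structure(list(series = x, n = n, window_length = l, k = k,
                 singular_values = sv$d, left_vectors = sv$u,
                 right_vectors = sv$v, groups = NULL,
                 signal_strength = NULL),
            class = "ssa_decomp")
}

#' @export
print.ssa_decomp <- function(x, ...) {
  cat(sprintf("<ssa_decomp> n = %d, L = %d, %d eigentriples\n",
              x$n, x$window_length, length(x$singular_values)))
  if (!is.null(x$groups)) {
    for (g in names(x$groups))
      cat(sprintf("  %s: %d eigentriple(s), strength %.2f%%\n", g,
                  length(x$groups[[g]]), x$signal_strength[[g]]))
  }
  invisible(x)
}

# Diagonal averaging (Hankelization) of a rank-subset reconstruction.
diag_average <- function(m) {
  l <- nrow(m); k <- ncol(m); n <- l + k - 1
  out <- numeric(n)
  cnt <- numeric(n)
  idx <- row(m) + col(m) - 1L
  out <- as.numeric(tapply(m, idx, sum))
  cnt <- as.numeric(tapply(rep(1, length(m)), idx, sum))
  out / cnt
}

reconstruct_indices <- function(decomp, idx) {
  d <- decomp$singular_values[idx]
  u <- decomp$left_vectors[, idx, drop = FALSE]
  v <- decomp$right_vectors[, idx, drop = FALSE]
  diag_average(u %*% (d * t(v)))
}

# Weighted (Hankel) correlation matrix between elementary reconstructions.
w_correlation <- function(decomp, n_comp) {
  n <- decomp$n; l <- decomp$window_length; k <- decomp$k
  w <- pmin(seq_len(n), l, k, n - seq_len(n) + 1)
  elem <- vapply(seq_len(n_comp), function(i) reconstruct_indices(decomp, i),
                 numeric(n))
  wip <- crossprod(elem * sqrt(w))
  nr <- sqrt(diag(wip))
  nr[nr == 0] <- 1
  wc <- wip / outer(nr, nr)
  wc[!is.finite(wc)] <- 0
  wc
}

#' Group SSA eigentriples
#'
#' Either an explicit partition of the eigentriple indices (a named list of
#' index vectors that together cover every index exactly once) or the
#' automatic w-correlation rule: eigentriples whose weighted correlation
#' exceeds `threshold` are merged (connected components); components whose
#' share of the total squared singular values is at least `min_strength`
#' percent become separate signal groups (`signal1`, `signal2`, ... in order
#' of leading eigentriple), everything else is pooled into `noise`.
#'
#' @param decomp an [ssa_decompose()] result.
#' @param grouping `"auto"` or a named list of index vectors.
#' @param threshold w-correlation merge threshold (default 0.5).
#' @param min_strength minimum percent strength for a component to count as
#'   signal (default 1).
#' @param n_comp number of leading eigentriples examined by the automatic
#'   rule (default: all with nonzero singular value, capped at 30).
#' @return the decomposition with `groups`, `reconstructed` and
#'   `signal_strength` populated.
#' @export
ssa_group <- function(decomp, grouping = "auto", threshold = 0.5,
                      min_strength = 1, n_comp = NULL) {
  stopifnot(inherits(decomp, "ssa_decomp"))
  d2 <- decomp$singular_values^2
  total <- sum(d2)
  if (total == 0) stop("all-zero series: signal strength undefined")
  n_sv <- length(decomp$singular_values)
  if (is.list(grouping)) {
    idx <- sort(unlist(grouping, use.names = FALSE))
    if (!identical(as.integer(idx), seq_len(n_sv)))
      stop("explicit grouping must partition eigentriple indices 1..",
           n_sv, " (each index exactly once)")
    groups <- grouping
    if (is.null(names(groups)) || any(names(groups) == ""))
      names(groups) <- paste0("group", seq_along(groups))
  } else if (identical(grouping, "auto")) {
    nz <- sum(d2 > 1e-12 * total)
    nc <- n_comp %||% min(max(nz, 2L), 30L, n_sv)
    wc <- w_correlation(decomp, nc)
    adj <- abs(wc) > threshold
    comp <- integer(nc); cur <- 0L
    for (i in seq_len(nc)) {
      if (comp[i] == 0L) {
        cur <- cur + 1L
        stack <- i
        while (length(stack)) {
          v <- stack[[1]]; stack <- stack[-1]
          if (comp[v] == 0L) {
            comp[v] <- cur
            stack <- c(stack, which(adj[v, ] & comp == 0L))
          }
        }
      }
    }
    comps <- split(seq_len(nc), comp)
    strength <- vapply(comps, function(ix) 100 * sum(d2[ix]) / total, 0)
    is_sig <- strength >= min_strength
    ord <- order(vapply(comps, min, 0L))
    groups <- list(); si <- 0L; noise_idx <- integer(0)
    for (ci in ord) {
      if (is_sig[ci]) {
        si <- si + 1L
        groups[[paste0("signal", si)]] <- comps[[ci]]
      } else noise_idx <- c(noise_idx, comps[[ci]])
    }
    noise_idx <- sort(c(noise_idx, setdiff(seq_len(n_sv), seq_len(nc))))
    if (length(noise_idx)) groups$noise <- noise_idx
    if (!si) {
      # nothing passed the strength rule: call the strongest component signal
      groups <- list(signal1 = comps[[which.max(strength)]])
      groups$noise <- sort(setdiff(seq_len(n_sv), groups$signal1))
    }
  } else stop("grouping must be \"auto\" or a named list of index vectors")
  decomp$groups <- groups
  decomp$signal_strength <- vapply(groups, function(ix)
    100 * sum(d2[ix]) / total, 0)
  decomp$reconstructed <- vapply(groups, function(ix)
    reconstruct_indices(decomp, ix), numeric(decomp$n))
  decomp
}

#' Reconstruct the series of one eigentriple group
#'
#' Diagonal averaging (Hankelization) of the grouped elementary matrices.
#' Reconstructing every group of a complete partition and summing returns
#' the original series to numerical precision.
#'
#' @param decomp a grouped [ssa_decompose()] result.
#' @param group_label name of the group.
#' @return single-channel `uniform_ts` if the input carried time metadata is
#'   not retained; a numeric vector of length `n`.
#' @export
ssa_reconstruct <- function(decomp, group_label) {
  stopifnot(inherits(decomp, "ssa_decomp"))
  if (is.null(decomp$groups)) stop("decomposition has no groups; call ssa_group()")
  if (!group_label %in% names(decomp$groups))
    stop(sprintf("unknown group '%s' (available: %s)", group_label,
                 paste(names(decomp$groups), collapse = ", ")))
  as.numeric(decomp$reconstructed[, group_label])
}

#' Signal strength of a group, in percent
#'
#' `100 * sum(singular values in group squared) / sum(all squared)`. Over a
#' complete partition the strengths sum to 100.
#'
#' @inheritParams ssa_reconstruct
#' @export
signal_strength <- function(decomp, group_label) {
  stopifnot(inherits(decomp, "ssa_decomp"))
  if (is.null(decomp$groups)) stop("decomposition has no groups; call ssa_group()")
  if (!group_label %in% names(decomp$groups))
    stop(sprintf("unknown group '%s'", group_label))
  as.numeric(decomp$signal_strength[[group_label]])
}

#' Export an SSA decomposition summary as JSON plus per-group CSV series
#'
#' @param decomp grouped decomposition.
#' @param path base path; writes `<path>.json` and `<path>_groups.csv`.
#' @return base path, invisibly.
#' @export
ssa_export <- function(decomp, path) {
  stopifnot(inherits(decomp, "ssa_decomp"), !is.null(decomp$groups))
  jsonlite::write_json(
    list(window_length = decomp$window_length,
         singular_values = decomp$singular_values,
         groups = decomp$groups,
         signal_strength = as.list(decomp$signal_strength)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(decomp$reconstructed),
                   paste0(path, "_groups.csv"), row.names = FALSE)
  invisible(path)
}
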