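#' Pipeline configuration
#'
#' Bundles every stage default so the whole analysis is reproducible from a
#' single object (and a single seed). All values are overridable; everything
#' is recorded in the report provenance.
#'
#' @param block_duration analysis block length in the input's time unit
#'   (default 7200 s = two hours).
#' @param channels the two channels to analyze (default `c("pH", "DO")`).
#' @param ssa_window SSA window length (default `n/2`).
#' @param ssa_threshold,ssa_min_strength automatic grouping parameters.
#' @param tau,E embedding overrides; `NULL` means automatic selection.
#' @param E_max scan bound for automatic dimension selection.
#' @param lib_sizes,n_draws,delays CCM settings (`NULL` lib sizes =
#'   automatic grid; delay grid default -8..8 blocks).
#' @param strong_rho,weak_rho CCM classification thresholds (0.8 / 0.5).
#' @param n_segments,stationarity_factor cross-prediction gate settings.
#' @param n_surrogates,level,surrogate_statistic surrogate gate settings.
#' @param sindy_degree,sindy_threshold sparse-regression settings.
#' @param ode_states `"2d"` fits the ODE in the observed (pH, DO) state
#'   plane; `"mixed3d"` fits in the mixed attractor coordinates
#'   `[DO(t), DO(t+lag), pH(t)]`.
#' @param mixed_lag delay (in blocks) of the second mixed coordinate
#'   (default 5).
#' @param lyap_max_periods divergence-curve horizon.
#' @param lyap_tol dynamic-correspondence tolerance on the per-block
#'   Lyapunov slope (default 0.05).
#' @param seed master seed; all stage randomness derives from it.
#' @export
diybot_config <- function(block_duration = 7200, channels = c("pH", "DO"),
                          ssa_window = NULL, ssa_threshold = 0.5,
                          ssa_min_strength = 1,
                          tau = NULL, E = NULL, E_max = 6L,
                          lib_sizes = NULL, n_draws = 50L, delays = -8:8,
                          strong_rho = 0.8, weak_rho = 0.5,
                          n_segments = 4L, stationarity_factor = 2,
                          n_surrogates = 99L, level = 0.05,
                          surrogate_statistic = "prediction_error",
                          sindy_degree = 2L, sindy_threshold = 0.05,
                          ode_states = c("2d", "mixed3d"), mixed_lag = 5L,
                          lyap_max_periods = 15L, lyap_tol = 0.05,
                          seed = 1L) {
  ode_states <- match.arg(ode_states)
  if (!(strong_rho > weak_rho && weak_rho > 0 && strong_rho <= 1))
    stop("thresholds must satisfy 0 < weak < strong <= 1")
  structure(as.list(environment()), class = "diybot_config")
}

#' Run the full digital-proxy pipeline
#'
#' Fixed stage order: block aggregation, per-channel SSA signal isolation,
#' nonlinear-stationarity gate, surrogate-data gate, delay selection and
#' embedding, CCM + extended CCM causal classification, sparse ODE
#' discovery, equilibrium/eigenvalue classification, Lyapunov
#' correspondence, marginal impact. A failed gate halts before model fitting
#' and returns an indeterminate report naming the gate — fitting an ODE to a
#' signal that is nonstationary or indistinguishable from linear noise is
#' the failure mode the gates exist to prevent.
#'
#' The management flag operationalizes the study conclusion: when the fitted
#' model's relevant equilibrium is a sink (spiral or node) and the empirical
#' and model attractors' Lyapunov exponents agree within `lyap_tol`
#' ("dynamic correspondence"), the system is `self_correcting`; a confident
#' non-sink classification yields `intervention_advised`; anything else is
#' `indeterminate`.
#'
#' @param input `uniform_ts` or path to a sensor CSV.
#' @param config a [diybot_config()].
#' @return object of class `diybot_report`.
#' @export
run_diybot <- function(input, config = diybot_config()) {
  stopifnot(inherits(config, "diybot_config"))
  t0 <- proc.time()[["elapsed"]]
  ts <- if (is.character(input)) read_sensor_csv(input) else input
  stopifnot(inherits(ts, "uniform_ts"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stamp <- function(nm, t) timings[[nm]] <<- round(tic() - t, 3)

  chans <- config$channels
  if (!all(chans %in% ts$channels)) {
    if (length(ts$channels) >= 2) chans <- ts$channels[1:2]
    else stop("input must provide two channels (have: ",
              paste(ts$channels, collapse = ", "), ")")
  }
  ts <- ut_select(ts, chans)

  report <- list(config = unclass(config), channels = chans,
                 stage_timings = NULL, failed_gate = NULL,
                 management_flag = "indeterminate")
  class(report) <- "diybot_report"

  ## 1. block aggregation -----------------------------------------------
  t <- tic()
  blocks <- if (config$block_duration > ts$step)
    aggregate_blocks(ts, config$block_duration) else ts
  nb <- ut_n(blocks)
  report$n_blocks <- nb
  stamp("aggregate", t)

  ## 2. SSA per channel (series are centered first; the mean is an offset,
  ## not dynamics, and would otherwise swamp the grouping) ---------------
  t <- tic()
  signals <- list(); ssa_summaries <- list()
  for (ch in chans) {
    x <- ut_channel(blocks, ch)
    mu <- mean(x)
    dec <- ssa_group(ssa_decompose(x - mu, config$ssa_window),
                     threshold = config$ssa_threshold,
                     min_strength = config$ssa_min_strength)
    sig_groups <- grep("^signal", names(dec$groups), value = TRUE)
    sig <- rowSums(dec$reconstructed[, sig_groups, drop = FALSE]) + mu
    signals[[ch]] <- sig
    ssa_summaries[[ch]] <- list(
      window_length = dec$window_length,
      groups = lapply(dec$groups, as.integer),
      signal_strength = as.list(dec$signal_strength),
      total_signal_strength = sum(unlist(dec$signal_strength[sig_groups])))
  }
  report$ssa <- ssa_summaries
  stamp("ssa", t)

  ## 3. embedding parameters (chosen first: the gate statistics use the
  ## same delay/dimension conventions as the reconstruction itself) -------
  t <- tic()
  tau <- config$tau %||% select_delay(signals[[chans[1]]])
  E <- config$E %||% as.integer(select_dimension(signals[[chans[1]]], tau,
                                                 config$E_max))
  report$embedding <- list(E = E, tau = tau)
  stamp("embedding", t)

  ## 4. stationarity gate --------------------------------------------------
  t <- tic()
  report$stationarity <- list()
  for (ch in chans) {
    cp <- nonlinear_cross_prediction(signals[[ch]],
                                     n_segments = config$n_segments,
                                     E = E, tau = tau,
                                     factor = config$stationarity_factor)
    report$stationarity[[ch]] <- list(
      heterogeneity_score = cp$heterogeneity_score,
      stationary = cp$stationary)
    if (!cp$stationary) {
      report$failed_gate <- "stationarity"
      report$failed_channel <- ch
    }
  }
  stamp("stationarity", t)
  if (!is.null(report$failed_gate)) return(finish_report(report, timings, t0))

  ## 5. surrogate gate ------------------------------------------------------
  t <- tic()
  report$surrogates <- list()
  for (i in seq_along(chans)) {
    st <- surrogate_test(signals[[chans[i]]],
                         statistic = config$surrogate_statistic,
                         n_surrogates = config$n_surrogates,
                         level = config$level, E = E, tau = tau,
                         seed = config$seed + i)
    report$surrogates[[chans[i]]] <- list(
      statistic = st$statistic_name, observed = st$observed_value,
      rank_p = st$rank_p, reject_linear_null = st$reject_linear_null)
    if (!st$reject_linear_null) {
      report$failed_gate <- "surrogate"
      report$failed_channel <- chans[i]
    }
  }
  stamp("surrogate", t)
  if (!is.null(report$failed_gate)) return(finish_report(report, timings, t0))

  ## 6. CCM causal classification -----------------------------------------
  t <- tic()
  s1 <- signals[[chans[1]]]; s2 <- signals[[chans[2]]]
  ccm_12 <- ccm(s2, s1, E, tau, lib_sizes = config$lib_sizes,
                n_draws = config$n_draws, seed = config$seed + 11)
  ccm_12$driver <- chans[1]; ccm_12$response <- chans[2]
  ccm_21 <- ccm(s1, s2, E, tau, lib_sizes = config$lib_sizes,
                n_draws = config$n_draws, seed = config$seed + 12)
  ccm_21$driver <- chans[2]; ccm_21$response <- chans[1]
  ext_12 <- extended_ccm(s2, s1, E, tau, delays = config$delays)
  ext_21 <- extended_ccm(s1, s2, E, tau, delays = config$delays)
  cls <- classify_interaction(ccm_12, ccm_21, ext_12, ext_21,
                              pair = chans, strong_rho = config$strong_rho,
                              weak_rho = config$weak_rho)
  report$ccm <- list(ccm_ab = ccm_12, ccm_ba = ccm_21,
                     ext_ab = ext_12, ext_ba = ext_21)
  report$classification <- cls
  stamp("ccm", t)

  ## 7. sparse ODE discovery ----------------------------------------------
  t <- tic()
  if (config$ode_states == "2d") {
    states <- cbind(s1, s2)
    colnames(states) <- chans
  } else {
    sig_ts <- uniform_ts(cbind(s1, s2), 1, chans, time_unit = "blocks")
    emb3 <- mixed_embed(sig_ts, list(c(chans[2], 0),
                                     c(chans[2], config$mixed_lag),
                                     c(chans[1], 0)))
    states <- emb3$points
    colnames(states) <- c(paste0(chans[2], "_t"),
                          paste0(chans[2], "_t", config$mixed_lag),
                          paste0(chans[1], "_t"))
  }
  derivs <- estimate_derivatives(states, step = 1)
  lib <- function_library(colnames(states), config$sindy_degree)
  model <- sindy_fit(states, derivs, lib, threshold = config$sindy_threshold)
  report$model <- model
  stamp("sindy", t)

  ## 8. equilibrium + eigenvalue classification ---------------------------
  t <- tic()
  rng <- apply(states, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-6)
  box <- cbind(rng[1, ] - 0.5 * span, rng[2, ] + 0.5 * span)
  eqs <- find_equilibria(model, box, seed = config$seed + 21)
  if (nrow(eqs$equilibria)) {
    ctr <- colMeans(states)
    dd <- sqrt(rowSums(sweep(eqs$equilibria, 2, ctr)^2))
    eq <- eqs$equilibria[which.min(dd), ]
    report$equilibrium <- eigen_classify(model, eq, residual_tol = 1e-5)
  } else {
    report$equilibrium <- NULL
    report$equilibrium_note <- "no equilibrium located in the search box"
  }
  stamp("equilibrium", t)

  ## 9. Lyapunov correspondence -------------------------------------------
  t <- tic()
  lyap_emp <- lyap_model <- NULL
  corresponds <- FALSE
  emp_try <- try({
    emb_e <- delay_embed(s1, E, tau)
    lyap_emp <- max_lyapunov(emb_e, neighbor_spec(theiler_window = tau * E),
                             max_periods = config$lyap_max_periods)
  }, silent = TRUE)
  if (!is.null(report$equilibrium)) {
    mod_try <- try({
      traj <- integrate_model(report$model, states[1, ], step = 1,
                              n_steps = nrow(states))
      emb_m <- delay_embed(ut_channel(traj, ncol(states)), E, tau)
      lyap_model <- max_lyapunov(emb_m, neighbor_spec(theiler_window = tau * E),
                                 max_periods = config$lyap_max_periods)
      report$model_trajectory <- traj
    }, silent = TRUE)
    if (!is.null(lyap_emp) && !is.null(lyap_model)) {
      se <- sqrt(lyap_emp$se^2 + lyap_model$se^2)
      corresponds <- abs(lyap_emp$slope - lyap_model$slope) <=
        max(config$lyap_tol, 2 * se)
    }
  }
  report$lyapunov <- list(empirical = lyap_emp, model = lyap_model,
                          corresponds = corresponds)
  stamp("lyapunov", t)

  ## 10. marginal impact ---------------------------------------------------
  if (!is.null(report$model) && !is.null(report$model_trajectory) &&
      config$ode_states == "2d") {
    report$marginal_impact <- marginal_impacts(
      report$model, report$model_trajectory,
      driver = chans[1], response = chans[2], type = "propagated")
  }

  ## 11. management flag ----------------------------------------------------
  cls_lab <- if (!is.null(report$equilibrium))
    report$equilibrium$classification else "unclassified"
  report$management_flag <- if (cls_lab %in% c("spiral_sink", "node_sink") &&
                                corresponds) "self_correcting"
  else if (!cls_lab %in% c("spiral_sink", "node_sink", "unclassified"))
    "intervention_advised"
  else "indeterminate"
  finish_report(report, timings, t0)
}

finish_report <- function(report, timings, t0) {
  report$stage_timings <- as.list(timings)
  report$total_time <- round(proc.time()[["elapsed"]] - t0, 3)
  cfg_json <- jsonlite::toJSON(report$config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  report$provenance <- list(config_hash = fnv1a(as.character(cfg_json)),
                            seed = report$config$seed,
                            package_version = as.character(
                              utils::packageVersion("diybot")))
  report
}

#' @export
print.diybot_report <- function(x, ...) {
  cat("<diybot_report>\n")
  cat("  blocks analyzed:", x$n_blocks %||% NA, "\n")
  if (!is.null(x$failed_gate))
    cat(sprintf("  HALTED at %s gate (channel %s)\n", x$failed_gate,
                x$failed_channel))
  if (!is.null(x$classification))
    cat("  causal summary:", x$classification$summary, "\n")
  if (!is.null(x$equilibrium))
    cat("  equilibrium class:", x$equilibrium$classification, "\n")
  cat("  management flag:", x$management_flag, "\n")
  invisible(x)
}

# Convert a report to plain JSON-safe lists.
report_to_list <- function(report) {
  cplx <- function(z) lapply(z, function(v) list(re = Re(v), im = Im(v)))
  out <- list(
    schema_version = "1",
    channels = report$channels,
    n_blocks = report$n_blocks,
    config = report$config,
    failed_gate = report$failed_gate,
    failed_channel = report$failed_channel,
    ssa = report$ssa,
    stationarity = report$stationarity,
    surrogates = report$surrogates,
    embedding = report$embedding,
    management_flag = report$management_flag,
    provenance = report$provenance)
  if (!is.null(report$classification)) {
    cl <- report$classification
    out$classification <- list(pair = cl$pair, a_drives_b = cl$a_drives_b,
                               b_drives_a = cl$b_drives_a,
                               synchrony_suspected = cl$synchrony_suspected,
                               summary = cl$summary,
                               rho = as.list(cl$rho),
                               peak_delays = as.list(cl$peak_delays))
  }
  if (!is.null(report$ccm)) {
    out$ccm <- lapply(report$ccm, function(r) {
      if (inherits(r, "ccm_result"))
        list(driver = r$driver, response = r$response, E = r$E, tau = r$tau,
             lib_sizes = r$lib_sizes, skill = r$skill, rho_max = r$rho_max,
             converged = r$converged)
      else list(delays = r$delays, skill_by_delay = r$skill_by_delay,
                peak_delay = r$peak_delay, true_causal = r$true_causal)
    })
  }
  if (!is.null(report$model)) {
    out$model <- list(state_names = report$model$state_names,
                      terms = report$model$library$terms,
                      coefficients = report$model$coefficients,
                      threshold = report$model$threshold,
                      equations = render_equations(report$model))
  }
  if (!is.null(report$equilibrium)) {
    eqa <- report$equilibrium
    out$equilibrium <- list(state = eqa$equilibrium,
                            eigenvalues = cplx(eqa$eigenvalues),
                            classification = eqa$classification)
  }
  if (!is.null(report$lyapunov)) {
    ly <- report$lyapunov
    pick <- function(l) if (is.null(l)) NULL else
      list(slope = l$slope, se = l$se, r_squared = l$r_squared,
           fit_range = l$fit_range)
    out$lyapunov <- list(empirical = pick(ly$empirical),
                         model = pick(ly$model),
                         corresponds = ly$corresponds)
  }
  if (!is.null(report$marginal_impact)) {
    mi <- report$marginal_impact
    out$marginal_impact <- list(driver = mi$driver, response = mi$response,
                                type = mi$type, tol = mi$tol,
                                decayed = mi$decayed,
                                decayed_to_zero_by = mi$decayed_to_zero_by,
                                values = mi$values)
  }
  out
}

#' Write a pipeline report to a directory
#'
#' Emits `report.json` (the machine-readable twin), `ccm_curves.csv` and
#' `model.json` when those stages ran, and a plain-text `summary.txt` with
#' the rendered equations and the management flag.
#'
#' @param report a `diybot_report`.
#' @param directory output directory (created if missing).
#' @param overwrite allow replacing an existing report (default FALSE).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, directory, overwrite = FALSE) {
  stopifnot(inherits(report, "diybot_report"))
  if (dir.exists(directory) &&
      file.exists(file.path(directory, "report.json")) && !overwrite)
    stop("report already exists in '", directory,
         "'; use overwrite = TRUE to replace it")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  jsonlite::write_json(report_to_list(report),
                       file.path(directory, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (!is.null(report$ccm))
    ccm_curves_csv(list(
      a_drives_b = report$ccm$ccm_ab,
      b_drives_a = report$ccm$ccm_ba), file.path(directory, "ccm_curves.csv"))
  if (!is.null(report$model))
    model_to_json(report$model, file.path(directory, "model.json"))
  lines <- c("DIYBOT pipeline summary",
             "=======================",
             sprintf("channels: %s", paste(report$channels, collapse = ", ")),
             sprintf("blocks analyzed: %s", report$n_blocks %||% NA))
  if (!is.null(report$failed_gate))
    lines <- c(lines, sprintf("HALTED at gate: %s (channel %s)",
                              report$failed_gate, report$failed_channel))
  if (!is.null(report$classification))
    lines <- c(lines,
               sprintf("causal interaction: %s", report$classification$summary),
               sprintf("  %s -> %s: %s", report$channels[1],
                       report$channels[2], report$classification$a_drives_b),
               sprintf("  %s -> %s: %s", report$channels[2],
                       report$channels[1], report$classification$b_drives_a))
  if (!is.null(report$model))
    lines <- c(lines, "fitted equations:",
               paste(" ", render_equations(report$model)))
  if (!is.null(report$equilibrium))
    lines <- c(lines, sprintf("equilibrium classification: %s",
                              report$equilibrium$classification))
  lines <- c(lines, sprintf("management flag: %s", report$management_flag))
  writeLines(lines, file.path(directory, "summary.txt"))
  invisible(directory)
}
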