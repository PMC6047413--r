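#' Data-driven initial conditions for the simulation
#'
#' `S_0` is the mean (normalised) SWA over the very first NREM episode of
#' at least 3 min (45 epochs); `SWA_0` is the empirical SWA at the start
#' of the recording (the first non-artifact epoch if epoch 0 is
#' artifactual).
#'
#' @param x an `epoch_series` with normalised SWA.
#' @param derivation SWA column used.
#' @return named numeric `c(S_0, SWA_0)`.
#' @export
initial_conditions <- function(x, derivation = 1) {
  eps <- detect_long_nrem_episodes(x)
  s0 <- NA_real_
  for (i in seq_len(nrow(eps))) {
    s0 <- episode_mean_swa(eps[i, ], x, derivation)
    if (!is.na(s0)) break
  }
  if (is.na(s0))
    stop("no NREM episode of >= 45 ts with usable SWA")
  first <- which(!x$artifact & !is.na(x$swa[, derivation]))[1]
  if (is.na(first)) stop("no usable epoch for SWA_0")
  c(S_0 = unname(s0), SWA_0 = unname(x$swa[first, derivation]))
}

#' Stage-1 starting grid for the multi-start fit
#'
#' Nine starts: three `gc` values crossed with three `rs` values, with a
#' common `S_U` start. The grids differ between the frontal and occipital
#' derivations (occipital Process S decays more slowly and has a higher
#' asymptote start).
#'
#' @param derivation_type `"frontal"` or `"occipital"`.
#' @return data.frame with columns `gc`, `rs`, `s_u` (9 rows).
#' @export
stage1_starts <- function(derivation_type = c("frontal", "occipital")) {
  derivation_type <- match.arg(derivation_type)
  if (derivation_type == "frontal") {
    gc <- c(0.0005, 0.0010, 0.0020); s_u <- 400
  } else {
    gc <- c(0.0002, 0.0004, 0.0008); s_u <- 450
  }
  g <- expand.grid(gc = gc, rs = c(0.0001, 0.0002, 0.0004),
                   KEEP.OUT.ATTRS = FALSE)
  g$s_u <- s_u
  g
}

#' Stage-2 starting grid around a stage-1 winner
#'
#' The winning `(gc, rs, S_U)` of stage 1 spawns nine refined starts:
#' `gc* + {-0.0002, 0, +0.0002}` crossed with `rs* + {-0.00002, 0,
#' +0.00002}`, all with `S_U* ` as the `S_U` start. Non-positive starts
#' are clamped to a small positive floor.
#'
#' @param best named list or vector with `gc`, `rs`, `s_u`.
#' @param floor smallest admissible starting rate.
#' @return data.frame with columns `gc`, `rs`, `s_u` (9 rows).
#' @export
stage2_starts <- function(best, floor = 1e-6) {
  g <- expand.grid(gc = best[["gc"]] + c(-2e-4, 0, 2e-4),
                   rs = best[["rs"]] + c(-2e-5, 0, 2e-5),
                   KEEP.OUT.ATTRS = FALSE)
  g$gc <- pmax(g$gc, floor)
  g$rs <- pmax(g$rs, floor)
  g$s_u <- best[["s_u"]]
  g
}

#' Build the squared-error objective for one derivation
#'
#' Precomputes the NREM episodes, the per-episode usable epoch sets and
#' the (smoothed) empirical episode means, then returns a function of
#' `(gc, rs, S_U)` that re-runs the full forward simulation and returns
#' the light/dark-balanced squared error. Candidate points with
#' non-positive rates, `S_U <= SWA_L`, or a failed simulation score
#' `+Inf`.
#'
#' @param x an `epoch_series` over the fit window, SWA normalised.
#' @param derivation SWA column used.
#' @param params fixed [model_params()] (everything but `gc`, `rs`,
#'   `S_U`).
#' @param smooth_window moving-median window for the empirical trace
#'   (`NULL` to fit against raw SWA).
#' @param substeps integrator substeps per epoch.
#' @param ba_as_wake passed to [build_triggers()].
#' @return function mapping `c(gc, rs, s_u)` to the squared error, with
#'   the precomputed pieces attached as attributes (`episodes`,
#'   `triggers`, `init`, `smoothed`).
#' @export
make_objective <- function(x, derivation = 1, params = model_params(),
                           smooth_window = 35, substeps = 10,
                           ba_as_wake = FALSE) {
  episodes <- detect_nrem_episodes(x)
  if (!nrow(episodes)) stop("no NREM episodes in the fit window")
  trig <- build_triggers(x, params, ba_as_wake = ba_as_wake)
  init <- initial_conditions(x, derivation)
  emp <- x$swa[, derivation]
  # The quantity being fitted is NREM SWA, so the de-noising median runs
  # over NREM non-artifact epochs only: wake/REM/BA levels sit near the
  # lower asymptote and would otherwise drag every episode-edge window
  # down, biasing the empirical episode means relative to the raw
  # simulated ones.
  smoothed <- if (is.null(smooth_window)) NULL else
    smooth_moving_median(emp, smooth_window,
                         artifact = x$artifact | x$state != "N")
  empv <- if (is.null(smoothed)) emp else smoothed
  # usable epoch sets and empirical means are identical for every
  # candidate, so fix them once
  idx_list <- list(); m_emp <- numeric(0); ph <- character(0)
  for (i in seq_len(nrow(episodes))) {
    idx <- (episodes$start[i] + 1L):episodes$end[i]
    idx <- idx[x$state[idx] == "N" & !x$artifact[idx] & !is.na(empv[idx])]
    if (!length(idx)) next
    idx_list[[length(idx_list) + 1L]] <- idx
    m_emp <- c(m_emp, mean(empv[idx]))
    ph <- c(ph, episodes$phase[i])
  }
  is_l <- ph == "L"; is_d <- ph == "D"
  if (!any(is_l) && !any(is_d)) stop("no usable episode")
  fn <- function(par) {
    gc <- par[1]; rs <- par[2]; s_u <- par[3]
    if (gc <= 0 || rs <= 0 || s_u <= params$SWA_L) return(Inf)
    sim <- tryCatch(
      .simulate_core(trig$wt, trig$remt,
                     params$rc, params$fc_R, params$fc_W, params$SWA_L,
                     gc, rs, s_u, init[["SWA_0"]], init[["S_0"]],
                     as.integer(substeps)),
      error = function(e) NULL)
    if (is.null(sim)) return(Inf)
    m_sim <- vapply(idx_list, function(ii) mean(sim$swa_sim[ii]), 0)
    d2 <- (m_emp - m_sim)^2
    ml <- if (any(is_l)) mean(d2[is_l]) else NA_real_
    md <- if (any(is_d)) mean(d2[is_d]) else NA_real_
    if (is.na(ml)) md else if (is.na(md)) ml else (ml + md) / 2
  }
  attr(fn, "episodes") <- episodes
  attr(fn, "triggers") <- trig
  attr(fn, "init") <- init
  attr(fn, "smoothed") <- smoothed
  fn
}

#' Run one stage of the multi-start simplex search
#'
#' Runs a derivative-free Nelder-Mead minimisation of the squared error
#' from each starting point. The simplex settings emulate a classic
#' `fminsearch`-style search: relative tolerance 1e-4, at most `200 * 3`
#' iterations. The full forward simulation is re-run at every objective
#' evaluation.
#'
#' @param starts data.frame with columns `gc`, `rs`, `s_u`.
#' @param objective function from [make_objective()].
#' @param reltol relative convergence tolerance.
#' @param maxit maximum iterations per start.
#' @return data.frame with the start, the converged parameters, `err`,
#'   the evaluation count and the convergence code per row.
#' @export
run_stage <- function(starts, objective, reltol = 1e-4, maxit = 600) {
  rows <- lapply(seq_len(nrow(starts)), function(i) {
    p0 <- c(starts$gc[i], starts$rs[i], starts$s_u[i])
    fit <- optim(p0, objective, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit,
                                parscale = abs(p0)))
    data.frame(start_gc = p0[1], start_rs = p0[2], start_s_u = p0[3],
               gc = fit$par[1], rs = fit$par[2], s_u = fit$par[3],
               err = fit$value, evals = fit$counts[["function"]],
               convergence = fit$convergence)
  })
  do.call(rbind, rows)
}

#' Two-stage multi-start estimation of (gc, rs, S_U)
#'
#' Stage 1 runs nine simplex searches from the 3 x 3 default grid of
#' `(gc, rs)` starts with a common `S_U` start; the winner seeds nine
#' refined stage-2 starts (see [stage2_starts()]). The final parameters
#' are the stage-2 minimum; ties break toward the lowest start index.
#' The relative spread `(max Err - min Err) / min Err` over the nine
#' stage-2 squared errors is reported as a stability diagnostic (values
#' below 10% indicate a stable solution).
#'
#' @param x an `epoch_series` over the fit window (normalised SWA).
#' @param derivation SWA column used.
#' @param derivation_type `"frontal"` or `"occipital"` start grid.
#' @param params fixed [model_params()].
#' @param smooth_window,substeps,ba_as_wake passed to [make_objective()].
#' @param reltol,maxit passed to [run_stage()].
#' @return list of class `swa_fit`: `gc`, `rs`, `s_u`, `err`, `spread`,
#'   `stage1`, `stage2` (per-start tables), `init`, `derivation`.
#' @export
two_stage_fit <- function(x, derivation = 1,
                          derivation_type = c("frontal", "occipital"),
                          params = model_params(), smooth_window = 35,
                          substeps = 10, ba_as_wake = FALSE,
                          reltol = 1e-4, maxit = 600) {
  derivation_type <- match.arg(derivation_type)
  objective <- make_objective(x, derivation, params, smooth_window,
                              substeps, ba_as_wake)
  s1 <- run_stage(stage1_starts(derivation_type), objective,
                  reltol, maxit)
  w1 <- which.min(s1$err)
  s2 <- run_stage(stage2_starts(s1[w1, c("gc", "rs", "s_u")]), objective,
                  reltol, maxit)
  w2 <- which.min(s2$err)
  spread <- (max(s2$err) - min(s2$err)) / min(s2$err)
  structure(list(gc = s2$gc[w2], rs = s2$rs[w2], s_u = s2$s_u[w2],
                 err = s2$err[w2], spread = spread,
                 stage1 = s1, stage2 = s2,
                 init = attr(objective, "init"),
                 derivation = if (is.character(derivation)) derivation
                              else derivations(x)[derivation],
                 derivation_type = derivation_type),
            class = "swa_fit")
}

#' @export
print.swa_fit <- function(x, ...) {
  cat("<swa_fit> derivation: ", x$derivation, " (", x$derivation_type,
      " grid)\n", sep = "")
  cat(sprintf("  gc = %.6g ts^-1, rs = %.6g ts^-1, S_U = %.5g%%\n",
              x$gc, x$rs, x$s_u))
  cat(sprintf("  Err = %.6g; stage-2 spread = %.2f%%\n",
              x$err, 100 * x$spread))
  invisible(x)
}

#' Serialise a fit result to JSON
#' @param fit a `swa_fit`.
#' @param path output path.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(
    list(gc = fit$gc, rs = fit$rs, s_u = fit$s_u, err = fit$err,
         spread = fit$spread, s_0 = fit$init[["S_0"]],
         swa_0 = fit$init[["SWA_0"]], derivation = fit$derivation,
         derivation_type = fit$derivation_type,
         stage1 = fit$stage1, stage2 = fit$stage2),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Assemble the optimisation window for a protocol
#'
#' * `RW` (regular wheel): the first 48 h are both baseline and fit
#'   window.
#' * `CW` (complex wheel): the 48 h of baseline preceding the wheel
#'   exchange (taken to occur at hour 48) form the fit window; the
#'   prediction window is the last regular-wheel day plus the first
#'   complex-wheel day.
#' * `EW` (enforced/exploratory wakefulness): only 24 h of baseline
#'   exist, so the first day is duplicated (states, artifacts, phases and
#'   SWA) to give a 48-h fit window; predictions run over the original
#'   recording (baseline day + deprivation/recovery day).
#'
#' SWA is normalised to the NREM mean over the protocol's baseline.
#'
#' @param x an `epoch_series` covering the protocol's span.
#' @param protocol `"RW"`, `"CW"` or `"EW"`.
#' @return list with `fit` (normalised `epoch_series`),
#'   `prediction_window` (0-based half-open interval into the original
#'   series), `baseline_window`, and `protocol`.
#' @export
prepare_fit_window <- function(x, protocol = c("RW", "CW", "EW")) {
  protocol <- match.arg(protocol)
  h48 <- 2L * TS_PER_DAY
  if (protocol == "RW") {
    if (n_ts(x) < h48) stop("RW requires >= 48 h")
    fit <- series_window(x, 0L, h48)
    fit <- normalize_swa(fit)
    list(fit = fit, prediction_window = c(0L, h48),
         baseline_window = c(0L, h48), protocol = protocol)
  } else if (protocol == "CW") {
    if (n_ts(x) < 3L * TS_PER_DAY) stop("CW requires >= 72 h")
    fit <- series_window(x, 0L, h48)
    fit <- normalize_swa(fit)
    list(fit = fit, prediction_window = c(TS_PER_DAY, 3L * TS_PER_DAY),
         baseline_window = c(0L, h48), protocol = protocol)
  } else {
    if (n_ts(x) < TS_PER_DAY) stop("EW requires >= 24 h of baseline")
    day1 <- series_window(x, 0L, TS_PER_DAY)
    fit <- series_concat(day1, day1)
    fit <- normalize_swa(fit, c(0L, TS_PER_DAY))
    list(fit = fit,
         prediction_window = c(0L, min(n_ts(x), h48)),
         baseline_window = c(0L, TS_PER_DAY), protocol = protocol)
  }
}
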