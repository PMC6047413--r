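#' Model parameters
#'
#' All symbols of the coupled SWA / Process S equations. The time unit is
#' one 4-s scoring epoch (ts); rates are per ts, levels are % of the mean
#' NREM SWA over baseline.
#'
#' SWA dynamics: a sigmoid-like build-up active only outside the triggers,
#' and two exponential fall terms toward the lower asymptote `SWA_L`,
#' switched on by the REM and wake triggers:
#' \deqn{dSWA/dt = rc \cdot SWA \cdot (S/S_U)(1 - SWA/S)(1-WT)(1-REMT)
#'   - fc_R (SWA - SWA_L) REMT - fc_W (SWA - SWA_L) WT}
#' Process S declines in proportion to SWA and rises toward its upper
#' asymptote:
#' \deqn{dS/dt = -gc \cdot SWA + (S_U - S) rs}
#'
#' @param rc build-up rate of SWA within NREM episodes, ts^-1 (0.5).
#' @param fc_R fall constant under the REM trigger, ts^-1 (0.2; 0.1-0.3
#'   depending on animal/derivation).
#' @param fc_W fall constant under the wake trigger, ts^-1 (0.2).
#' @param SWA_L lower asymptote of SWA, % (20).
#' @param t_a,t_p advance/prolongation of the REM trigger, ts (8, 6).
#' @param t_aw,t_pw advance/prolongation of the wake trigger, ts (8, 4).
#' @param gc gain constant: decline of Process S per unit SWA, ts^-1
#'   (estimated per animal and derivation; default a typical frontal
#'   value).
#' @param rs rise rate of Process S, ts^-1 (estimated).
#' @param S_U upper asymptote of Process S, % (estimated).
#' @param S_0 initial Process S level, % (`NA` until chosen from data:
#'   mean SWA over the first NREM episode of at least 3 min).
#' @param SWA_0 initial SWA level, % (`NA` until chosen from data: the
#'   first usable empirical SWA value).
#' @return list of class `model_params`.
#' @export
model_params <- function(rc = 0.5, fc_R = 0.2, fc_W = 0.2, SWA_L = 20,
                         t_a = 8, t_p = 6, t_aw = 8, t_pw = 4,
                         gc = 0.0010, rs = 0.0002, S_U = 400,
                         S_0 = NA_real_, SWA_0 = NA_real_) {
  p <- list(rc = rc, fc_R = fc_R, fc_W = fc_W, SWA_L = SWA_L,
            t_a = t_a, t_p = t_p, t_aw = t_aw, t_pw = t_pw,
            gc = gc, rs = rs, S_U = S_U, S_0 = S_0, SWA_0 = SWA_0)
  rates <- c("rc", "fc_R", "fc_W", "gc", "rs")
  if (any(unlist(p[rates]) < 0)) stop("all rates must be >= 0")
  if (any(unlist(p[c("t_a", "t_p", "t_aw", "t_pw")]) < 0))
    stop("trigger offsets must be >= 0")
  if (SWA_L >= S_U) stop("SWA_L must be below S_U")
  if (!is.na(SWA_0) && SWA_0 < SWA_L)
    warning("SWA_0 below the lower asymptote SWA_L")
  if (!is.na(S_0) && (S_0 <= SWA_L || S_0 > S_U))
    warning("S_0 outside (SWA_L, S_U]")
  class(p) <- "model_params"
  p
}

#' Instantaneous model derivatives
#'
#' Right-hand side of the coupled equations at one state point; mainly a
#' reference implementation for checking the integrator.
#'
#' @param swa current SWA level, %.
#' @param s current Process S level, % (must be > 0).
#' @param wt,remt wake / REM trigger values (0 or 1).
#' @param params a [model_params()] list.
#' @return named numeric `c(dswa, ds)` in % per ts.
#' @export
swa_rhs <- function(swa, s, wt, remt, params) {
  if (s <= 0) stop("Process S must be positive")
  build <- params$rc * swa * (s / params$S_U) * (1 - swa / s) *
    (1 - wt) * (1 - remt)
  dswa <- build - params$fc_R * (swa - params$SWA_L) * remt -
    params$fc_W * (swa - params$SWA_L) * wt
  ds <- -params$gc * swa + (params$S_U - s) * params$rs
  c(dswa = dswa, ds = ds)
}

#' Simulate SWA and Process S over a recording
#'
#' Integrates the model with triggers held piecewise constant within each
#' 4-s epoch, using classical RK4 at `substeps` fixed substeps per epoch
#' (compiled). The per-epoch output is the time average of the dense
#' solution over that epoch, mirroring the convention of averaging all
#' solver points belonging to one epoch.
#'
#' @param triggers list with integer vectors `wt` and `remt` (from
#'   [build_triggers()]), equal length.
#' @param params a [model_params()] with `SWA_0` and `S_0` set (unless
#'   given explicitly).
#' @param swa0,s0 initial conditions, % (default `params$SWA_0`,
#'   `params$S_0`).
#' @param substeps RK4 substeps per epoch (default 10, i.e. max step
#'   0.4 s; the vector field is smooth within an epoch so this is far
#'   inside the accuracy needed).
#' @return list of class `swa_simulation`: `swa_sim`, `s_sim` (per-epoch
#'   averages), `swa_end`, `s_end` (state at epoch boundaries), `substeps`,
#'   `n_steps`.
#' @export
simulate_swa <- function(triggers, params, swa0 = params$SWA_0,
                         s0 = params$S_0, substeps = 10) {
  if (is.na(swa0) || is.na(s0))
    stop("initial conditions SWA_0 and S_0 must be set")
  wt <- as.integer(triggers$wt)
  remt <- as.integer(triggers$remt)
  if (length(wt) != length(remt))
    stop("wt and remt must have equal length")
  res <- .simulate_core(wt, remt,
                        params$rc, params$fc_R, params$fc_W, params$SWA_L,
                        params$gc, params$rs, params$S_U,
                        swa0, s0, as.integer(substeps))
  res$substeps <- substeps
  class(res) <- "swa_simulation"
  res
}

#' @export
print.swa_simulation <- function(x, ...) {
  cat("<swa_simulation> ", length(x$swa_sim), " epochs, ",
      x$substeps, " substeps/epoch\n", sep = "")
  cat("  SWA range: ", paste(signif(range(x$swa_sim), 5), collapse = " - "),
      "; S range: ", paste(signif(range(x$s_sim), 5), collapse = " - "),
      "\n", sep = "")
  invisible(x)
}

#' Write a simulation as TSV
#' @param sim a `swa_simulation`.
#' @param path output path.
#' @export
write_simulation <- function(sim, path) {
  df <- data.frame(epoch_index = seq_along(sim$swa_sim) - 1L,
                   swa_sim = sim$swa_sim, s_sim = sim$s_sim)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
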