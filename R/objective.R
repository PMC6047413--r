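#' Moving-median smoothing of an SWA trace
#'
#' Centred moving median with an odd window; at the boundaries the window
#' is clipped to the available epochs. Artifact epochs contribute nothing
#' to any window's median and are left unvalued (`NA`) in the output.
#'
#' @param values per-epoch numeric vector.
#' @param window odd window length in epochs (default 35).
#' @param artifact optional logical mask of epochs to exclude.
#' @return smoothed numeric vector.
#' @export
smooth_moving_median <- function(values, window = 35, artifact = NULL) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  n <- length(values)
  if (is.null(artifact)) artifact <- rep(FALSE, n)
  v <- values
  v[artifact] <- NA_real_
  h <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (artifact[i]) next
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    out[i] <- median(v[lo:hi], na.rm = TRUE)
  }
  out
}

#' Per-episode deviations between empirical and simulated SWA
#'
#' For each NREM episode, the empirical and the simulated mean SWA are
#' taken over exactly the same usable epochs (state `N`, non-artifact,
#' value present) and their difference `d(i) = m_empirical - m_simulation`
#' is recorded together with the episode's lighting phase. Episodes with
#' no usable epoch are skipped.
#'
#' @param episodes data.frame from [detect_nrem_episodes()].
#' @param x an `epoch_series` with (normalised) SWA.
#' @param sim a `swa_simulation` over the same epochs.
#' @param derivation SWA column used.
#' @param smoothed optional smoothed empirical trace (from
#'   [smooth_moving_median()]) used instead of the raw SWA.
#' @return data.frame with `start`, `end`, `phase`, `m_emp`, `m_sim`, `d`.
#' @export
episode_deviations <- function(episodes, x, sim, derivation = 1,
                               smoothed = NULL) {
  emp <- if (is.null(smoothed)) x$swa[, derivation] else smoothed
  simv <- sim$swa_sim
  if (length(simv) != n_ts(x)) stop("simulation length mismatch")
  rows <- lapply(seq_len(nrow(episodes)), function(i) {
    idx <- (episodes$start[i] + 1L):episodes$end[i]
    use <- x$state[idx] == "N" & !x$artifact[idx] & !is.na(emp[idx])
    if (!any(use)) return(NULL)
    m_emp <- mean(emp[idx][use])
    m_sim <- mean(simv[idx][use])
    data.frame(start = episodes$start[i], end = episodes$end[i],
               phase = episodes$phase[i], m_emp = m_emp, m_sim = m_sim,
               d = m_emp - m_sim, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0),
                      phase = character(0), m_emp = numeric(0),
                      m_sim = numeric(0), d = numeric(0))
  out
}

#' Light/dark-balanced squared error
#'
#' `M(phase)` is the mean of `d(i)^2` over that phase's episodes and the
#' overall error is `Err = (M(light) + M(dark)) / 2`, weighing the phases
#' equally even though NREM episodes are about three times more numerous
#' in the light phase. If one phase has no episode, `Err` falls back to
#' the populated phase's `M` with a warning.
#'
#' @param devs data.frame from [episode_deviations()].
#' @return list of class `objective_report`: `m_light`, `m_dark`, `err`,
#'   `n_light`, `n_dark`, and the deviations `devs`.
#' @export
squared_error <- function(devs) {
  dl <- devs$d[devs$phase == "L"]
  dd <- devs$d[devs$phase == "D"]
  m_light <- if (length(dl)) mean(dl^2) else NA_real_
  m_dark <- if (length(dd)) mean(dd^2) else NA_real_
  if (!length(dl) && !length(dd)) stop("no episodes with usable epochs")
  if (!length(dl) || !length(dd)) {
    warning("one lighting phase has no NREM episode; ",
            "using the populated phase only")
    err <- if (length(dl)) m_light else m_dark
  } else {
    err <- (m_light + m_dark) / 2
  }
  structure(list(m_light = m_light, m_dark = m_dark, err = err,
                 n_light = length(dl), n_dark = length(dd), devs = devs),
            class = "objective_report")
}

#' @export
print.objective_report <- function(x, ...) {
  cat("<objective_report> Err = ", signif(x$err, 6),
      " (M_light = ", signif(x$m_light, 6), ", n = ", x$n_light,
      "; M_dark = ", signif(x$m_dark, 6), ", n = ", x$n_dark, ")\n",
      sep = "")
  invisible(x)
}

#' Serialise an objective report to JSON
#' @param report an `objective_report`.
#' @param path output path.
#' @export
write_objective_report <- function(report, path) {
  jsonlite::write_json(list(err = report$err, m_light = report$m_light,
                            m_dark = report$m_dark,
                            n_light = report$n_light,
                            n_dark = report$n_dark),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Binned signed and absolute prediction errors over a window
#'
#' Compares simulated against empirical SWA epoch-by-epoch over a ts
#' window (e.g. the 40 min = 600 ts following a long wake bout, in
#' 10-min = 150-ts bins). Only `N`-state non-artifact epochs contribute.
#' The signed error is `mean(sim - emp)`, so positive values mean the
#' model overestimates; the absolute error is `mean(|sim - emp|)`. Empty
#' bins yield `NA`, not zero.
#'
#' @param x an `epoch_series`.
#' @param sim a `swa_simulation` over the same epochs.
#' @param window 0-based half-open `c(from, to)` ts interval.
#' @param bin bin width in ts (default 150); `NULL` for one bin spanning
#'   the window.
#' @param derivation SWA column used.
#' @param smoothed optional smoothed empirical trace; the default compares
#'   against raw empirical SWA.
#' @return data.frame with `bin_start`, `bin_end`, `n_epochs`,
#'   `signed_error`, `abs_error`.
#' @export
window_errors <- function(x, sim, window, bin = 150, derivation = 1,
                          smoothed = NULL) {
  emp <- if (is.null(smoothed)) x$swa[, derivation] else smoothed
  from <- max(0L, as.integer(window[1]))
  to <- min(n_ts(x), as.integer(window[2]))
  if (from >= to) stop("empty window")
  if (is.null(bin)) bin <- to - from
  edges <- seq(from, to, by = bin)
  if (edges[length(edges)] < to) edges <- c(edges, to)
  rows <- lapply(seq_len(length(edges) - 1L), function(b) {
    idx <- (edges[b] + 1L):edges[b + 1L]
    use <- x$state[idx] == "N" & !x$artifact[idx] & !is.na(emp[idx])
    diffs <- sim$swa_sim[idx][use] - emp[idx][use]
    data.frame(bin_start = edges[b], bin_end = edges[b + 1L],
               n_epochs = sum(use),
               signed_error = if (any(use)) mean(diffs) else NA_real_,
               abs_error = if (any(use)) mean(abs(diffs)) else NA_real_)
  })
  do.call(rbind, rows)
}
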