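#' Detect NREM sleep episodes
#'
#' A NREM episode is a maximal run of `N` epochs, tolerating interruptions
#' of at most `max_gap` consecutive non-`N` epochs at a time, trimmed so
#' that both the first and last epoch are `N`, and lasting at least
#' `min_len` epochs in total (gaps included). The defaults encode
#' "longer than 1 min" (1 min = 15 ts, so >= 16 ts) with interruptions of
#' at most 4 ts (16 s).
#'
#' @param x an `epoch_series`.
#' @param min_len minimum episode span in epochs (default 16).
#' @param max_gap longest tolerated single interruption, epochs (default 4).
#' @param kind label attached to the detected episodes.
#' @return data.frame with 0-based half-open columns `start`, `end`,
#'   plus `kind` and `phase` (lighting phase of the start epoch).
#' @export
detect_nrem_episodes <- function(x, min_len = 16, max_gap = 4,
                                 kind = "nrem_episode") {
  runs <- state_runs(x$state == "N")
  if (!nrow(runs)) return(empty_episodes(kind))
  # merge successive N runs separated by gaps of <= max_gap epochs
  start <- runs$start[1]; end <- runs$end[1]
  out_s <- integer(0); out_e <- integer(0)
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - end <= max_gap) {
        end <- runs$end[i]
      } else {
        out_s <- c(out_s, start); out_e <- c(out_e, end)
        start <- runs$start[i]; end <- runs$end[i]
      }
    }
  }
  out_s <- c(out_s, start); out_e <- c(out_e, end)
  keep <- (out_e - out_s) >= min_len
  episodes_df(out_s[keep], out_e[keep], kind, x)
}

#' Detect long NREM episodes (>= 3 min)
#'
#' Same construction as [detect_nrem_episodes()] with a 45-epoch (3 min)
#' minimum span; used among other things to pick the initial Process S
#' level.
#'
#' @inheritParams detect_nrem_episodes
#' @export
detect_long_nrem_episodes <- function(x, min_len = 45, max_gap = 4) {
  detect_nrem_episodes(x, min_len = min_len, max_gap = max_gap,
                       kind = "long_nrem_episode")
}

#' Detect long wake bouts
#'
#' Builds maximal wake-dominated periods by merging runs of wake (`W`,
#' and `BA`) across sleep gaps of at most `max_sleep_gap` epochs, keeps
#' periods of at least `min_len` epochs, and tags at most the longest
#' period per 24-h day. The defaults (1 h minimum, 5 min gaps, longest
#' per day) are configuration, not values taken from any reference
#' analysis; consolidated spontaneous dark-phase wake bouts in mice run
#' for several hours.
#'
#' @param x an `epoch_series`.
#' @param min_len minimum bout span, epochs (default 900 = 1 h).
#' @param max_sleep_gap longest tolerated sleep interruption, epochs
#'   (default 75 = 5 min).
#' @param longest_per_day keep only the longest qualifying bout in each
#'   24-h day (day of the bout's start epoch); default `TRUE`.
#' @return data.frame as in [detect_nrem_episodes()], kind
#'   `"long_wake_bout"`.
#' @export
detect_long_wake_bouts <- function(x, min_len = 900, max_sleep_gap = 75,
                                   longest_per_day = TRUE) {
  runs <- state_runs(x$state %in% c("W", "BA"))
  if (!nrow(runs)) return(empty_episodes("long_wake_bout"))
  start <- runs$start[1]; end <- runs$end[1]
  out_s <- integer(0); out_e <- integer(0)
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - end <= max_sleep_gap) {
        end <- runs$end[i]
      } else {
        out_s <- c(out_s, start); out_e <- c(out_e, end)
        start <- runs$start[i]; end <- runs$end[i]
      }
    }
  }
  out_s <- c(out_s, start); out_e <- c(out_e, end)
  keep <- (out_e - out_s) >= min_len
  out_s <- out_s[keep]; out_e <- out_e[keep]
  if (longest_per_day && length(out_s)) {
    day <- out_s %/% TS_PER_DAY
    sel <- unlist(lapply(split(seq_along(out_s), day), function(ii) {
      ii[which.max(out_e[ii] - out_s[ii])]
    }), use.names = FALSE)
    sel <- sort(sel)
    out_s <- out_s[sel]; out_e <- out_e[sel]
  }
  episodes_df(out_s, out_e, "long_wake_bout", x)
}

# maximal runs of TRUE as 0-based half-open intervals
state_runs <- function(flag) {
  r <- rle(flag)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  data.frame(start = start[r$values], end = end[r$values])
}

episodes_df <- function(start, end, kind, x) {
  data.frame(start = as.integer(start), end = as.integer(end),
             kind = rep_len(kind, length(start)),
             phase = x$phase[start + 1L],
             stringsAsFactors = FALSE)
}

empty_episodes <- function(kind) {
  data.frame(start = integer(0), end = integer(0),
             kind = character(0), phase = character(0),
             stringsAsFactors = FALSE)
}

#' Mean SWA of one episode
#'
#' Mean over the episode's usable epochs: state `N`, non-artifact, value
#' not `NA`. Gap epochs inside a merged episode are not `N` and never
#' contribute.
#'
#' @param episode a one-row data.frame (or list) with 0-based `start`,
#'   `end`.
#' @param x an `epoch_series`.
#' @param derivation column name or index of the SWA derivation.
#' @param values optional per-epoch replacement values (e.g. a smoothed
#'   empirical trace or a simulated one) used instead of `x$swa`.
#' @return mean SWA, or `NA` if the episode has no usable epoch.
#' @export
episode_mean_swa <- function(episode, x, derivation = 1, values = NULL) {
  idx <- (episode$start + 1L):episode$end
  v <- if (is.null(values)) x$swa[, derivation] else values
  use <- x$state[idx] == "N" & !x$artifact[idx] & !is.na(v[idx])
  if (!any(use)) return(NA_real_)
  mean(v[idx][use])
}

#' Write episodes as a BED-like TSV
#' @param episodes data.frame from a `detect_*` function.
#' @param path output path.
#' @export
write_episodes <- function(episodes, path) {
  out <- data.frame(start_ts = episodes$start, end_ts = episodes$end,
                    kind = episodes$kind, phase = episodes$phase)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
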