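#' Build a binary trigger from a hypnogram state
#'
#' A trigger anticipates and outlasts the scored state: every maximal run
#' `[a, b)` of the target state contributes the interval
#' `[a - advance, b + prolong)` (clipped to the recording); the trigger is
#' the union of these intervals. Runs of any length generate a trigger,
#' and overlapping extensions merge.
#'
#' @param x an `epoch_series`.
#' @param target_state state code generating the trigger (`"R"` for the
#'   REM trigger REMT, `"W"` for the wake trigger WT).
#' @param advance epochs by which the trigger precedes the state onset.
#' @param prolong epochs by which the trigger outlasts the state offset.
#' @param states optional character vector of state codes treated as the
#'   target (e.g. `c("W", "BA")` to let brief awakenings drive the wake
#'   trigger); overrides `target_state`.
#' @return integer 0/1 vector of length `n_ts(x)`.
#' @export
build_trigger <- function(x, target_state = "R", advance = 8, prolong = 6,
                          states = NULL) {
  if (advance < 0 || prolong < 0) stop("advance and prolong must be >= 0")
  if (is.null(states)) states <- target_state
  n <- n_ts(x)
  out <- integer(n)
  runs <- state_runs(x$state %in% states)
  if (!nrow(runs)) return(out)
  lo <- pmax(0L, runs$start - as.integer(advance))
  hi <- pmin(n, runs$end + as.integer(prolong))
  for (i in seq_along(lo)) out[(lo[i] + 1L):hi[i]] <- 1L
  out
}

#' Build the REM and wake trigger pair
#'
#' Convenience wrapper constructing `REMT(t)` from REM runs with offsets
#' `(t_a, t_p)` and `WT(t)` from wake runs with `(t_aw, t_pw)`.
#' Brief awakenings are scored as a distinct state and by default do not
#' generate the wake trigger; set `ba_as_wake = TRUE` to include them in
#' the wake runs.
#'
#' @param x an `epoch_series`.
#' @param params a [model_params()] list supplying `t_a`, `t_p`, `t_aw`,
#'   `t_pw`.
#' @param ba_as_wake treat `BA` epochs as wake when building `WT`.
#' @return list with integer vectors `remt` and `wt`.
#' @export
build_triggers <- function(x, params = model_params(), ba_as_wake = FALSE) {
  wt_states <- if (ba_as_wake) c("W", "BA") else "W"
  list(remt = build_trigger(x, "R", params$t_a, params$t_p),
       wt = build_trigger(x, states = wt_states,
                          advance = params$t_aw, prolong = params$t_pw))
}
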