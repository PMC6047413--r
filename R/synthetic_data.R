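#' Configuration for the synthetic mouse dataset generator
#'
#' The generator emulates C57BL/6J-like sleep architecture under a 12:12
#' light/dark cycle: per-phase semi-Markov chains over \{W, N, R, BA\}
#' with geometric dwell times, one consolidated multi-hour wake bout
#' injected at each dark onset, and SWA produced by the forward model
#' itself plus epoch noise. The default chains are calibrated to the
#' canonical mouse state occupancies (light: about 60% NREM, 11% REM,
#' 25% wake, 4% brief awakenings; dark: about 79% wake, 17% NREM) and
#' the default bout duration (6.23 +/- 2.58 h) to reported consolidated
#' dark-phase wake bouts.
#'
#' @param n_days number of 24-h days (default 2, i.e. the 48-h fit span).
#' @param seed integer seed; the whole dataset is deterministic given the
#'   config.
#' @param truth [model_params()] used to generate SWA (ground truth for
#'   recovery studies); needs `S_0` and `SWA_0` set.
#' @param sigma lognormal sdlog of the multiplicative per-epoch noise on
#'   NREM SWA (default 0.15, i.e. 15% epoch noise).
#' @param sigma_off additive SD of SWA in wake/REM/BA epochs around
#'   `SWA_L` (default 5%).
#' @param artifact_rate fraction of epochs flagged artifactual (default
#'   0.028).
#' @param bout_mean_h,bout_sd_h,bout_range_h mean, SD and truncation
#'   range (hours) of the injected dark-phase wake bout.
#' @param light,dark per-phase chain specs: list with `dwell` (named mean
#'   dwell times in epochs for W, N, R; BA dwells are geometric with
#'   `ba_p` truncated at 5) and `trans` (4x4 row-stochastic embedded
#'   transition matrix over W, N, R, BA, zero diagonal).
#' @param ba_p geometric parameter of BA dwell times.
#' @param onset_dwell mean dwell (epochs) of the first NREM run after
#'   each sustained waking period (light onset and post-bout sleep
#'   onset). Sleep onset under high pressure is consolidated, which is
#'   also what makes the first >= 3 min NREM episode a faithful read-out
#'   of the initial Process S level.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_days = 2, seed = 1,
                             truth = model_params(S_0 = 300, SWA_0 = 100),
                             sigma = 0.15, sigma_off = 5,
                             artifact_rate = 0.028,
                             bout_mean_h = 6.23, bout_sd_h = 2.58,
                             bout_range_h = c(1, 11),
                             light = NULL, dark = NULL, ba_p = 0.5,
                             onset_dwell = 150) {
  if (artifact_rate < 0 || artifact_rate > 0.1)
    stop("artifact_rate must lie in [0, 0.1]")
  states <- STATE_LEVELS
  if (is.null(light)) {
    trans <- matrix(c(0, 1, 0, 0,
                      0, 0, 0.2933, 0.7067,
                      0.3068, 0.3752, 0, 0.3180,
                      0.2, 0.8, 0, 0),
                    4, 4, byrow = TRUE, dimnames = list(states, states))
    light <- list(dwell = c(W = 40, N = 24, R = 15), trans = trans,
                  start = "N")
  }
  if (is.null(dark)) {
    trans <- matrix(c(0, 1, 0, 0,
                      0.2464, 0, 0.1962, 0.5574,
                      0.1, 0.655, 0, 0.245,
                      0, 1, 0, 0),
                    4, 4, byrow = TRUE, dimnames = list(states, states))
    dark <- list(dwell = c(W = 120, N = 20, R = 12), trans = trans,
                 start = "N")
  }
  for (ph in list(light, dark)) {
    if (any(abs(rowSums(ph$trans) - 1) > 1e-8))
      stop("transition matrix rows must sum to 1")
    if (any(ph$dwell <= 0)) stop("dwell means must be > 0")
  }
  structure(list(n_days = n_days, seed = seed, truth = truth,
                 sigma = sigma, sigma_off = sigma_off,
                 artifact_rate = artifact_rate,
                 bout_mean_h = bout_mean_h, bout_sd_h = bout_sd_h,
                 bout_range_h = bout_range_h,
                 light = light, dark = dark, ba_p = ba_p,
                 onset_dwell = onset_dwell),
            class = "generator_config")
}

# one semi-Markov realisation of length n epochs; the first dwell can be
# drawn with its own (longer) mean to model consolidated sleep onset
# after sustained waking
semi_markov <- function(chain, n, ba_p, first_dwell = NULL) {
  if (n <= 0) return(character(0))
  out <- character(0)
  s <- chain$start
  first <- TRUE
  while (length(out) < n) {
    dwell <- if (s == "BA") {
      min(rgeom(1, ba_p) + 1L, 5L)
    } else {
      m <- if (first && !is.null(first_dwell)) first_dwell
           else chain$dwell[[s]]
      rgeom(1, 1 / m) + 1L
    }
    first <- FALSE
    out <- c(out, rep(s, dwell))
    s <- sample(STATE_LEVELS, 1, prob = chain$trans[s, ])
  }
  out[seq_len(n)]
}

#' Generate a synthetic hypnogram
#'
#' Seeded semi-Markov simulation per lighting phase with one consolidated
#' wake bout injected at each dark onset. States and phases only; SWA is
#' added by [generate_swa()].
#'
#' @param cfg a [generator_config()].
#' @return an `epoch_series` without SWA.
#' @export
generate_hypnogram <- function(cfg) {
  set.seed(cfg$seed)
  ts_h <- 900  # epochs per hour
  days <- lapply(seq_len(cfg$n_days), function(d) {
    light <- semi_markov(cfg$light, TS_PER_PHASE, cfg$ba_p,
                         first_dwell = cfg$onset_dwell)
    bout_h <- min(max(rnorm(1, cfg$bout_mean_h, cfg$bout_sd_h),
                      cfg$bout_range_h[1]), cfg$bout_range_h[2])
    bout <- round(bout_h * ts_h)
    dark <- c(rep("W", bout),
              semi_markov(cfg$dark, TS_PER_PHASE - bout, cfg$ba_p,
                          first_dwell = cfg$onset_dwell))
    c(light, dark)
  })
  state <- unlist(days)
  epoch_series(state, phase = default_phase(length(state)))
}

#' Add model-generated noisy SWA to a hypnogram
#'
#' Builds the triggers with the ground-truth offsets, runs the forward
#' model, and derives empirical SWA: NREM epochs get the simulated value
#' times lognormal epoch noise, other states get `SWA_L` plus additive
#' noise (floored at 0), and a random fraction of epochs is flagged
#' artifactual. The trace is then renormalised to its own baseline NREM
#' mean, which is the unit empirical data come in; the ground truth is
#' rescaled identically (`truth_norm`) so that recovered parameters are
#' directly comparable.
#'
#' @param hyp an `epoch_series` (states/phases only).
#' @param cfg a [generator_config()] (noise model and truth).
#' @param seed seed for the noise draws (default `cfg$seed + 1`).
#' @param derivation name of the generated SWA column.
#' @return list of class `swa_synthetic`: `series` (normalised SWA),
#'   `truth` (raw), `truth_norm` (levels rescaled by the normalisation
#'   factor), `renorm`, `sim` (the noise-free simulation, raw units).
#' @export
generate_swa <- function(hyp, cfg, seed = cfg$seed + 1,
                         derivation = "fro") {
  set.seed(seed)
  truth <- cfg$truth
  trig <- build_triggers(hyp, truth)
  sim <- simulate_swa(trig, truth)
  n <- n_ts(hyp)
  is_n <- hyp$state == "N"
  swa <- numeric(n)
  swa[is_n] <- sim$swa_sim[is_n] *
    rlnorm(sum(is_n), meanlog = 0, sdlog = cfg$sigma)
  swa[!is_n] <- pmax(0, truth$SWA_L + rnorm(sum(!is_n), 0, cfg$sigma_off))
  artifact <- runif(n) < cfg$artifact_rate
  swa_m <- matrix(swa, ncol = 1, dimnames = list(NULL, derivation))
  series <- epoch_series(hyp$state, swa = swa_m, artifact = artifact,
                         phase = hyp$phase)
  series <- normalize_swa(series)
  k <- attr(series, "renorm")[[derivation]]
  truth_norm <- truth
  for (f in c("SWA_L", "S_0", "SWA_0", "S_U"))
    truth_norm[[f]] <- truth[[f]] * k
  structure(list(series = series, truth = truth,
                 truth_norm = truth_norm, renorm = k, sim = sim),
            class = "swa_synthetic")
}

#' Generate a complete synthetic dataset
#'
#' Composes [generate_hypnogram()] and [generate_swa()] and optionally
#' writes the epoch TSV, the ground truth and a manifest (seed + config
#' hash) to a directory.
#'
#' @param cfg a [generator_config()].
#' @param dir output directory (`NULL` to skip writing).
#' @return list of class `swa_synthetic` (see [generate_swa()]) with an
#'   added `manifest`.
#' @export
make_dataset <- function(cfg, dir = NULL) {
  hyp <- generate_hypnogram(cfg)
  ds <- generate_swa(hyp, cfg)
  cfg_json <- jsonlite::toJSON(config_fingerprint(cfg), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  ds$manifest <- list(seed = cfg$seed, n_days = cfg$n_days,
                      config_md5 = hash)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_epoch_table(ds$series, file.path(dir, "epochs.tsv"))
    jsonlite::write_json(c(unclass(ds$truth_norm),
                           list(renorm = ds$renorm)),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(ds$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  ds
}

# flat, order-stable summary of a config for hashing
config_fingerprint <- function(cfg) {
  list(n_days = cfg$n_days, seed = cfg$seed,
       truth = unclass(cfg$truth), sigma = cfg$sigma,
       sigma_off = cfg$sigma_off, artifact_rate = cfg$artifact_rate,
       bout = c(cfg$bout_mean_h, cfg$bout_sd_h, cfg$bout_range_h),
       light_dwell = as.numeric(cfg$light$dwell),
       light_trans = as.numeric(cfg$light$trans),
       dark_dwell = as.numeric(cfg$dark$dwell),
       dark_trans = as.numeric(cfg$dark$trans),
       ba_p = cfg$ba_p, onset_dwell = cfg$onset_dwell)
}

#' Read a ground-truth JSON back into model parameters
#' @param path path to a `truth.json` written by [make_dataset()].
#' @export
read_truth <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_params, v[setdiff(names(v), "renorm")])
}

#' State occupancy by lighting phase
#'
#' Fraction of epochs in each state, split by phase; handy for checking
#' generated architecture against target occupancies.
#'
#' @param x an `epoch_series`.
#' @return matrix phases x states of fractions.
#' @export
state_occupancy <- function(x) {
  out <- t(sapply(PHASE_LEVELS, function(ph) {
    sel <- x$phase == ph
    if (!any(sel)) return(rep(NA_real_, 4))
    tab <- table(factor(x$state[sel], STATE_LEVELS))
    as.numeric(tab) / sum(sel)
  }))
  colnames(out) <- STATE_LEVELS
  out
}
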