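#' Construct an epoch series
#'
#' An `epoch_series` holds one recording at 4-s epoch resolution: the scored
#' vigilance state, an artifact mask, the lighting phase, and zero or more
#' SWA traces (one column per EEG derivation, e.g. frontal and occipital).
#'
#' Epoch indexing is 0-based and intervals are half-open `[a, b)`;
#' recordings are assumed to start at light onset (ZT0).
#'
#' @param state character or factor of vigilance states, one of
#'   `"W"` (wake), `"N"` (NREM sleep), `"R"` (REM sleep), `"BA"`
#'   (brief awakening, runs of at most 5 epochs).
#' @param swa numeric matrix (epochs x derivations) of slow-wave activity
#'   (0.5-4 Hz EEG power), or a vector for a single derivation, or `NULL`.
#'   Columns should be named by derivation; unnamed columns are called
#'   `d1, d2, ...`.
#' @param artifact logical vector; `TRUE` marks epochs whose SWA must be
#'   ignored (the state label remains valid). Defaults to all `FALSE`.
#' @param phase `"L"`/`"D"` lighting phase per epoch. Defaults to 12:12
#'   blocks of 10800 epochs starting with light.
#' @param check_ba if `TRUE` (default), runs of `BA` longer than 5 epochs
#'   are an error.
#' @return object of class `epoch_series`.
#' @export
epoch_series <- function(state, swa = NULL, artifact = NULL, phase = NULL,
                         check_ba = TRUE) {
  state <- as.character(state)
  n <- length(state)
  bad <- which(!state %in% STATE_LEVELS)
  if (length(bad))
    stop("unknown state code '", state[bad[1]], "' at epoch ", bad[1] - 1L,
         " (row ", bad[1], ")")
  if (is.null(artifact)) artifact <- rep(FALSE, n)
  artifact <- as.logical(artifact)
  if (is.null(phase)) phase <- default_phase(n)
  phase <- as.character(phase)
  if (!all(phase %in% PHASE_LEVELS))
    stop("phase must be 'L' or 'D'")
  if (length(artifact) != n || length(phase) != n)
    stop("state, artifact and phase must have equal length")
  if (anyNA(artifact)) stop("artifact must be TRUE/FALSE without NA")
  if (!is.null(swa)) {
    if (is.null(dim(swa))) swa <- matrix(as.numeric(swa), ncol = 1)
    swa <- as.matrix(swa)
    storage.mode(swa) <- "double"
    if (nrow(swa) != n) stop("swa must have one row per epoch")
    if (is.null(colnames(swa)))
      colnames(swa) <- paste0("d", seq_len(ncol(swa)))
    ok <- !artifact
    bad_swa <- which(ok & apply(swa, 1, function(v) any(!is.finite(v) | v < 0)))
    if (length(bad_swa))
      stop("non-finite or negative SWA at non-artifact epoch ",
           bad_swa[1] - 1L, " (row ", bad_swa[1], ")")
  }
  if (check_ba) {
    r <- rle(state == "BA")
    if (any(r$values & r$lengths > 5L)) {
      i <- which(r$values & r$lengths > 5L)[1]
      at <- sum(r$lengths[seq_len(i - 1L)])
      stop("run of BA longer than 5 epochs starting at epoch ", at,
           " (row ", at + 1L, ")")
    }
  }
  structure(list(state = state, artifact = artifact, phase = phase,
                 swa = swa, epoch_duration = 4),
            class = "epoch_series")
}

default_phase <- function(n) {
  blocks <- rep(rep(PHASE_LEVELS, length.out = ceiling(n / TS_PER_PHASE)),
                each = TS_PER_PHASE)
  blocks[seq_len(n)]
}

#' Number of 4-s epochs in an epoch series
#' @param x an `epoch_series`.
#' @export
n_ts <- function(x) length(x$state)

#' Names of the SWA derivations in an epoch series
#' @param x an `epoch_series`.
#' @export
derivations <- function(x) colnames(x$swa)

#' @export
print.epoch_series <- function(x, ...) {
  cat("<epoch_series> ", n_ts(x), " epochs (", n_ts(x) * 4 / 3600,
      " h), derivations: ",
      if (is.null(x$swa)) "none" else paste(derivations(x), collapse = ", "),
      "\n", sep = "")
  tab <- table(factor(x$state, STATE_LEVELS))
  cat("  states: ", paste(names(tab), tab, sep = "=", collapse = " "),
      "; artifacts: ", sum(x$artifact), "\n", sep = "")
  invisible(x)
}

#' Subset an epoch series by a half-open epoch interval
#'
#' @param x an `epoch_series`.
#' @param from,to 0-based half-open bounds `[from, to)`.
#' @export
series_window <- function(x, from, to) {
  if (from < 0 || to > n_ts(x) || from >= to)
    stop("window [", from, ", ", to, ") out of range")
  idx <- (from + 1L):to
  epoch_series(x$state[idx],
               swa = if (is.null(x$swa)) NULL else x$swa[idx, , drop = FALSE],
               artifact = x$artifact[idx], phase = x$phase[idx])
}

#' Concatenate epoch series
#' @param ... `epoch_series` objects with identical derivations.
#' @export
series_concat <- function(...) {
  xs <- list(...)
  swa <- if (is.null(xs[[1]]$swa)) NULL else
    do.call(rbind, lapply(xs, `[[`, "swa"))
  epoch_series(unlist(lapply(xs, `[[`, "state")),
               swa = swa,
               artifact = unlist(lapply(xs, `[[`, "artifact")),
               phase = unlist(lapply(xs, `[[`, "phase")))
}

#' Read an epoch table (TSV)
#'
#' The canonical interchange format is a UTF-8 tab-separated table with a
#' header and columns `epoch_index` (contiguous from 0), `state`
#' (`W|N|R|BA`), `artifact` (`0|1`), `phase` (`L|D`) and one `swa_<name>`
#' column per derivation.
#'
#' @param path file path.
#' @return an [epoch_series()].
#' @export
read_epoch_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("epoch_index", "state", "artifact", "phase")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!identical(as.integer(df$epoch_index), seq_len(nrow(df)) - 1L)) {
    bad <- which(as.integer(df$epoch_index) != seq_len(nrow(df)) - 1L)[1]
    stop("epoch_index not contiguous from 0 at row ", bad)
  }
  swa_cols <- grep("^swa_", names(df), value = TRUE)
  swa <- NULL
  if (length(swa_cols)) {
    swa <- as.matrix(df[swa_cols])
    colnames(swa) <- sub("^swa_", "", swa_cols)
  }
  epoch_series(df$state, swa = swa,
               artifact = df$artifact != 0, phase = df$phase)
}

#' Write an epoch table (TSV)
#'
#' Inverse of [read_epoch_table()]; `write_epoch_table(read_epoch_table(f), f2)`
#' reproduces `f` byte-wise at the writer's printed precision (15
#' significant digits).
#'
#' @param x an `epoch_series`.
#' @param path output file path.
#' @export
write_epoch_table <- function(x, path) {
  df <- data.frame(epoch_index = seq_len(n_ts(x)) - 1L,
                   state = x$state,
                   artifact = as.integer(x$artifact),
                   phase = x$phase,
                   stringsAsFactors = FALSE)
  if (!is.null(x$swa))
    for (d in derivations(x))
      df[[paste0("swa_", d)]] <- sprintf("%.15g", x$swa[, d])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}

#' Per-epoch EEG power spectra (Hann-tapered FFT)
#'
#' Computes a one-sided power spectrum per 4-s epoch of raw EEG on the
#' scoring grid: 0.25 Hz resolution, 0 to `max_freq` Hz (81 bins for the
#' default 20 Hz). Power is normalised so that the sum over the full
#' one-sided spectrum equals the energy of the Hann-windowed epoch
#' (Parseval).
#'
#' @param raw numeric matrix, one row per epoch, `sample_rate *
#'   epoch_duration` columns (1024 samples at 256 Hz); a vector is taken
#'   as a single epoch.
#' @param sample_rate samples per second (default 256).
#' @param max_freq highest frequency bin to keep, Hz (default 20; must lie
#'   on the 0.25 Hz grid). Use `sample_rate / 2` for the full spectrum.
#' @param epoch_duration epoch length in seconds (fixed 4 in this design).
#' @return matrix epochs x bins with `freq` attribute (Hz) and `artifact`
#'   attribute flagging epochs that contained NaN samples (their power is
#'   `NA`).
#' @export
epoch_band_power <- function(raw, sample_rate = 256, max_freq = 20,
                             epoch_duration = 4) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  n_samp <- sample_rate * epoch_duration
  if (ncol(raw) != n_samp)
    stop("each epoch must have ", n_samp, " samples (", epoch_duration,
         " s at ", sample_rate, " Hz), got ", ncol(raw))
  df <- 1 / epoch_duration
  if (max_freq > sample_rate / 2 || (max_freq / df) %% 1 != 0)
    stop("max_freq must lie on the ", df, " Hz bin grid within Nyquist")
  k_keep <- 0:(max_freq / df)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n_samp - 1)) / (n_samp - 1)))  # Hann
  bad <- unname(apply(raw, 1, function(v) anyNA(v)))
  out <- matrix(NA_real_, nrow(raw), length(k_keep))
  half <- n_samp / 2
  for (i in which(!bad)) {
    X <- fft(raw[i, ] * w)
    p <- Mod(X)^2 / n_samp
    one_sided <- p[1:(half + 1)]
    one_sided[2:half] <- 2 * one_sided[2:half]
    out[i, ] <- one_sided[k_keep + 1]
  }
  colnames(out) <- format(k_keep * df, trim = TRUE)
  attr(out, "freq") <- k_keep * df
  attr(out, "artifact") <- bad
  out
}

#' Slow-wave activity from epoch spectra
#'
#' Sums spectral power over the slow-wave band, both endpoints included
#' (0.5 and 4.0 Hz, i.e. 15 bins at 0.25 Hz resolution).
#'
#' @param spectra matrix from [epoch_band_power()] (needs its `freq`
#'   attribute).
#' @param band numeric length-2, band edges in Hz; must lie on the bin grid.
#' @return numeric vector, one SWA value per epoch (`NA` for flagged
#'   epochs).
#' @export
swa_from_spectra <- function(spectra, band = c(0.5, 4)) {
  freq <- attr(spectra, "freq")
  if (is.null(freq)) stop("spectra must carry a 'freq' attribute")
  if (!all(band %in% freq))
    stop("band edges must lie on the frequency bin grid")
  sel <- freq >= band[1] & freq <= band[2]
  rowSums(spectra[, sel, drop = FALSE])
}

#' Normalise SWA to its baseline NREM mean
#'
#' Rescales every SWA column so that its mean over non-artifact NREM
#' epochs inside the baseline window equals 100. This is the unit in
#' which all model levels (`SWA_L`, `S_0`, `S_U`, ...) are expressed.
#'
#' @param x an `epoch_series` with SWA.
#' @param baseline_window 0-based half-open `[from, to)` interval;
#'   default the whole recording.
#' @return the rescaled `epoch_series`, with attribute `renorm` giving the
#'   per-derivation factor applied.
#' @export
normalize_swa <- function(x, baseline_window = NULL) {
  if (is.null(x$swa)) stop("series has no SWA")
  if (is.null(baseline_window)) baseline_window <- c(0L, n_ts(x))
  idx <- (baseline_window[1] + 1L):baseline_window[2]
  usable <- idx[x$state[idx] == "N" & !x$artifact[idx]]
  fac <- numeric(ncol(x$swa))
  for (j in seq_len(ncol(x$swa))) {
    m <- mean(x$swa[usable, j])
    if (!length(usable) || !is.finite(m) || m <= 0)
      stop("no usable baseline NREM epoch for derivation '",
           derivations(x)[j], "'")
    fac[j] <- 100 / m
    x$swa[, j] <- x$swa[, j] * fac[j]
  }
  names(fac) <- derivations(x)
  attr(x, "renorm") <- fac
  x
}
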