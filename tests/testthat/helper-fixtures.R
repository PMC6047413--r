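# shared fixture builders: everything is generated in code, no files

# epoch series from a compact state spec, e.g. st("N", 20, "W", 4, "N", 10)
st <- function(...) {
  args <- list(...)
  unlist(lapply(seq(1, length(args), by = 2), function(i)
    rep(args[[i]], args[[i + 1]])))
}

make_series <- function(states, swa = NULL, artifact = NULL, phase = NULL) {
  if (is.null(swa)) swa <- rep(100, length(states))
  epoch_series(states, swa = matrix(swa, ncol = 1,
                                    dimnames = list(NULL, "fro")),
               artifact = artifact, phase = phase)
}

random_hypnogram <- function(n, prob = c(0.35, 0.4, 0.1, 0.15)) {
  # uniform-ish draws; BA runs are clipped to the 5-epoch scoring rule
  s <- sample(c("W", "N", "R", "BA"), n, replace = TRUE, prob = prob)
  r <- rle(s)
  long_ba <- r$values == "BA" & r$lengths > 5
  r$values[long_ba] <- "W"
  inverse.rle(r)
}

# independent brute-force episode finder: maximal regex matches of
# N-runs joined by gaps of 1..max_gap non-N epochs
regex_episodes <- function(states, min_len = 16, max_gap = 4) {
  chr <- c(W = "w", N = "N", R = "r", BA = "b")[states]
  s <- paste(chr, collapse = "")
  pat <- if (max_gap > 0)
    sprintf("N+(?:[^N]{1,%d}N+)*", max_gap) else "N+"
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), end = integer(0)))
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  keep <- (end - start) >= min_len
  data.frame(start = start[keep], end = end[keep])
}

# independent trigger oracle: epoch t is triggered iff some target-state
# epoch lies within [t - prolong, t + advance]
oracle_trigger <- function(states, target, advance, prolong) {
  z <- as.integer(states %in% target)
  n <- length(z)
  cs <- c(0L, cumsum(z))
  t <- seq_len(n)
  lo <- pmax(1L, t - prolong)
  hi <- pmin(n, t + advance)
  as.integer(cs[hi + 1L] - cs[lo] > 0L)
}

# explicit-Euler reference integrator (dt in ts), with per-epoch
# trapezoid averages like the RK4 core
euler_sim <- function(wt, remt, p, swa0, s0, dt = 0.001) {
  n <- length(wt)
  substeps <- round(1 / dt)
  swa <- swa0; s <- s0
  swa_out <- s_out <- swa_end <- s_end <- numeric(n)
  for (i in seq_len(n)) {
    w <- wt[i]; r <- remt[i]
    acc_swa <- 0.5 * swa; acc_s <- 0.5 * s
    for (j in seq_len(substeps)) {
      build <- p$rc * swa * (s - swa) / p$S_U * (1 - w) * (1 - r)
      dswa <- build - p$fc_R * (swa - p$SWA_L) * r -
        p$fc_W * (swa - p$SWA_L) * w
      ds <- -p$gc * swa + (p$S_U - s) * p$rs
      swa <- swa + dt * dswa
      s <- s + dt * ds
      wgt <- if (j == substeps) 0.5 else 1
      acc_swa <- acc_swa + wgt * swa
      acc_s <- acc_s + wgt * s
    }
    swa_out[i] <- acc_swa * dt
    s_out[i] <- acc_s * dt
    swa_end[i] <- swa
    s_end[i] <- s
  }
  list(swa_sim = swa_out, s_sim = s_out, swa_end = swa_end, s_end = s_end)
}

# direct DFT of a windowed epoch at one bin (independent of stats::fft)
naive_dft_power <- function(x, w, k) {
  n <- length(x)
  j <- 0:(n - 1)
  X <- sum(w * x * exp(-2i * pi * k * j / n))
  scale <- if (k == 0 || k == n / 2) 1 else 2
  scale * Mod(X)^2 / n
}
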