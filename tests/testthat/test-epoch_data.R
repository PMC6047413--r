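test_that("epoch table load/validate/round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  x <- make_series(st("N", 2, "W", 1, "R", 1), swa = c(1, 2.5, 3, 4))
  write_epoch_table(x, tmp)
  y <- read_epoch_table(tmp)
  expect_equal(n_ts(y), 4)
  expect_identical(y$state, x$state)
  expect_equal(y$swa, x$swa)

  # byte-wise round trip on a 100-ts fixture
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  set.seed(7)
  big <- make_series(random_hypnogram(100), swa = round(runif(100, 0, 300), 3))
  write_epoch_table(big, tmp2)
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  write_epoch_table(read_epoch_table(tmp2), tmp3)
  expect_identical(readBin(tmp2, "raw", file.size(tmp2)),
                   readBin(tmp3, "raw", file.size(tmp3)))
})

test_that("epoch table rejects malformed input with row numbers", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  x <- make_series(rep("N", 10))
  write_epoch_table(x, tmp)

  lines <- readLines(tmp)
  bad <- lines
  bad[8] <- sub("\tN\t", "\tX\t", bad[8])  # data row 7
  writeLines(bad, tmp)
  expect_error(read_epoch_table(tmp), "row 7")

  bad <- lines
  bad[5] <- sub("^3", "9", bad[5])
  writeLines(bad, tmp)
  expect_error(read_epoch_table(tmp), "contiguous")

  writeLines(sub("\tstate", "\tvigilance", lines), tmp)
  expect_error(read_epoch_table(tmp), "missing column")

  expect_error(epoch_series(rep("BA", 6)), "BA longer than 5")
  expect_error(epoch_series(c("N", "N"), swa = c(1, -2)), "row 2")
})

test_that("epoch band power matches a direct-DFT oracle", {
  n <- 1024
  expect_equal(unname(epoch_band_power(rep(0, n))[1, ]), rep(0, 81))

  # unit 2 Hz sine: power concentrated at the 2 Hz bin
  x <- sin(2 * pi * 2 * (0:(n - 1)) / 256)
  p <- epoch_band_power(x)
  freq <- attr(p, "freq")
  expect_equal(freq, seq(0, 20, by = 0.25))
  expect_length(freq, 81)
  k2 <- which(freq == 2)
  # a Hann-windowed pure tone leaks only into the two adjacent bins
  expect_gt(sum(p[1, (k2 - 1):(k2 + 1)]), 0.999 * sum(p[1, ]))
  expect_gt(p[1, k2], 0.5 * sum(p[1, ]))
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  expect_equal(unname(p[1, k2]), naive_dft_power(x, w, 8),
               tolerance = 1e-10)

  expect_error(epoch_band_power(rep(0, 512)), "1024 samples")
  flagged <- epoch_band_power(rbind(x, NaN * x))
  expect_identical(attr(flagged, "artifact"), c(FALSE, TRUE))
  expect_true(all(is.na(flagged[2, ])))
})

test_that("band power satisfies Parseval against windowed energy", {
  set.seed(42)
  n <- 1024
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  raw <- matrix(rnorm(100 * n), nrow = 100)
  full <- epoch_band_power(raw, max_freq = 128)
  for (i in 1:100) {
    expect_equal(sum(full[i, ]), sum((w * raw[i, ])^2),
                 tolerance = 1e-6)
  }
})

test_that("SWA sums the 0.5-4 Hz band inclusively", {
  p <- matrix(1, 2, 81)
  attr(p, "freq") <- seq(0, 20, by = 0.25)
  expect_equal(swa_from_spectra(p), c(15, 15))
  expect_equal(swa_from_spectra(0 * p), c(0, 0))
  p10 <- 0 * p
  p10[, which(attr(p, "freq") == 10)] <- 7
  attr(p10, "freq") <- attr(p, "freq")
  expect_equal(swa_from_spectra(p10), c(0, 0))
  expect_error(swa_from_spectra(p, band = c(0.6, 4)), "bin grid")
})

test_that("normalisation sets the baseline NREM mean to 100", {
  x <- make_series(rep("N", 8), swa = rep(5, 8))
  expect_equal(unname(normalize_swa(x)$swa[, 1]), rep(100, 8))

  y <- make_series(c("N", "N", "W"), swa = c(2, 4, 1000))
  ny <- normalize_swa(y)
  # NREM mean is 3, so the factor is 100/3; the wake epoch is scaled
  # too but never enters the denominator
  expect_equal(unname(ny$swa[, 1]), c(200 / 3, 400 / 3, 1e5 / 3))

  set.seed(1)
  for (i in 1:20) {
    states <- random_hypnogram(200)
    if (!any(states == "N")) next
    z <- make_series(states, swa = runif(200, 1, 50),
                     artifact = runif(200) < 0.1)
    usable <- z$state == "N" & !z$artifact
    if (!any(usable)) next
    nz <- normalize_swa(z)
    expect_equal(mean(nz$swa[usable, 1]), 100, tolerance = 1e-9)
  }

  expect_error(normalize_swa(make_series(rep("W", 5))), "baseline NREM")
})
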