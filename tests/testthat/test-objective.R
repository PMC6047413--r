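test_that("moving median smooths with clipped boundary windows", {
  expect_equal(smooth_moving_median(rep(7, 20), 5), rep(7, 20))
  expect_equal(smooth_moving_median(c(1, 100, 2, 3, 4), 3),
               c(50.5, 2, 3, 3, 3.5))
  expect_error(smooth_moving_median(1:10, 4), "odd")

  v <- c(1, 2, 1000, 3, 4)
  sm <- smooth_moving_median(v, 3, artifact = c(F, F, T, F, F))
  expect_true(is.na(sm[3]))
  expect_equal(sm[2], 1.5)  # median(1, 2); artifact value never enters
  expect_equal(sm[4], 3.5)
})

test_that("episode deviations pair empirical and simulated means", {
  x <- make_series(rep("N", 40), swa = rep(110, 40))
  ep <- detect_nrem_episodes(x)
  sim0 <- list(swa_sim = x$swa[, 1])
  expect_equal(episode_deviations(ep, x, sim0)$d, 0)

  sim1 <- list(swa_sim = rep(100, 40))
  expect_equal(episode_deviations(ep, x, sim1)$d, 10)

  # artifact epochs are excluded from both means symmetrically
  y <- make_series(rep("N", 40), swa = c(rep(110, 39), 1e6),
                   artifact = c(rep(FALSE, 39), TRUE))
  simv <- rep(100, 40); simv[40] <- -1e6
  d <- episode_deviations(detect_nrem_episodes(y), y,
                          list(swa_sim = simv))
  expect_equal(d$d, 10)
})

test_that("squared error balances light and dark phases", {
  devs <- data.frame(phase = c("L", "L", "D"), d = c(1, -1, 2))
  rep1 <- squared_error(devs)
  expect_equal(rep1$m_light, 1)
  expect_equal(rep1$m_dark, 4)
  expect_equal(rep1$err, 2.5)

  expect_equal(squared_error(data.frame(phase = c("L", "D"),
                                        d = c(0, 0)))$err, 0)

  # duplicating every episode leaves the mean of squares unchanged
  expect_equal(squared_error(rbind(devs, devs))$err, rep1$err)
  # permutation invariance
  expect_equal(squared_error(devs[c(3, 1, 2), ])$err, rep1$err)

  expect_warning(one <- squared_error(data.frame(phase = c("L", "L"),
                                                 d = c(3, 5))),
                 "no NREM episode")
  expect_equal(one$err, 17)
})

test_that("Err equals an independent recomputation on random fixtures", {
  set.seed(9)
  for (i in 1:20) {
    nl <- sample(1:30, 1); nd <- sample(1:30, 1)
    devs <- data.frame(phase = c(rep("L", nl), rep("D", nd)),
                       d = rnorm(nl + nd, sd = 10))
    got <- squared_error(devs)$err
    want <- (sum(devs$d[devs$phase == "L"]^2) / nl +
             sum(devs$d[devs$phase == "D"]^2) / nd) / 2
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("window errors carry sign convention sim minus emp", {
  x <- make_series(rep("N", 600), swa = rep(100, 600))
  up <- list(swa_sim = rep(105, 600))
  we <- window_errors(x, up, c(0, 600), bin = 150)
  expect_equal(nrow(we), 4)
  expect_equal(we$signed_error, rep(5, 4))
  expect_equal(we$abs_error, rep(5, 4))

  mix <- list(swa_sim = rep(c(105, 95), 300))
  wm <- window_errors(x, mix, c(0, 600), bin = NULL)
  expect_equal(wm$signed_error, 0)
  expect_equal(wm$abs_error, 5)

  # empty bins (no N epochs) give NA, not zero
  w <- make_series(rep("W", 300), swa = rep(20, 300))
  ww <- window_errors(w, list(swa_sim = rep(30, 300)), c(0, 300),
                      bin = NULL)
  expect_true(is.na(ww$signed_error))
  expect_true(is.na(ww$abs_error))

  # |signed| <= absolute for any window
  set.seed(2)
  z <- make_series(random_hypnogram(500), swa = runif(500, 50, 200))
  sims <- list(swa_sim = runif(500, 50, 200))
  wz <- window_errors(z, sims, c(0, 500), bin = 100)
  ok <- !is.na(wz$signed_error)
  expect_true(all(abs(wz$signed_error[ok]) <= wz$abs_error[ok] + 1e-12))
})
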