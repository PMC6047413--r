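test_that("the right-hand side matches hand arithmetic", {
  p <- model_params(S_U = 400, rc = 0.5)
  # fall term vanishes at the lower asymptote
  expect_equal(swa_rhs(20, 300, wt = 1, remt = 0, p)[["dswa"]], 0)
  # logistic ceiling: build term vanishes when SWA = S
  expect_equal(swa_rhs(250, 250, wt = 0, remt = 0, p)[["dswa"]], 0)
  # dSWA/dt = 0.5 * 100 * (300/400) * (1 - 100/300) = 25
  expect_equal(swa_rhs(100, 300, wt = 0, remt = 0, p)[["dswa"]], 25)
  # Process S fixed point with gc = 0 at S = S_U
  p0 <- model_params(gc = 0)
  expect_equal(swa_rhs(100, 400, wt = 0, remt = 0, p0)[["ds"]], 0)
  expect_error(swa_rhs(100, 0, 0, 0, p), "positive")
})

test_that("sustained wake drives exponential decay to SWA_L", {
  n <- 50
  p <- model_params(fc_W = 0.2, SWA_L = 20, SWA_0 = 120, S_0 = 300)
  trig <- list(wt = rep(1L, n), remt = rep(0L, n))
  sim <- simulate_swa(trig, p)
  tt <- seq_len(n)
  # instantaneous value at epoch boundaries
  expect_equal(sim$swa_end, 20 + 100 * exp(-0.2 * tt), tolerance = 1e-8)
  expect_equal(sim$swa_end[10], 20 + 100 * exp(-2), tolerance = 1e-8)
  # epoch averages against the analytically integrated mean; the output
  # is a trapezoid average of the dense solution, so quadrature error
  # ~ (fc/substeps)^2 / 12 bounds the agreement
  avg <- 20 + 100 / 0.2 * (exp(-0.2 * (tt - 1)) - exp(-0.2 * tt))
  expect_equal(sim$swa_sim, avg, tolerance = 1e-4)

  # equilibrium: starting at the asymptote stays there
  pe <- model_params(SWA_0 = 20, S_0 = 300)
  sime <- simulate_swa(list(wt = rep(1L, n), remt = rep(0L, n)), pe)
  expect_equal(sime$swa_sim, rep(20, n), tolerance = 1e-9)
})

test_that("gc = 0 relaxes Process S to S_U along the closed form", {
  n <- 2000
  p <- model_params(gc = 0, rs = 2e-4, S_U = 400, S_0 = 150, SWA_0 = 100)
  sim <- simulate_swa(list(wt = rep(1L, n), remt = rep(0L, n)), p)
  tt <- seq_len(n)
  expect_equal(sim$s_end, 400 - (400 - 150) * exp(-2e-4 * tt),
               tolerance = 1e-4)
})

test_that("frozen S yields the logistic closed form", {
  n <- 100
  p <- model_params(gc = 0, rs = 0, S_U = 400, S_0 = 300, SWA_0 = 50)
  sim <- simulate_swa(list(wt = rep(0L, n), remt = rep(0L, n)), p)
  r <- p$rc * p$S_0 / p$S_U
  tt <- seq_len(n)
  swa_exact <- p$S_0 / (1 + (p$S_0 - p$SWA_0) / p$SWA_0 * exp(-r * tt))
  expect_equal(sim$swa_end, swa_exact, tolerance = 1e-3)
})

test_that("RK4 output agrees with a fine explicit-Euler oracle", {
  set.seed(33)
  for (seed in 1:3) {
    states <- random_hypnogram(300)
    x <- make_series(states)
    p <- model_params(S_0 = 280, SWA_0 = 150)
    trig <- build_triggers(x, p)
    sim <- simulate_swa(trig, p)
    ref <- euler_sim(trig$wt, trig$remt, p, p$SWA_0, p$S_0, dt = 0.001)
    rms <- sqrt(mean((sim$swa_sim - ref$swa_sim)^2)) / mean(ref$swa_sim)
    expect_lt(rms, 0.005)
  }
})

test_that("simulated trajectories stay within physical bounds", {
  set.seed(44)
  for (i in 1:10) {
    x <- make_series(random_hypnogram(800))
    p <- model_params(S_0 = runif(1, 150, 380), SWA_0 = runif(1, 25, 300))
    trig <- build_triggers(x, p)
    sim <- simulate_swa(trig, p)
    expect_true(all(sim$swa_sim >= p$SWA_L - 1e-6))
    expect_true(all(sim$swa_sim <= max(p$SWA_0, p$S_U) + 1e-6))
    expect_true(all(sim$s_sim >= 0))
    expect_true(all(sim$s_sim <= max(p$S_0, p$S_U) + 1e-6))
    # sign agreement of Process S with its own derivative, skipping
    # epochs where dS/dt changes sign within the epoch
    ds_num <- diff(sim$s_end)
    rhs_at <- function(k) -p$gc * sim$swa_end[k] +
      (p$S_U - sim$s_end[k]) * p$rs
    f_start <- rhs_at(seq_len(length(ds_num)))
    f_end <- rhs_at(seq_len(length(ds_num)) + 1L)
    chk <- sign(f_start) == sign(f_end) & abs(ds_num) > 1e-6 &
      abs(f_end) > 1e-8
    expect_true(all(sign(ds_num[chk]) == sign(f_end[chk])))
  }
})

test_that("integration failures report the epoch", {
  # absurd rate blows the fixed-step scheme up deterministically
  p <- model_params(S_0 = 300, SWA_0 = 150)
  p$rc <- 1e6
  trig <- list(wt = rep(0L, 100), remt = rep(0L, 100))
  expect_error(simulate_swa(trig, p, substeps = 1), "epoch")
  expect_error(simulate_swa(trig, model_params(S_0 = 300)), "initial conditions")
})
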