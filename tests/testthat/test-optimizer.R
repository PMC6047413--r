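test_that("initial conditions follow the episode and first-epoch rules", {
  # 3 min threshold: 45 epochs; a 44-epoch run does not qualify
  states <- st("N", 44, "W", 10, "N", 50, "W", 6)
  swa <- c(rep(90, 44), rep(20, 10), rep(180, 50), rep(20, 6))
  x <- make_series(states, swa = swa)
  ic <- initial_conditions(x)
  expect_equal(ic[["S_0"]], 180)
  expect_equal(ic[["SWA_0"]], 90)

  # artifactual first epoch falls through to the next usable one
  y <- make_series(st("N", 50, "W", 5), swa = c(55, 90, rep(180, 48),
                                                rep(20, 5)),
                   artifact = c(TRUE, rep(FALSE, 54)))
  expect_equal(initial_conditions(y)[["SWA_0"]], 90)

  expect_error(initial_conditions(make_series(rep("W", 100))), "45 ts")
})

test_that("stage-1 grids hold the published starting values", {
  fro <- stage1_starts("frontal")
  expect_equal(nrow(fro), 9)
  expect_equal(sort(unique(fro$gc)), c(0.0005, 0.0010, 0.0020))
  expect_equal(sort(unique(fro$rs)), c(0.0001, 0.0002, 0.0004))
  expect_equal(unique(fro$s_u), 400)
  occ <- stage1_starts("occipital")
  expect_equal(sort(unique(occ$gc)), c(0.0002, 0.0004, 0.0008))
  expect_equal(unique(occ$s_u), 450)
})

test_that("stage-2 starts offset the winner and clamp at the floor", {
  g <- stage2_starts(list(gc = 0.0010, rs = 0.0002, s_u = 420))
  expect_equal(sort(unique(g$gc)), c(0.0008, 0.0010, 0.0012))
  expect_equal(sort(unique(g$rs)), c(0.00018, 0.0002, 0.00022))
  expect_equal(unique(g$s_u), 420)
  low <- stage2_starts(list(gc = 0.0001, rs = 0.00001, s_u = 400))
  expect_true(all(low$gc > 0))
  expect_true(all(low$rs > 0))
  expect_equal(min(low$gc), 1e-6)
})

test_that("fit windows follow the protocol conventions", {
  n <- 21600
  set.seed(3)
  day <- random_hypnogram(n)
  swa <- runif(n, 10, 50)
  x3 <- make_series(rep(day, 3), swa = rep(swa, 3))

  rw <- prepare_fit_window(x3, "RW")
  expect_equal(n_ts(rw$fit), 43200)
  expect_equal(rw$prediction_window, c(0L, 43200L))

  cw <- prepare_fit_window(x3, "CW")
  expect_equal(n_ts(cw$fit), 43200)
  expect_equal(cw$prediction_window, c(21600L, 64800L))

  x1 <- make_series(day, swa = swa)
  ew <- prepare_fit_window(x1, "EW")
  expect_equal(n_ts(ew$fit), 43200)
  first <- series_window(ew$fit, 0, 21600)
  second <- series_window(ew$fit, 21600, 43200)
  expect_identical(first$state, second$state)
  expect_equal(first$swa, second$swa)
  # duplicated baseline normalises to 100 over its first day
  usable <- first$state == "N" & !first$artifact
  expect_equal(mean(first$swa[usable, 1]), 100, tolerance = 1e-9)

  expect_error(prepare_fit_window(x1, "RW"), "48 h")
  expect_error(prepare_fit_window(x3, "EW"), NA)
  expect_error(prepare_fit_window(x1, "CW"), "72 h")
})

# one small noise-free dataset shared by the search tests
fit_world <- local({
  cfg <- generator_config(n_days = 1, seed = 42, sigma = 0,
                          sigma_off = 0, artifact_rate = 0)
  make_dataset(cfg)
})

test_that("each simplex start descends on noise-free data", {
  obj <- make_objective(fit_world$series)
  starts <- stage1_starts("frontal")[c(1, 5, 9), ]
  res <- run_stage(starts, obj)
  for (i in seq_len(nrow(res))) {
    f0 <- obj(c(res$start_gc[i], res$start_rs[i], res$start_s_u[i]))
    expect_lte(res$err[i], f0)
  }
  # invalid candidates score +Inf rather than erroring
  expect_identical(obj(c(-1e-3, 2e-4, 400)), Inf)
  expect_identical(obj(c(1e-3, 2e-4, 10)), Inf)
})

test_that("the stage runner is deterministic", {
  obj <- make_objective(fit_world$series)
  s <- stage1_starts("frontal")[5, ]
  r1 <- run_stage(s, obj)
  r2 <- run_stage(s, obj)
  expect_identical(r1, r2)
})
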