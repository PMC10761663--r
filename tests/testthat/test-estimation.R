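test_that("noiseless AIF samples are recovered to machine-level accuracy", {
  tac <- sample_aif(mean_feng, proto$injections, proto$schedule)
  win <- tac[cardiac_idx, ]
  # init at truth
  fit1 <- fit_aif(win, proto$injections, init = mean_feng)
  expect_true(fit1$converged)
  expect_lt(max(abs(unclass(fit1$estimate) - unclass(mean_feng)) /
                  unclass(mean_feng)), 1e-6)
  # init at the bound midpoint (the default)
  fit2 <- fit_aif(win, proto$injections)
  expect_lt(max(abs(unclass(fit2$estimate) - unclass(mean_feng)) /
                  unclass(mean_feng)), 1e-6)
  expect_error(fit_aif(win[1:3, ], proto$injections), "at least 4")
})

test_that("AIF fit beats a coarse 4-D grid search on noisy samples", {
  tac <- sample_aif(mean_feng, proto$injections, proto$schedule)
  bounds <- default_aif_bounds()
  d <- petwin:::.aif_design(proto$schedule[cardiac_idx, ], proto$injections)
  axes <- lapply(seq_along(bounds$lower), function(i)
    seq(bounds$lower[i], bounds$upper[i], length.out = 11))
  grid <- as.matrix(expand.grid(axes))
  set.seed(31)
  for (r in 1:5) {
    noisy <- add_frame_noise(tac, noise_config(0.15, 310 + r))
    y <- noisy$activity[cardiac_idx]
    fit <- fit_aif(noisy[cardiac_idx, ], proto$injections)
    rss_grid <- min(apply(grid, 1, function(q)
      sum((petwin:::.aif_model(q, d) - y)^2)))
    expect_gte(rss_grid, fit$residual_ss - 1e-9)
  }
})

test_that("noiseless 2TCM fit recovers the generating parameters", {
  tac <- tac_2tcm(sim_tcm, mean_feng, proto$injections, proto$schedule)
  fit <- fit_2tcm(tac[short_idx, ], mean_feng, proto$injections)
  expect_true(fit$converged)
  est <- unclass(fit$estimate)[1:3]
  truth <- unclass(sim_tcm)[1:3]
  expect_lt(max(abs(est - truth) / truth), 1e-4)
  expect_equal(fit$Ki, 0.0125, tolerance = 1e-4)
  expect_error(fit_2tcm(tac[1:2, ], mean_feng, proto$injections),
               "at least 3")
})

test_that("2TCM fit beats a coarse 3-D grid search on noisy samples", {
  tac <- tac_2tcm(sim_tcm, mean_feng, proto$injections, proto$schedule)
  bounds <- default_tcm_bounds()
  d <- petwin:::.tcm_design(proto$schedule[short_idx, ], mean_feng,
                            proto$injections, 0.03)
  axes <- lapply(seq_along(bounds$lower), function(i)
    seq(bounds$lower[i], bounds$upper[i], length.out = 11))
  grid <- as.matrix(expand.grid(axes))
  set.seed(77)
  for (r in 1:5) {
    y <- petwin:::.add_frame_noise_stream(
      tac$activity[short_idx], proto$schedule$frame_duration[short_idx],
      0.4, 60)
    fit <- petwin:::.fit_2tcm_core(y, d)
    rss_grid <- min(apply(grid, 1, function(q)
      sum((petwin:::.tcm_model(q, d) - y)^2)))
    expect_gte(rss_grid, fit$residual_ss - 1e-9)
  }
})

test_that("fits never end above the residual at the initialization", {
  tac <- tac_2tcm(sim_tcm, mean_feng, proto$injections, proto$schedule)
  d <- petwin:::.tcm_design(proto$schedule[short_idx, ], mean_feng,
                            proto$injections, 0.03)
  init <- c(K1 = 0.1, k2 = 0.1, k3 = 0.05)
  set.seed(5)
  for (r in 1:5) {
    y <- petwin:::.add_frame_noise_stream(
      tac$activity[short_idx], proto$schedule$frame_duration[short_idx],
      0.4, 60)
    fit <- petwin:::.fit_2tcm_core(y, d, init = init)
    rss_init <- sum((petwin:::.tcm_model(unname(init), d) - y)^2)
    expect_lte(fit$residual_ss, rss_init + 1e-12)
  }
})

test_that("patlak fit recovers exact lines and flat curves", {
  sched <- frame_schedule(seq(0, 35, by = 1), rep(1, 36))
  plasma <- dplyr::mutate(sched, activity = 10 * exp(-0.02 *
                                                       frame_midtimes(sched)))
  x <- patlak_transform(plasma, plasma)$x
  tissue <- dplyr::mutate(plasma, activity = (0.02 * x + 0.5) * activity)
  fit <- fit_patlak(tissue, plasma, t_start = 5)
  expect_equal(fit$Ki, 0.02, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-10)
  # constant tissue and plasma: zero slope
  flat_p <- dplyr::mutate(sched, activity = 5)
  flat_t <- dplyr::mutate(sched, activity = 5)
  expect_equal(fit_patlak(flat_t, flat_p, t_start = 5)$Ki, 0,
               tolerance = 1e-12)
  expect_error(fit_patlak(tissue, plasma, t_start = 40), "at least 2")
})

test_that("patlak Ki of a 2TCM curve is within 10% of the 2TCM Ki", {
  val_idx <- select_window(proto$schedule, c(0, 36))
  sched <- proto$schedule[val_idx, ]
  plasma <- sample_aif(mean_feng, single_inj, sched)
  tissue <- tac_2tcm(sim_tcm, mean_feng, single_inj, sched)
  fit <- fit_patlak(tissue, plasma, t_start = 15)
  expect_equal(fit$Ki, 0.0125, tolerance = 0.1)
})

test_that("bounds constructors behave as documented", {
  b <- default_aif_bounds()
  expect_equal(unname(b$lower["A1"]), 0.5 * (263 - 120))
  expect_equal(unname(b$upper["A1"]), 2 * (263 + 120))
  bh <- default_aif_bounds("human")
  expect_equal(unname(c(bh$lower["A1"], bh$upper["A1"])), c(300, 800))
  bt <- default_tcm_bounds()
  expect_equal(unname(bt$lower), c(0.025, 0.025, 0.01))
  expect_equal(unname(bt$upper), c(0.2, 0.5, 0.08))
  expect_error(param_bounds(c(1, 2), c(2, 1)))
})
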