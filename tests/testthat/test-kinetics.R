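test_that("impulse response has the right limits and values", {
  p <- sim_tcm
  expect_equal(impulse_response(p, 0), 0.075)
  expect_equal(impulse_response(p, 1e6), net_influx_rate(p),
               tolerance = 1e-12)
  # frozen scalar evaluation at t = 10 min
  expect_equal(impulse_response(p, 10), 0.02283118, tolerance = 1e-7)
  # degenerate k2 + k3 = 0: analytic limit is the constant K1
  p0 <- tcm_params(0.1, 0, 0)
  expect_equal(impulse_response(p0, c(0, 5, 50)), rep(0.1, 3))
})

test_that("net influx rate follows Ki = K1 k3 / (k2 + k3)", {
  expect_equal(net_influx_rate(sim_tcm), 0.0125)
  expect_equal(net_influx_rate(tcm_params(0.075, 0.15, 0)), 0)
  expect_equal(net_influx_rate(tcm_params(0.075, 0, 0.03)), 0.075)
  expect_error(net_influx_rate(tcm_params(0.075, 0, 0)), "undefined")
})

test_that("2TCM forward model has the right degenerate limits", {
  sched <- proto$schedule
  cp <- sample_aif(mean_feng, proto$injections, sched)
  # K1 = 0: pure vascular signal
  # (sample_aif integrates exactly; tac_2tcm uses sub-frame Simpson, so
  # agreement is to quadrature accuracy)
  t0 <- tac_2tcm(tcm_params(0, 0, 0, 0.03), mean_feng, proto$injections, sched)
  expect_equal(t0$activity, 0.03 * cp$activity, tolerance = 1e-4)
  # vb = 0, k2 = k3 = 0: irreversible uptake limit K1 * int Cp
  t1 <- tac_2tcm(tcm_params(0.05, 0, 0, 0), mean_feng, proto$injections, sched)
  ends <- sched$frame_start + sched$frame_duration
  int_avg <- (multi_injection_aif_integral(mean_feng, proto$injections, ends) -
                multi_injection_aif_integral(mean_feng, proto$injections,
                                             sched$frame_start))
  # frame average of K1 * int Cp: compare against Simpson-free trapezoid of
  # the exact running integral at frame endpoints
  fine <- seq(0, 60, by = 0.005)
  ivals <- multi_injection_aif_integral(mean_feng, proto$injections, fine)
  favg <- sapply(seq_len(nrow(sched)), function(i) {
    sel <- fine >= sched$frame_start[i] & fine <= ends[i]
    mean(ivals[sel])
  })
  expect_equal(t1$activity, 0.05 * favg, tolerance = 1e-3)
})

test_that("convolution forward model agrees with an ODE-solver oracle", {
  skip_if_not_installed("deSolve")
  sched <- proto$schedule
  mids <- frame_midtimes(sched)
  p <- sim_tcm
  cpfun <- function(t) multi_injection_aif(mean_feng, proto$injections, t)
  deriv <- function(t, y, parms)
    list(c(p[["K1"]] * cpfun(t) - (p[["k2"]] + p[["k3"]]) * y[1],
           p[["k3"]] * y[1]))
  sol <- deSolve::ode(c(0, 0), c(0, mids), deriv, NULL,
                      rtol = 1e-10, atol = 1e-10)
  ct_ode <- (1 - 0.03) * (sol[-1, 2] + sol[-1, 3]) + 0.03 * cpfun(mids)
  ct_cf <- petwin:::.ct_values(p, mean_feng, proto$injections, mids)
  expect_lt(max(abs(ct_cf - ct_ode) / ct_ode), 5e-3)
})

test_that("forward model is linear in the input and monotone in K1", {
  sched <- proto$schedule[seq(1, 50, by = 4), ]
  base <- tac_2tcm(sim_tcm, mean_feng, proto$injections, sched)
  # doubling the input amplitudes doubles the tissue curve
  dbl <- feng_params(2 * 263, 2 * 16, 3.56, 0.029)
  expect_equal(tac_2tcm(sim_tcm, dbl, proto$injections, sched)$activity,
               2 * base$activity, tolerance = 1e-12)
  # monotone in K1, and nonnegative
  hi <- tac_2tcm(tcm_params(0.09, 0.15, 0.03), mean_feng, proto$injections,
                 sched)
  expect_true(all(hi$activity > base$activity))
  expect_true(all(base$activity >= 0))
})

test_that("patlak transform is exact on algebraically linear data", {
  sched <- proto$schedule[select_window(proto$schedule, c(0, 36)), ]
  plasma <- sample_aif(mean_feng, single_inj, sched)
  # construct tissue to satisfy C_T = Ki * int Cp + V * Cp under the
  # transform's own integral convention
  pts0 <- patlak_transform(plasma, plasma)    # x from the plasma curve
  Ki <- 0.0125; V <- 0.6
  tissue <- dplyr::mutate(plasma,
                          activity = Ki * pts0$x * plasma$activity +
                            V * plasma$activity)
  pts <- patlak_transform(tissue, plasma)
  fit <- lm(y ~ x, data = pts)
  expect_equal(unname(coef(fit)), c(V, Ki), tolerance = 1e-10)
  # identical curves give y = 1 everywhere
  expect_equal(pts0$y, rep(1, nrow(pts0)))
})

test_that("patlak slope of a 2TCM curve approaches Ki at late times", {
  sched <- proto$schedule
  plasma <- sample_aif(mean_feng, single_inj, sched)
  tissue <- tac_2tcm(sim_tcm, mean_feng, single_inj, sched)
  pts <- patlak_transform(tissue, plasma)
  late <- pts[pts$time >= 30, ]
  slope <- coef(lm(y ~ x, data = late))[["x"]]
  expect_equal(slope, 0.0125, tolerance = 0.05)
})

test_that("patlak transform drops nonpositive plasma frames with warning", {
  sched <- frame_schedule(0:3, rep(1, 4))
  plasma <- dplyr::mutate(sched, activity = c(1, 0, 2, 3))
  tissue <- dplyr::mutate(sched, activity = rep(1, 4))
  expect_warning(pts <- patlak_transform(tissue, plasma), "nonpositive")
  expect_equal(nrow(pts), 3L)
})
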