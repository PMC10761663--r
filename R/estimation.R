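#' Parameter bounds for bounded least-squares fits
#'
#' @param lower,upper Named numeric vectors, `lower < upper` elementwise.
#' @return A list of class `param_bounds`.
#' @export
param_bounds <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == length(upper), all(lower < upper))
  structure(list(lower = lower, upper = upper), class = "param_bounds")
}

#' Default bounds for the Feng AIF fit
#'
#' The simulation-study convention: 0.5 x the smallest and 2 x the largest
#' value of each parameter across the mean +- SD design grid. The
#' human-style alternative constrains A1 to 300-800 kBq/ml.
#'
#' @param style `"simulation"` (default) or `"human"`.
#' @return A [param_bounds()] over (A1, A2, mu1, mu2).
#' @export
default_aif_bounds <- function(style = c("simulation", "human")) {
  style <- match.arg(style)
  ref <- feng_reference()
  lo <- 0.5 * (unclass(ref$mean) - ref$sd)
  hi <- 2 * (unclass(ref$mean) + ref$sd)
  if (style == "human") {
    lo[["A1"]] <- 300
    hi[["A1"]] <- 800
  }
  param_bounds(lo, hi)
}

#' Default bounds for the 2TCM fit
#'
#' Same construction rule as [default_aif_bounds()] applied to the
#' simulation grid K1 in \{0.05, 0.075, 0.1\}, k2 in \{0.05, 0.15, 0.25\},
#' k3 in \{0.02, 0.03, 0.04\}.
#'
#' @return A [param_bounds()] over (K1, k2, k3).
#' @export
default_tcm_bounds <- function() {
  param_bounds(0.5 * c(K1 = 0.05, k2 = 0.05, k3 = 0.02),
               2 * c(K1 = 0.1, k2 = 0.25, k3 = 0.04))
}

.fit_control <- function() {
  minpack.lm::nls.lm.control(maxiter = 500L, ftol = 1e-8, ptol = 1e-8)
}

.new_fit <- function(class, estimate, lm_fit, extra = list()) {
  structure(c(list(
    estimate = estimate,
    residual_ss = sum(lm_fit$fvec^2),
    converged = lm_fit$info %in% 1:4,
    n_iter = lm_fit$niter
  ), extra), class = c(class, "petwin_fit"))
}

# Analytic derivatives of the frame-averaged Feng model with respect to
# (A1, A2, mu1, mu2); the model is linear in A1, A2 and the mu derivatives
# follow from differentiating the antiderivative.
.feng_F_basis <- function(mu, t) {
  t <- pmax(t, 0)
  (1 - exp(-mu * t) * (1 + mu * t)) / mu^2       # int_0^t s e^{-mu s} ds
}
.feng_F_exp <- function(mu, t) {
  t <- pmax(t, 0)
  (1 - exp(-mu * t)) / mu                        # int_0^t e^{-mu s} ds
}
.dF_basis_dmu <- function(mu, t) {
  t <- pmax(t, 0)
  t^2 * exp(-mu * t) / mu - 2 * .feng_F_basis(mu, t) / mu
}
.dF_exp_dmu <- function(mu, t) {
  t <- pmax(t, 0)
  t * exp(-mu * t) / mu - .feng_F_exp(mu, t) / mu
}

# Frame-averaged model and Jacobian for a window of frames under an impulse
# train: shifted start/end times are precomputed once.
.aif_design <- function(schedule, injections) {
  s <- outer(schedule$frame_start, injections$injection_time, `-`)
  e <- outer(schedule$frame_start + schedule$frame_duration,
             injections$injection_time, `-`)
  list(s = s, e = e, w = injections$dose_fraction,
       dur = schedule$frame_duration)
}
.aif_model <- function(q, d) {
  acc <- 0
  for (j in seq_along(d$w)) {
    acc <- acc + d$w[j] *
      (q[1] * (.feng_F_basis(q[3], d$e[, j]) - .feng_F_basis(q[3], d$s[, j])) +
       q[2] * (.feng_F_exp(q[4], d$e[, j]) - .feng_F_exp(q[4], d$s[, j])) -
       q[2] * (.feng_F_exp(q[3], d$e[, j]) - .feng_F_exp(q[3], d$s[, j])))
  }
  acc / d$dur
}
.aif_jacobian <- function(q, d) {
  g <- matrix(0, nrow(d$s), 4L)
  for (j in seq_along(d$w)) {
    dB <- .feng_F_basis(q[3], d$e[, j]) - .feng_F_basis(q[3], d$s[, j])
    dE2 <- .feng_F_exp(q[4], d$e[, j]) - .feng_F_exp(q[4], d$s[, j])
    dE1 <- .feng_F_exp(q[3], d$e[, j]) - .feng_F_exp(q[3], d$s[, j])
    g[, 1] <- g[, 1] + d$w[j] * dB
    g[, 2] <- g[, 2] + d$w[j] * (dE2 - dE1)
    g[, 3] <- g[, 3] + d$w[j] *
      (q[1] * (.dF_basis_dmu(q[3], d$e[, j]) - .dF_basis_dmu(q[3], d$s[, j])) -
       q[2] * (.dF_exp_dmu(q[3], d$e[, j]) - .dF_exp_dmu(q[3], d$s[, j])))
    g[, 4] <- g[, 4] + d$w[j] *
      q[2] * (.dF_exp_dmu(q[4], d$e[, j]) - .dF_exp_dmu(q[4], d$s[, j]))
  }
  g / d$dur
}

#' Fit the Feng multi-injection input function to windowed samples
#'
#' Bounded trust-region Levenberg-Marquardt least squares (via
#' \pkg{minpack.lm}) of the frame-averaged multi-injection Feng model to the
#' frames of `samples`. The recovered parameters define the input function
#' over the whole acquisition through [multi_injection_aif()].
#'
#' @param samples A time-activity curve tibble, typically restricted to the
#'   cardiac window frames; must contain at least 4 frames.
#' @param injections An [injection_schedule()] tibble.
#' @param bounds A [param_bounds()] over (A1, A2, mu1, mu2); default
#'   [default_aif_bounds()].
#' @param init Initial [feng_params()]; default midpoint of the bounds.
#' @return An object of class `aif_fit` with elements `estimate`
#'   ([feng_params()]), `residual_ss`, `converged`, `n_iter`.
#' @examples
#' p <- standard_protocol()
#' truth <- feng_params(263, 16, 3.56, 0.029)
#' tac <- sample_aif(truth, p$injections, p$schedule)
#' fit <- fit_aif(tac[select_window(p$schedule, c(39, 48)), ], p$injections)
#' @export
fit_aif <- function(samples, injections, bounds = default_aif_bounds(),
                    init = NULL) {
  validate_schedule(samples)
  validate_injections(injections)
  stopifnot(inherits(bounds, "param_bounds"), "activity" %in% names(samples))
  if (nrow(samples) < 4L)
    stop("at least 4 frames are needed to fit 4 Feng parameters", call. = FALSE)
  d <- .aif_design(samples, injections)
  out <- .fit_aif_core(samples$activity, d, bounds, init)
  out$injections <- injections
  out$n_frames <- nrow(samples)
  out
}

# Core AIF fit against a precomputed frame design; used by the study driver.
.fit_aif_core <- function(y, d, bounds = default_aif_bounds(), init = NULL) {
  start <- if (is.null(init)) (bounds$lower + bounds$upper) / 2
           else unclass(init)[c("A1", "A2", "mu1", "mu2")]
  fit <- minpack.lm::nls.lm(
    par = unname(start), lower = unname(bounds$lower),
    upper = unname(bounds$upper),
    fn = function(q) .aif_model(q, d) - y,
    jac = function(q) .aif_jacobian(q, d),
    control = .fit_control()
  )
  q <- stats::coef(fit)
  .new_fit("aif_fit", feng_params(q[1], q[2], q[3], q[4]), fit)
}

# Precomputation shared by all 2TCM fits against one input function: Simpson
# nodes for the fitted frames with plasma curve and integral evaluated once.
.tcm_design <- function(schedule, aif_params, injections, vb, nsub = 8L) {
  nodes <- .frame_nodes(schedule, nsub, breaks = injections$injection_time)
  list(nodes = nodes,
       cp = .cp(aif_params, injections, nodes$t),
       ip = .cp_int(aif_params, injections, nodes$t),
       aif_params = aif_params, injections = injections, vb = vb)
}
.tcm_model <- function(q, d) {
  b <- q[2] + q[3]
  conv <- if (b <= 0) q[1] * d$ip
          else (q[1] * q[2] / b) * .cp_econv(d$aif_params, d$injections,
                                             d$nodes$t, b) +
               (q[1] * q[3] / b) * d$ip
  .frame_average_nodes((1 - d$vb) * conv + d$vb * d$cp, d$nodes)
}

#' Fit the irreversible 2TCM to a windowed tissue curve
#'
#' Bounded Levenberg-Marquardt least squares of the frame-averaged 2TCM
#' (vascular fraction fixed) to the frames of `tac`, estimating
#' (K1, k2, k3). Ki is derived from the estimate via [net_influx_rate()].
#'
#' @param tac A time-activity curve tibble restricted to the fitting
#'   window(s); at least 3 frames.
#' @param aif_params A [feng_params()] input function (e.g. recovered by
#'   [fit_aif()]).
#' @param injections An [injection_schedule()] tibble.
#' @param vb Fixed plasma volume fraction (default 0.03).
#' @param bounds A [param_bounds()] over (K1, k2, k3); default
#'   [default_tcm_bounds()].
#' @param init Initial values; default `c(0.1, 0.1, 0.05)`.
#' @return An object of class `tcm_fit` with elements `estimate`
#'   ([tcm_params()]), `Ki`, `residual_ss`, `converged`, `n_iter`. `Ki` is
#'   `NA` (and the fit flagged unconverged) if `k2 + k3` collapses to 0.
#' @export
fit_2tcm <- function(tac, aif_params, injections, vb = 0.03,
                     bounds = default_tcm_bounds(),
                     init = c(K1 = 0.1, k2 = 0.1, k3 = 0.05)) {
  validate_schedule(tac)
  stopifnot(inherits(aif_params, "feng_params"), "activity" %in% names(tac))
  if (nrow(tac) < 3L)
    stop("at least 3 frames are needed to fit (K1, k2, k3)", call. = FALSE)
  d <- .tcm_design(tac, aif_params, injections, vb)
  .fit_2tcm_core(tac$activity, d, bounds, init)
}

# Core fit against a precomputed design; used by fit_2tcm, the study
# drivers, and voxel-wise mapping.
.fit_2tcm_core <- function(y, d, bounds = default_tcm_bounds(),
                           init = c(K1 = 0.1, k2 = 0.1, k3 = 0.05)) {
  fit <- minpack.lm::nls.lm(
    par = unname(init), lower = unname(bounds$lower),
    upper = unname(bounds$upper),
    fn = function(q) .tcm_model(q, d) - y,
    control = .fit_control()
  )
  q <- stats::coef(fit)
  est <- tcm_params(q[1], q[2], q[3], d$vb)
  ki <- if (q[2] + q[3] > 0) net_influx_rate(est) else NA_real_
  out <- .new_fit("tcm_fit", est, fit, list(Ki = ki))
  if (is.na(ki)) out$converged <- FALSE
  out
}

#' Patlak graphical estimate of the net influx rate
#'
#' Ordinary linear least squares on the [patlak_transform()] points with
#' frame midtime at or after `t_start` (and before `t_end`); the slope is
#' Ki, the intercept the effective distribution volume.
#'
#' @param tissue,plasma Time-activity curve tibbles sharing a schedule.
#' @param t_start Start of the linear (pseudo-equilibrium) segment in
#'   minutes (default 15).
#' @param t_end Optional end of the segment (default `Inf`).
#' @return An object of class `patlak_fit` with elements `Ki`, `intercept`,
#'   `n_points`, `r_squared`, and the fitted `points` tibble.
#' @export
fit_patlak <- function(tissue, plasma, t_start = 15, t_end = Inf) {
  pts <- patlak_transform(tissue, plasma)
  pts <- pts[pts$time >= t_start & pts$time < t_end, ]
  if (nrow(pts) < 2L)
    stop("at least 2 Patlak points at or after t_start are required",
         call. = FALSE)
  fit <- stats::lm(y ~ x, data = pts)
  ss_tot <- sum((pts$y - mean(pts$y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(
    Ki = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n_points = nrow(pts),
    r_squared = r2,
    points = pts
  ), class = c("patlak_fit", "petwin_fit"))
}

#' @export
print.petwin_fit <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  if (!is.null(x$estimate)) {
    cat("estimate:\n"); print(unclass(x$estimate))
  }
  if (!is.null(x$Ki)) cat("Ki:", format(x$Ki), "ml/g/min\n")
  if (!is.null(x$residual_ss))
    cat("residual_ss:", format(x$residual_ss),
        " converged:", x$converged, "\n")
  invisible(x)
}
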