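#' Area-under-curve percentage error over noise repetitions
#'
#' For each repetition the signed percentage error between the estimated
#' curve's AUC and the noiseless truth AUC is computed (trapezoid on the
#' shared evaluation grid); the mean over repetitions is returned. With
#' `absolute = TRUE` the per-repetition errors enter as absolute values,
#' the convention used for Table-1-style study summaries.
#'
#' @param estimated Numeric vector (one curve) or matrix with one row per
#'   repetition and one column per grid point.
#' @param truth Numeric vector of the noiseless curve on the same grid.
#' @param times Numeric vector of grid times (min).
#' @param absolute Average `|error|` instead of signed error.
#' @return Percentage error (scalar).
#' @examples
#' t <- 0:10
#' auc_error(rbind(1.1 * exp(-t / 5)), exp(-t / 5), t) # +10
#' @export
auc_error <- function(estimated, truth, times, absolute = FALSE) {
  if (is.vector(estimated)) estimated <- matrix(estimated, nrow = 1L)
  stopifnot(ncol(estimated) == length(truth), length(times) == length(truth))
  auc <- function(y) sum(diff(times) * (y[-1] + y[-length(y)]) / 2)
  auc_hat <- auc(truth)
  if (auc_hat <= 0) stop("truth AUC must be positive", call. = FALSE)
  errs <- 100 * (apply(estimated, 1L, auc) - auc_hat) / auc_hat
  if (absolute) mean(abs(errs)) else mean(errs)
}

#' Normalized root-mean-square error over noise repetitions
#'
#' Per repetition, the root of the mean squared relative error across grid
#' points \eqn{\sqrt{\frac1n \sum_i (f_i - \hat f_i)^2 / \hat f_i^2}};
#' averaged over repetitions. Grid points where the truth is exactly zero
#' are excluded with a warning.
#'
#' @inheritParams auc_error
#' @return NRMSE (unitless scalar, >= 0).
#' @examples
#' nrmse(rbind(1.1 * (1:5)), 1:5) # 0.1
#' @export
nrmse <- function(estimated, truth) {
  if (is.vector(estimated)) estimated <- matrix(estimated, nrow = 1L)
  stopifnot(ncol(estimated) == length(truth))
  ok <- truth != 0
  if (!all(ok)) {
    warning(sum(!ok), " grid point(s) with zero truth excluded")
    estimated <- estimated[, ok, drop = FALSE]
    truth <- truth[ok]
  }
  rel2 <- sweep(estimated, 2L, truth)^2 / rep(truth^2, each = nrow(estimated))
  mean(sqrt(rowMeans(rel2)))
}

#' Relative error, coefficient of variation, Pearson correlation
#'
#' `relative_error()` returns `100 * (estimate - truth) / truth`;
#' `cv_pct()` returns `100 * sd / mean`; `pearson_r()` is the standard
#' product-moment correlation.
#'
#' @param estimate,truth Numeric; `truth` must be nonzero.
#' @return Percent (scalar or vector following the inputs).
#' @examples
#' relative_error(0.0275, 0.025) # 10
#' @export
relative_error <- function(estimate, truth) {
  if (any(truth == 0)) stop("truth must be nonzero", call. = FALSE)
  100 * (estimate - truth) / truth
}

#' @rdname relative_error
#' @param estimates Numeric vector of repeated estimates.
#' @export
cv_pct <- function(estimates) {
  m <- mean(estimates)
  if (m == 0) stop("mean of estimates is zero; CV undefined", call. = FALSE)
  100 * stats::sd(estimates) / m
}

#' @rdname relative_error
#' @param x,y Numeric vectors of equal length (>= 2).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  stats::cor(x, y)
}
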