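#' Feng input-function parameters
#'
#' The third-order Feng model describes the arterial plasma concentration
#' after a bolus as \eqn{A_1 t e^{-\mu_1 t} + A_2 (e^{-\mu_2 t} -
#' e^{-\mu_1 t})}: a ramp-times-exponential first-pass peak with washout rate
#' \eqn{\mu_1} plus a slowly clearing tail with rate \eqn{\mu_2}.
#'
#' @param A1,A2 Amplitudes (kBq/ml), positive.
#' @param mu1 Fast washout rate (1/min); must exceed `mu2`.
#' @param mu2 Slow clearance rate (1/min), positive.
#' @return A named numeric vector of class `feng_params`.
#' @examples
#' feng_params(263, 16, 3.56, 0.029)
#' @export
feng_params <- function(A1, A2, mu1, mu2) {
  p <- c(A1 = as.numeric(A1), A2 = as.numeric(A2),
         mu1 = as.numeric(mu1), mu2 = as.numeric(mu2))
  if (any(!is.finite(p)) || any(p <= 0))
    stop("Feng parameters must be positive and finite", call. = FALSE)
  if (p[["mu1"]] <= p[["mu2"]])
    stop("mu1 (fast washout) must exceed mu2 (slow clearance)", call. = FALSE)
  structure(p, class = "feng_params")
}

#' Population mean and SD of the Feng parameters
#'
#' Reference FDG values used for the simulation designs: A1 = 263 +- 120 and
#' A2 = 16 +- 1.32 kBq/ml, mu1 = 3.56 +- 1.31 and mu2 = 0.029 +- 0.012 1/min.
#'
#' @return A list with elements `mean` (a [feng_params()]) and `sd`
#'   (named numeric).
#' @export
feng_reference <- function() {
  list(mean = feng_params(263, 16, 3.56, 0.029),
       sd = c(A1 = 120, A2 = 1.32, mu1 = 1.31, mu2 = 0.012))
}

#' Evaluate the single-injection Feng curve
#'
#' @param params A [feng_params()] object.
#' @param t Time(s) in minutes, `t >= 0`.
#' @return Plasma activity concentration (kBq/ml); 0 at `t = 0`.
#' @examples
#' feng_value(feng_params(263, 16, 3.56, 0.029), 1)
#' @export
feng_value <- function(params, t) {
  stopifnot(inherits(params, "feng_params"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  .feng_f(params, t)
}

#' Multi-injection model-based input function
#'
#' Closed-form convolution of the Feng curve with an impulse train: each
#' injection `j` contributes `dose_fraction[j] * feng_value(params, t - t_j)`
#' for `t >= t_j`.
#'
#' @inheritParams feng_value
#' @param injections An [injection_schedule()] tibble.
#' @return Plasma activity concentration (kBq/ml) at `t`.
#' @examples
#' p <- standard_protocol()
#' multi_injection_aif(feng_params(263, 16, 3.56, 0.029), p$injections, 50)
#' @export
multi_injection_aif <- function(params, injections, t) {
  stopifnot(inherits(params, "feng_params"))
  validate_injections(injections)
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  .cp(params, injections, t)
}

#' Running integral of the multi-injection input function
#'
#' Exact \eqn{\int_0^t C_p(\tau) d\tau} from the closed-form antiderivative
#' of the Feng model.
#'
#' @inheritParams multi_injection_aif
#' @return Integrated plasma activity (kBq min/ml).
#' @export
multi_injection_aif_integral <- function(params, injections, t) {
  stopifnot(inherits(params, "feng_params"))
  validate_injections(injections)
  .cp_int(params, injections, t)
}

#' Sample an input function on a frame schedule
#'
#' PET frames measure mean activity over the frame, so each frame value is
#' the exact frame average \eqn{\frac{1}{\Delta t}\int C_p}, computed from
#' the closed-form antiderivative of the Feng model.
#'
#' @inheritParams multi_injection_aif
#' @param schedule A [frame_schedule()] tibble.
#' @return A time-activity curve: the schedule tibble with an added
#'   `activity` column (kBq/ml).
#' @examples
#' p <- standard_protocol()
#' tac <- sample_aif(feng_params(263, 16, 3.56, 0.029), p$injections, p$schedule)
#' @export
sample_aif <- function(params, injections, schedule) {
  stopifnot(inherits(params, "feng_params"))
  validate_injections(injections)
  validate_schedule(schedule)
  ends <- schedule$frame_start + schedule$frame_duration
  act <- (.cp_int(params, injections, ends) -
            .cp_int(params, injections, schedule$frame_start)) /
    schedule$frame_duration
  dplyr::mutate(schedule, activity = act)
}

#' @export
print.feng_params <- function(x, ...) {
  cat("Feng input-function parameters:\n")
  print(unclass(x))
  invisible(x)
}
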