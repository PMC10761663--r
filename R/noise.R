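#' Frame-noise configuration
#'
#' Parameters of the frame-duration-scaled Gaussian noise model
#' \eqn{C^\eta = C + \eta \, c \, \sqrt{C / \Delta t}} with
#' \eqn{\eta \sim N(0, 1)} drawn independently per frame.
#'
#' @param c Nonnegative noise scaling factor (unitless).
#' @param seed Integer seed for the frame noise generator.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(c = 0, seed = 1L) {
  stopifnot(is.numeric(c), length(c) == 1L, c >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(c = c, seed = as.integer(seed)), class = "noise_config")
}

#' Add frame-duration-scaled Gaussian noise to a time-activity curve
#'
#' Per frame the noise standard deviation is `c * sqrt(C / dt)` where `C` is
#' the noiseless frame activity and `dt` the frame duration. With the default
#' `dt_unit = "min"` the duration enters in minutes; `dt_unit = "s"` uses
#' seconds, which lowers the noise SD by `sqrt(60)` at equal `c`. Negative
#' noisy values are retained (clipping would bias low-activity frames); the
#' input curve is returned unchanged when `c = 0`.
#'
#' @param curve A time-activity curve tibble with nonnegative `activity`.
#' @param config A [noise_config()].
#' @param dt_unit Unit in which the frame duration enters the noise SD,
#'   `"min"` (default) or `"s"`.
#' @return A new time-activity curve tibble; the input is not modified.
#' @examples
#' p <- standard_protocol()
#' tac <- sample_aif(feng_params(263, 16, 3.56, 0.029), p$injections, p$schedule)
#' noisy <- add_frame_noise(tac, noise_config(c = 0.15, seed = 7))
#' @export
add_frame_noise <- function(curve, config, dt_unit = c("min", "s")) {
  validate_schedule(curve)
  stopifnot(inherits(config, "noise_config"), "activity" %in% names(curve))
  dt_unit <- match.arg(dt_unit)
  if (any(curve$activity < 0))
    stop("input activities must be nonnegative", call. = FALSE)
  if (config$c == 0) return(curve)
  dt <- curve$frame_duration * if (dt_unit == "s") 60 else 1
  sd <- config$c * sqrt(curve$activity / dt)
  eta <- withr::with_seed(config$seed, stats::rnorm(nrow(curve)))
  dplyr::mutate(curve, activity = .data$activity + eta * sd)
}

# Internal variant drawing from the current RNG stream (no reseeding), for
# study drivers that manage their own per-cell substreams.
.add_frame_noise_stream <- function(activity, frame_duration, c, dt_scale = 1) {
  if (c == 0) return(activity)
  activity + stats::rnorm(length(activity)) *
    (c * sqrt(pmax(activity, 0) / (frame_duration * dt_scale)))
}
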