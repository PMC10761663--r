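#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style tidiers for fitted objects and study results
#'
#' `tidy()` returns one row per estimated quantity; `glance()` returns a
#' one-row model-level summary. For study objects `tidy()` returns the
#' per-cell table and `glance()` the pooled summary.
#'
#' @param x A fitted object (`aif_fit`, `tcm_fit`, `patlak_fit`) or study
#'   result (`aif_study`, `tac_study`).
#' @param ... Unused.
#' @return A tibble.
#' @name petwin-tidiers
NULL

#' @rdname petwin-tidiers
#' @export
tidy.aif_fit <- function(x, ...) {
  tibble::tibble(term = names(unclass(x$estimate)),
                 estimate = as.numeric(unclass(x$estimate)),
                 unit = c("kBq/ml", "kBq/ml", "1/min", "1/min"))
}

#' @rdname petwin-tidiers
#' @export
tidy.tcm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("K1", "k2", "k3", "vb", "Ki"),
    estimate = c(as.numeric(unclass(x$estimate)), x$Ki),
    unit = c("ml/g/min", "1/min", "1/min", "unitless", "ml/g/min")
  )
}

#' @rdname petwin-tidiers
#' @export
tidy.patlak_fit <- function(x, ...) {
  tibble::tibble(term = c("Ki", "intercept"),
                 estimate = c(x$Ki, x$intercept),
                 unit = c("ml/g/min", "unitless"))
}

#' @rdname petwin-tidiers
#' @export
glance.petwin_fit <- function(x, ...) {
  tibble::tibble(residual_ss = x$residual_ss %||% NA_real_,
                 converged = x$converged %||% NA,
                 n_iter = x$n_iter %||% NA_integer_)
}

#' @rdname petwin-tidiers
#' @export
glance.patlak_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_points = x$n_points)
}

#' @rdname petwin-tidiers
#' @export
tidy.aif_study <- function(x, ...) x$cells

#' @rdname petwin-tidiers
#' @export
glance.aif_study <- function(x, ...) x$summary

#' @rdname petwin-tidiers
#' @export
tidy.tac_study <- function(x, ...) x$cells

#' @rdname petwin-tidiers
#' @export
glance.tac_study <- function(x, ...) x$summary

#' Plot a time-activity curve
#'
#' Step-plus-midpoint rendering of a frame-sampled curve.
#'
#' @param tac A time-activity curve tibble.
#' @param ... Extra aesthetics passed to [ggplot2::geom_point()].
#' @return A ggplot object.
#' @export
plot_tac <- function(tac, ...) {
  validate_schedule(tac)
  df <- dplyr::mutate(tac, midtime = frame_midtimes(tac))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$midtime, y = .data$activity)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_point(...) +
    ggplot2::labs(x = "time (min)", y = "activity (kBq/ml)") +
    ggplot2::theme_minimal()
}

#' @rdname petwin-tidiers
#' @param object An `aif_study`, `tac_study`, or `patlak_fit` object.
#' @export
autoplot.aif_study <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = factor(.data$noise_c),
                               y = .data$auc_error_abs)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "noise level c", y = "|AUC error| (%)",
                  title = "Input-function recovery across design cells") +
    ggplot2::theme_minimal()
}

#' @rdname petwin-tidiers
#' @export
autoplot.tac_study <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$parameter, y = .data$rel_error_pct,
                               fill = factor(.data$noise_c))) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "relative error (%)", fill = "noise c",
                  title = "Kinetic-parameter recovery across design cells") +
    ggplot2::theme_minimal()
}

#' @rdname petwin-tidiers
#' @export
autoplot.patlak_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$Ki, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(x = "normalized plasma integral (min)",
                  y = "tissue / plasma") +
    ggplot2::theme_minimal()
}
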