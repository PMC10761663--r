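#' Irreversible two-tissue-compartment parameters
#'
#' Micro-parameters of the irreversible 2TCM for FDG: influx `K1` (ml/g/min),
#' efflux `k2` (1/min), phosphorylation `k3` (1/min), and the vascular
#' (plasma) volume fraction `vb`.
#'
#' @param K1,k2,k3 Nonnegative rate constants.
#' @param vb Plasma volume fraction in `[0, 1]` (default 0.03, the value used
#'   for brain tissue throughout).
#' @return A named numeric vector of class `tcm_params`.
#' @examples
#' tcm_params(0.075, 0.15, 0.03)
#' @export
tcm_params <- function(K1, k2, k3, vb = 0.03) {
  p <- c(K1 = as.numeric(K1), k2 = as.numeric(k2),
         k3 = as.numeric(k3), vb = as.numeric(vb))
  if (any(!is.finite(p)) || any(p[c("K1", "k2", "k3")] < 0))
    stop("K1, k2, k3 must be nonnegative and finite", call. = FALSE)
  if (p[["vb"]] < 0 || p[["vb"]] > 1)
    stop("vb must lie in [0, 1]", call. = FALSE)
  structure(p, class = "tcm_params")
}

#' Tissue impulse response of the irreversible 2TCM
#'
#' The kernel \eqn{\frac{K_1 k_2}{k_2+k_3} e^{-(k_2+k_3)t} +
#' \frac{K_1 k_3}{k_2+k_3}}; equals `K1` at `t = 0` and decays to the
#' trapping plateau `K1 k3 / (k2 + k3)`. When `k2 + k3 = 0` the analytic
#' limit is the constant `K1`.
#'
#' @param params A [tcm_params()] object.
#' @param t Time(s) in minutes, `t >= 0`.
#' @return Impulse response (ml/g/min).
#' @export
impulse_response <- function(params, t) {
  stopifnot(inherits(params, "tcm_params"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  b <- params[["k2"]] + params[["k3"]]
  if (b == 0) return(rep(params[["K1"]], length(t)))
  params[["K1"]] * params[["k2"]] / b * exp(-b * t) +
    params[["K1"]] * params[["k3"]] / b
}

#' Net influx rate Ki
#'
#' \eqn{K_i = K_1 k_3 / (k_2 + k_3)} (ml/g/min), the macro-parameter of
#' irreversible FDG uptake.
#'
#' @param params A [tcm_params()] object (or anything with named elements
#'   `K1`, `k2`, `k3`).
#' @return Ki in ml/g/min.
#' @examples
#' net_influx_rate(tcm_params(0.075, 0.15, 0.03)) # 0.0125
#' @export
net_influx_rate <- function(params) {
  b <- params[["k2"]] + params[["k3"]]
  if (b <= 0) stop("Ki is undefined when k2 + k3 = 0", call. = FALSE)
  params[["K1"]] * params[["k3"]] / b
}

# Continuous 2TCM tissue curve at times t (closed form): the kernel
# convolution uses the exact exponential convolution of the Feng input and
# its running integral.
.ct_values <- function(params, aif_params, injections, t) {
  b <- params[["k2"]] + params[["k3"]]
  vb <- params[["vb"]]
  cp <- .cp(aif_params, injections, t)
  if (params[["K1"]] == 0) return(vb * cp)
  if (b == 0) {
    conv <- params[["K1"]] * .cp_int(aif_params, injections, t)
  } else {
    alpha <- params[["K1"]] * params[["k2"]] / b
    beta <- params[["K1"]] * params[["k3"]] / b
    conv <- alpha * .cp_econv(aif_params, injections, t, b) +
      beta * .cp_int(aif_params, injections, t)
  }
  (1 - vb) * conv + vb * cp
}

#' Forward 2TCM tissue time-activity curve
#'
#' Computes \eqn{C_T(t) = (1-v_b)\,(h \otimes C_p)(t) + v_b C_p(t)} with the
#' impulse response \eqn{h} of [impulse_response()] and a Feng
#' multi-injection plasma input, then frame-averages onto the schedule
#' (composite Simpson on sub-frame nodes of the closed-form solution).
#'
#' @param params A [tcm_params()] object.
#' @param aif_params A [feng_params()] object describing the plasma input.
#' @param injections An [injection_schedule()] tibble.
#' @param schedule A [frame_schedule()] tibble.
#' @param nsub Even number of Simpson subintervals per frame (default 8).
#' @return A time-activity curve tibble (`frame_start`, `frame_duration`,
#'   `activity`).
#' @examples
#' p <- standard_protocol()
#' tac_2tcm(tcm_params(0.075, 0.15, 0.03), feng_params(263, 16, 3.56, 0.029),
#'          p$injections, p$schedule)
#' @export
tac_2tcm <- function(params, aif_params, injections, schedule, nsub = 8L) {
  stopifnot(inherits(params, "tcm_params"), inherits(aif_params, "feng_params"))
  validate_injections(injections)
  validate_schedule(schedule)
  nodes <- .frame_nodes(schedule, nsub, breaks = injections$injection_time)
  vals <- .ct_values(params, aif_params, injections, nodes$t)
  dplyr::mutate(schedule, activity = .frame_average_nodes(vals, nodes))
}

#' Patlak transform of a tissue/plasma curve pair
#'
#' Maps the two frame-sampled curves to Patlak coordinates
#' \eqn{x_i = \int_0^{t_i} C_p / C_p(t_i)} (min) and
#' \eqn{y_i = C_T(t_i) / C_p(t_i)} at the frame midtimes. The plasma
#' integral is a cumulative trapezoid over the midtime grid anchored at
#' time zero with zero activity (curves start at injection). After
#' pseudo-equilibrium the points fall on a line with slope Ki.
#'
#' @param tissue,plasma Time-activity curve tibbles sharing one schedule.
#' @return A tibble with columns `time` (frame midtime, min), `x` (min),
#'   `y` (unitless). Frames with nonpositive plasma activity are dropped
#'   with a warning.
#' @export
patlak_transform <- function(tissue, plasma) {
  validate_schedule(tissue); validate_schedule(plasma)
  if (nrow(tissue) != nrow(plasma) ||
      any(abs(tissue$frame_start - plasma$frame_start) > 1e-9))
    stop("tissue and plasma curves must share a schedule", call. = FALSE)
  mid <- frame_midtimes(plasma)
  grid_t <- c(0, mid)
  grid_cp <- c(0, plasma$activity)
  ipl <- cumsum(c(0, diff(grid_t) * (grid_cp[-1] + grid_cp[-length(grid_cp)]) / 2))
  ipl <- ipl[-1]
  ok <- plasma$activity > 0
  if (!all(ok))
    warning(sum(!ok), " frame(s) with nonpositive plasma activity excluded")
  tibble::tibble(
    time = mid[ok],
    x = ipl[ok] / plasma$activity[ok],
    y = tissue$activity[ok] / plasma$activity[ok]
  )
}
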