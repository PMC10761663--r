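#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule is a tibble with one row per reconstructed time frame.
#' Times are minutes from the first tracer injection; frame intervals are
#' half-open `[start, start + duration)`.
#'
#' @param frame_start Numeric vector of frame start times (min).
#' @param frame_duration Numeric vector of frame durations (min), same length.
#' @return A tibble with columns `frame_start` and `frame_duration`.
#' @examples
#' frame_schedule(c(0, 0.5), c(0.5, 0.5))
#' @export
frame_schedule <- function(frame_start, frame_duration) {
  sched <- tibble::tibble(
    frame_start = as.numeric(frame_start),
    frame_duration = as.numeric(frame_duration)
  )
  validate_schedule(sched)
  sched
}

#' @rdname frame_schedule
#' @param schedule A frame-schedule tibble.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(
    is.data.frame(schedule),
    all(c("frame_start", "frame_duration") %in% names(schedule))
  )
  if (nrow(schedule) == 0L) return(invisible(schedule))
  with(schedule, {
    if (any(!is.finite(frame_start)) || any(!is.finite(frame_duration)))
      stop("frame times must be finite", call. = FALSE)
    if (any(frame_duration <= 0))
      stop("frame durations must be positive", call. = FALSE)
    ends <- frame_start + frame_duration
    if (is.unsorted(frame_start, strictly = TRUE))
      stop("frames must be sorted by start time", call. = FALSE)
    if (any(frame_start[-1] < ends[-length(ends)] - 1e-9))
      stop("frames must not overlap", call. = FALSE)
  })
  invisible(schedule)
}

#' Injection schedule of a multi-injection protocol
#'
#' @param injection_time Strictly increasing injection times (min).
#' @param dose_fraction Positive dose fractions, one per injection, summing to 1.
#' @return A tibble with columns `injection_time` and `dose_fraction`.
#' @examples
#' injection_schedule(c(0, 42.5, 49))
#' @export
injection_schedule <- function(injection_time,
                               dose_fraction = rep(1 / length(injection_time),
                                                   length(injection_time))) {
  inj <- tibble::tibble(
    injection_time = as.numeric(injection_time),
    dose_fraction = as.numeric(dose_fraction)
  )
  validate_injections(inj)
  inj
}

#' @rdname injection_schedule
#' @param injections An injection-schedule tibble.
#' @export
validate_injections <- function(injections) {
  stopifnot(
    is.data.frame(injections),
    all(c("injection_time", "dose_fraction") %in% names(injections))
  )
  with(injections, {
    if (is.unsorted(injection_time, strictly = TRUE))
      stop("injection times must be strictly increasing", call. = FALSE)
    if (any(dose_fraction <= 0))
      stop("dose fractions must be positive", call. = FALSE)
    if (abs(sum(dose_fraction) - 1) > 1e-8)
      stop("dose fractions must sum to 1", call. = FALSE)
  })
  invisible(injections)
}

#' Imaging window
#'
#' @param label Window name.
#' @param start,end Window limits in minutes, `0 <= start < end`.
#' @return A one-row tibble with columns `label`, `start`, `end`.
#' @export
imaging_window <- function(label, start, end) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(start), is.numeric(end), start >= 0, start < end)
  tibble::tibble(label = label, start = as.numeric(start), end = as.numeric(end))
}

#' The canonical triple-injection 60-min protocol
#'
#' Returns the acquisition layout used throughout: a 36-min uptake
#' and validation phase after the first injection, a 3-min late brain scan
#' (36-39 min, 2 x 90 s), a 9-min cardiac scan (39-48 min; 3 x 60 s,
#' 3 x 20 s, 4 x 30 s, 3 x 60 s) during which the second dose is injected at
#' 42.5 min, and a 12-min early brain scan (48-60 min; 2 x 90 s, 3 x 180 s)
#' with the third dose at 49 min. The simulation schedule tiles the full
#' 0-60 min with 50 frames (3 x 20 s, 4 x 30 s, 3 x 60 s, 22 x 90 s followed
#' by the frames above) so that simulated curves cover the validation window.
#'
#' @param dose_fraction Dose fraction per injection (default equal thirds).
#' @return A list with elements `schedule` (50-frame simulation schedule),
#'   `injections`, and `windows` (tibble of the four imaging windows:
#'   `validation` 0-36, `brain_late` 36-39, `cardiac` 39-48,
#'   `brain_early` 48-60 min).
#' @examples
#' p <- standard_protocol()
#' sum(p$schedule$frame_duration) # 60 min
#' @export
standard_protocol <- function(dose_fraction = rep(1 / 3, 3)) {
  durations_s <- c(rep(20, 3), rep(30, 4), rep(60, 3), rep(90, 22),
                   rep(60, 3), rep(20, 3), rep(30, 4), rep(60, 3),
                   rep(90, 2), rep(180, 3))
  durations <- durations_s / 60
  starts <- cumsum(c(0, durations[-length(durations)]))
  list(
    schedule = frame_schedule(starts, durations),
    injections = injection_schedule(c(0, 42.5, 49), dose_fraction),
    windows = dplyr::bind_rows(
      imaging_window("validation", 0, 36),
      imaging_window("brain_late", 36, 39),
      imaging_window("cardiac", 39, 48),
      imaging_window("brain_early", 48, 60)
    )
  )
}

#' Frame midtimes
#'
#' @param schedule A frame-schedule tibble.
#' @return Numeric vector of frame midpoint times (min).
#' @export
frame_midtimes <- function(schedule) {
  validate_schedule(schedule)
  schedule$frame_start + schedule$frame_duration / 2
}

#' Select frames fully contained in a window
#'
#' Frames are half-open `[start, start + duration)`; a frame is selected when
#' it lies entirely within `[window$start, window$end)`. Frames straddling a
#' boundary are excluded.
#'
#' @param schedule A frame-schedule tibble.
#' @param window An imaging-window tibble (one row), or a numeric
#'   `c(start, end)` pair.
#' @return Integer vector of selected frame indices.
#' @export
select_window <- function(schedule, window) {
  validate_schedule(schedule)
  if (is.numeric(window)) {
    stopifnot(length(window) == 2L, window[1] <= window[2])
    window <- tibble::tibble(label = "window", start = window[1],
                             end = window[2])
  }
  eps <- 1e-9
  which(schedule$frame_start >= window$start - eps &
          schedule$frame_start + schedule$frame_duration <= window$end + eps)
}

#' Read a protocol configuration file
#'
#' The file (YAML, JSON also parses as YAML) holds `frames` as a list of
#' `[n_frames, duration_s]` blocks, `injection_times_min`, and optional
#' `dose_fractions`.
#'
#' @param path Path to the config file.
#' @return A list with `schedule` and `injections` as in [standard_protocol()].
#' @export
read_protocol_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$frames), !is.null(cfg$injection_times_min))
  durations <- unlist(lapply(cfg$frames, function(b) rep(b[[2]], b[[1]]))) / 60
  starts <- cumsum(c(0, durations[-length(durations)]))
  times <- as.numeric(cfg$injection_times_min)
  fracs <- if (is.null(cfg$dose_fractions)) rep(1 / length(times), length(times))
           else as.numeric(cfg$dose_fractions)
  list(schedule = frame_schedule(starts, durations),
       injections = injection_schedule(times, fracs))
}
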