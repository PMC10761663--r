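#' Read and write time-activity curves as CSV
#'
#' The on-disk format has the header
#' `frame_start_min,frame_duration_min,activity_kBq_ml` and round-trips
#' exactly on text.
#'
#' @param path File path.
#' @return `read_tac()` returns a time-activity curve tibble.
#' @export
read_tac <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("frame_start_min", "frame_duration_min", "activity_kBq_ml")
  if (!all(need %in% names(df)))
    stop("TAC file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tac <- tibble::tibble(
    frame_start = as.numeric(df$frame_start_min),
    frame_duration = as.numeric(df$frame_duration_min),
    activity = as.numeric(df$activity_kBq_ml)
  )
  validate_schedule(tac)
  tac
}

#' @rdname read_tac
#' @param tac A time-activity curve tibble (`frame_start`,
#'   `frame_duration`, `activity`).
#' @export
write_tac <- function(tac, path) {
  validate_schedule(tac)
  stopifnot("activity" %in% names(tac))
  df <- data.frame(
    frame_start_min = format(tac$frame_start, digits = 17, trim = TRUE,
                             scientific = FALSE),
    frame_duration_min = format(tac$frame_duration, digits = 17,
                                trim = TRUE, scientific = FALSE),
    activity_kBq_ml = format(tac$activity, digits = 17, trim = TRUE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.pixdim_header <- function(voxel_size, nframes = NULL) {
  pd <- c(-1, voxel_size, if (is.null(nframes)) NULL else 1)
  list(pixdim = c(pd, rep(0, 8 - length(pd))))
}

#' Read and write dynamic images as NIfTI with a frame-schedule sidecar
#'
#' NIfTI carries no per-frame timing, so the schedule is stored in a
#' sidecar CSV (`<path>.frames.csv` by default) with columns
#' `frame_start_min` and `frame_duration_min`.
#'
#' @param image A [dynamic_image()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param sidecar Path of the schedule sidecar CSV.
#' @return `read_dynamic_image()` returns a [dynamic_image()].
#' @export
write_dynamic_image <- function(image, path,
                                sidecar = paste0(path, ".frames.csv")) {
  stopifnot(inherits(image, "dynamic_image"))
  nii <- RNifti::asNifti(image$data,
                         reference = .pixdim_header(image$voxel_size,
                                                    nrow(image$schedule)))
  RNifti::writeNifti(nii, path)
  utils::write.csv(
    data.frame(frame_start_min = image$schedule$frame_start,
               frame_duration_min = image$schedule$frame_duration),
    sidecar, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dynamic_image
#' @export
read_dynamic_image <- function(path, sidecar = paste0(path, ".frames.csv")) {
  nii <- RNifti::readNifti(path)
  df <- utils::read.csv(sidecar)
  sched <- frame_schedule(df$frame_start_min, df$frame_duration_min)
  dynamic_image(array(as.numeric(nii), dim(nii)),
                RNifti::pixdim(nii)[1:3], sched)
}

#' Read and write label maps as NIfTI
#'
#' The region table is stored as a sidecar CSV (`<path>.regions.csv`) with
#' columns `label` and `name`.
#'
#' @param labels A [label_map()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param voxel_size Voxel size in mm.
#' @param sidecar Path of the region-table sidecar CSV.
#' @return `read_label_map()` returns a [label_map()].
#' @export
write_label_map <- function(labels, path, voxel_size = c(1, 1, 1),
                            sidecar = paste0(path, ".regions.csv")) {
  stopifnot(inherits(labels, "label_map"))
  nii <- RNifti::asNifti(labels$labels,
                         reference = .pixdim_header(voxel_size),
                         datatype = "int16")
  RNifti::writeNifti(nii, path)
  utils::write.csv(labels$regions, sidecar, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path, sidecar = paste0(path, ".regions.csv")) {
  nii <- RNifti::readNifti(path)
  label_map(array(as.integer(nii), dim(nii)), utils::read.csv(sidecar))
}

#' Write parametric maps as one NIfTI volume per parameter
#'
#' @param maps A `parametric_maps` object from [voxelwise_maps()].
#' @param prefix Output path prefix; files are `<prefix>_K1.nii.gz` etc.
#' @return Invisibly, the written paths.
#' @export
write_parametric_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "parametric_maps"))
  paths <- character(0)
  for (nm in c("K1", "k2", "k3", "Ki")) {
    p <- paste0(prefix, "_", nm, ".nii.gz")
    nii <- RNifti::asNifti(maps[[nm]],
                           reference = .pixdim_header(maps$voxel_size),
                           datatype = "float")
    RNifti::writeNifti(nii, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
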