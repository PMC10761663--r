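#' Dynamic image container
#'
#' A 4D voxel grid of activity concentrations (kBq/ml) with its voxel size
#' and frame schedule. Voxel indexing is 0-based for world coordinates:
#' the center of voxel `(i, j, k)` (1-based array index) lies at
#' `(i - 1, j - 1, k - 1) * voxel_size` mm. No affine/orientation handling;
#' axis-aligned grids only.
#'
#' @param data 4D numeric array; the 4th dimension indexes frames.
#' @param voxel_size Length-3 positive numeric (mm).
#' @param schedule A [frame_schedule()] whose length matches `dim(data)[4]`.
#' @return A list of class `dynamic_image`.
#' @export
dynamic_image <- function(data, voxel_size, schedule) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            is.numeric(voxel_size), length(voxel_size) == 3L,
            all(voxel_size > 0))
  validate_schedule(schedule)
  if (dim(data)[4] != nrow(schedule))
    stop("4th dimension must equal the number of frames", call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 schedule = schedule), class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  cat("<dynamic_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ", paste(x$voxel_size, collapse = " x "),
      " mm, ", nrow(x$schedule), " frames\n", sep = "")
  invisible(x)
}

#' Integer label map with a region table
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param regions A tibble with columns `label` and `name` covering every
#'   nonzero label present.
#' @return A list of class `label_map`.
#' @export
label_map <- function(labels, regions) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L,
            is.data.frame(regions),
            all(c("label", "name") %in% names(regions)))
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, regions$label)
  if (length(missing))
    stop("labels without region-table entry: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, regions = tibble::as_tibble(regions)),
            class = "label_map")
}

#' Combined spatial resolution of independent Gaussian blurs
#'
#' Root-sum-of-squares of the component FWHMs.
#'
#' @param components Nonnegative FWHMs (mm).
#' @return Combined FWHM (mm).
#' @examples
#' combined_fwhm(c(3, 4)) # 5
#' @export
combined_fwhm <- function(components) {
  stopifnot(is.numeric(components), all(components >= 0))
  sqrt(sum(components^2))
}

# 1D reflective-boundary Gaussian smoothing matrix (whole-sample reflection).
.smooth_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  off <- (-r):r
  w <- stats::dnorm(off, sd = sigma_vox)
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + off
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    for (m in seq_along(idx)) S[i, idx[m]] <- S[i, idx[m]] + w[m]
  }
  S
}

#' In-plane Gaussian smoothing of a dynamic image
#'
#' Applies a 2D Gaussian kernel to every axial slice of every frame, with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` converted to voxel units per in-plane
#' axis, and reflective boundaries. `fwhm = 0` is the identity.
#'
#' @param image A [dynamic_image()].
#' @param fwhm Kernel full width at half maximum (mm), `>= 0`.
#' @return A smoothed [dynamic_image()].
#' @export
gaussian_smooth <- function(image, fwhm) {
  stopifnot(inherits(image, "dynamic_image"), fwhm >= 0)
  if (fwhm == 0) return(image)
  sig_mm <- fwhm / (2 * sqrt(2 * log(2)))
  dm <- dim(image$data)
  Sx <- .smooth_matrix(dm[1], sig_mm / image$voxel_size[1])
  Sy <- t(.smooth_matrix(dm[2], sig_mm / image$voxel_size[2]))
  out <- image$data
  for (f in seq_len(dm[4])) for (z in seq_len(dm[3])) {
    out[, , z, f] <- Sx %*% image$data[, , z, f] %*% Sy
  }
  dynamic_image(out, image$voxel_size, image$schedule)
}

# Voxel-center world coordinates (mm) for a grid.
.voxel_centers <- function(dm, voxel_size) {
  list(x = (seq_len(dm[1]) - 1) * voxel_size[1],
       y = (seq_len(dm[2]) - 1) * voxel_size[2],
       z = (seq_len(dm[3]) - 1) * voxel_size[3])
}

#' Mean time-activity curve in a spherical ROI
#'
#' Averages, per frame, the voxels whose centers lie within
#' `diameter / 2` mm of `center` (world coordinates, mm).
#'
#' @param image A [dynamic_image()].
#' @param center Length-3 numeric, sphere center (mm).
#' @param diameter Sphere diameter (mm); the cardiac blood-pool ROI uses
#'   10 mm.
#' @return A time-activity curve tibble.
#' @export
spherical_roi_mean <- function(image, center, diameter) {
  stopifnot(inherits(image, "dynamic_image"), length(center) == 3L,
            diameter > 0)
  dm <- dim(image$data)
  cc <- .voxel_centers(dm, image$voxel_size)
  d2 <- outer(outer((cc$x - center[1])^2, (cc$y - center[2])^2, `+`),
              (cc$z - center[3])^2, `+`)
  inside <- d2 <= (diameter / 2)^2
  if (!any(inside)) stop("spherical ROI contains no voxel centers",
                         call. = FALSE)
  vox <- matrix(image$data, prod(dm[1:3]), dm[4])
  act <- colMeans(vox[as.vector(inside), , drop = FALSE])
  dplyr::mutate(image$schedule, activity = act)
}

#' Per-region mean time-activity curves
#'
#' @param image A [dynamic_image()].
#' @param labels A [label_map()] aligned with the image grid.
#' @return A tibble with one row per region x frame: `region`, `label`,
#'   `frame_start`, `frame_duration`, `activity`.
#' @export
label_roi_tacs <- function(image, labels) {
  stopifnot(inherits(image, "dynamic_image"), inherits(labels, "label_map"))
  dm <- dim(image$data)
  if (!all(dim(labels$labels) == dm[1:3]))
    stop("label map does not match image spatial dimensions", call. = FALSE)
  vox <- matrix(image$data, prod(dm[1:3]), dm[4])
  lab <- as.vector(labels$labels)
  purrr::map_dfr(seq_len(nrow(labels$regions)), function(i) {
    l <- labels$regions$label[i]
    sel <- lab == l
    if (!any(sel)) stop("no voxels carry label ", l, call. = FALSE)
    dplyr::mutate(image$schedule,
                  region = labels$regions$name[i], label = l,
                  activity = colMeans(vox[sel, , drop = FALSE]),
                  .before = 1)
  })
}

#' Voxel-wise 2TCM parametric maps
#'
#' Fits the irreversible 2TCM (vb fixed) to every masked voxel using the
#' frames inside `windows`, and derives Ki per voxel. Per-voxel fit
#' failures are flagged, not raised.
#'
#' @param image A [dynamic_image()].
#' @param aif_params A [feng_params()] input function.
#' @param injections An [injection_schedule()] tibble.
#' @param windows Numeric `c(start, end)` pair or a multi-row window tibble
#'   (default: the 36-39 plus 48-60 min short imaging window).
#' @param mask 3D logical array of voxels to fit.
#' @param vb Fixed plasma volume fraction (default 0.03).
#' @param bounds,init Passed to the bounded fit (defaults as in
#'   [fit_2tcm()]).
#' @return An object of class `parametric_maps`: 3D arrays `K1`, `k2`,
#'   `k3`, `Ki`, `residual_ss`, logical `converged`, plus the `mask`;
#'   voxels outside the mask are `NA`.
#' @export
voxelwise_maps <- function(image, aif_params, injections,
                           windows = rbind(c(36, 39), c(48, 60)),
                           mask, vb = 0.03,
                           bounds = default_tcm_bounds(),
                           init = c(K1 = 0.1, k2 = 0.1, k3 = 0.05)) {
  stopifnot(inherits(image, "dynamic_image"), is.array(mask),
            all(dim(mask) == dim(image$data)[1:3]))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  sched <- image$schedule
  if (is.numeric(windows) && is.null(dim(windows)))
    windows <- matrix(windows, nrow = 1L)
  widx <- sort(unique(unlist(lapply(seq_len(nrow(windows)), function(i)
    select_window(sched, as.numeric(windows[i, 1:2]))))))
  if (length(widx) < 3L) stop("fewer than 3 frames in the fitting windows",
                              call. = FALSE)
  d <- .tcm_design(sched[widx, ], aif_params, injections, vb)
  dm <- dim(image$data)
  vox <- matrix(image$data, prod(dm[1:3]), dm[4])[, widx, drop = FALSE]
  sel <- which(as.vector(mask))
  blank <- array(NA_real_, dm[1:3])
  maps <- list(K1 = blank, k2 = blank, k3 = blank, Ki = blank,
               residual_ss = blank,
               converged = array(NA, dm[1:3]))
  for (v in sel) {
    f <- .fit_2tcm_core(vox[v, ], d, bounds, init)
    maps$K1[v] <- f$estimate[["K1"]]
    maps$k2[v] <- f$estimate[["k2"]]
    maps$k3[v] <- f$estimate[["k3"]]
    maps$Ki[v] <- f$Ki
    maps$residual_ss[v] <- f$residual_ss
    maps$converged[v] <- f$converged
  }
  structure(c(maps, list(mask = mask, voxel_size = image$voxel_size)),
            class = "parametric_maps")
}

#' Voxel-wise Patlak net-influx map
#'
#' Linear Patlak fit per masked voxel against a plasma curve, using frames
#' with midtimes in `[t_start, t_end)` (the transform abscissa is shared
#' across voxels, so the fit is vectorized).
#'
#' @inheritParams voxelwise_maps
#' @param plasma A plasma time-activity curve tibble on the image schedule.
#' @param t_start,t_end Linear-segment limits in minutes (defaults 15 and
#'   36, the pseudo-equilibrium portion of the validation window).
#' @return A 3D array of Ki values (`NA` outside the mask).
#' @export
voxelwise_patlak <- function(image, plasma, mask, t_start = 15, t_end = 36) {
  stopifnot(inherits(image, "dynamic_image"), is.array(mask))
  sched <- image$schedule
  if (nrow(plasma) != nrow(sched))
    stop("plasma curve must be sampled on the image schedule", call. = FALSE)
  mid <- frame_midtimes(sched)
  grid_t <- c(0, mid); grid_cp <- c(0, plasma$activity)
  ipl <- cumsum(c(0, diff(grid_t) * (grid_cp[-1] + grid_cp[-length(grid_cp)]) / 2))[-1]
  use <- which(mid >= t_start & mid < t_end & plasma$activity > 0)
  if (length(use) < 2L) stop("fewer than 2 usable Patlak frames", call. = FALSE)
  x <- ipl[use] / plasma$activity[use]
  dm <- dim(image$data)
  vox <- matrix(image$data, prod(dm[1:3]), dm[4])[, use, drop = FALSE]
  y <- sweep(vox, 2L, plasma$activity[use], "/")
  xc <- x - mean(x)
  slope <- as.vector(y %*% xc) / sum(xc^2)
  out <- array(NA_real_, dm[1:3])
  out[as.vector(mask)] <- slope[as.vector(mask)]
  out
}

#' Default synthetic brain-and-blood-pool phantom geometry
#'
#' A concentric-ellipsoid "brain" (gray-matter shell, white-matter core,
#' zero-uptake CSF ventricles) plus a separate blood-pool sphere fed by the
#' pure input function, on a small grid so voxel-wise fitting stays fast.
#' Default kinetic parameters are typical human FDG values for gray matter
#' (K1 = 0.08 ml/g/min, k2 = 0.11, k3 = 0.04 1/min) and white matter
#' (0.05, 0.07, 0.03), vb = 0.03; the blood region is modeled as vb = 1
#' with zero tissue exchange so its curve is exactly the input function.
#'
#' @param dim Grid size (default `c(48, 48, 24)`).
#' @param voxel_size Voxel size in mm (default `c(4, 4, 5)`).
#' @return A list with `labels` (a [label_map()]) and `params` (a tibble
#'   of per-region [tcm_params()] fields: `label`, `name`, `K1`, `k2`,
#'   `k3`, `vb`).
#' @export
brain_phantom_geometry <- function(dim = c(48, 48, 24),
                                   voxel_size = c(4, 4, 5)) {
  stopifnot(length(dim) == 3L, all(dim >= 8))
  ctr <- (dim + 1) / 2
  ax <- dim * c(1 / 3, 1 / 3, 0.375)  # brain ellipsoid semi-axes (voxels)
  i <- slice.index(array(0, dim), 1)
  j <- slice.index(array(0, dim), 2)
  k <- slice.index(array(0, dim), 3)
  r2 <- ((i - ctr[1]) / ax[1])^2 + ((j - ctr[2]) / ax[2])^2 +
    ((k - ctr[3]) / ax[3])^2
  lab <- array(0L, dim)
  lab[r2 <= 1] <- 1L                                  # gray-matter shell
  lab[r2 <= 0.75^2] <- 2L                             # white-matter core
  vent <- ((i - ctr[1]) / (ax[1] / 4))^2 + ((j - ctr[2]) / (ax[2] / 2.5))^2 +
    ((k - ctr[3]) / (ax[3] / 3))^2
  lab[vent <= 1] <- 3L                                # CSF ventricles
  bl_ctr <- c(5, 5, 5); bl_r <- 3                     # blood pool (voxels)
  bl <- (i - bl_ctr[1])^2 + (j - bl_ctr[2])^2 + (k - bl_ctr[3])^2 <= bl_r^2
  lab[bl] <- 4L
  regions <- tibble::tibble(
    label = 1:4,
    name = c("gray_matter", "white_matter", "csf", "blood_pool")
  )
  params <- tibble::tibble(
    label = 1:4,
    name = regions$name,
    K1 = c(0.08, 0.05, 0, 0),
    k2 = c(0.11, 0.07, 0, 0),
    k3 = c(0.04, 0.03, 0, 0),
    vb = c(0.03, 0.03, 0, 1)
  )
  list(labels = label_map(lab, regions), params = params)
}

#' Synthesize a dynamic phantom from a label map
#'
#' Every voxel of a region follows the frame-averaged 2TCM curve for that
#' region's parameters under the given input function; frame noise is then
#' added independently per voxel and frame. Ground truth (parameter maps,
#' Ki map, region curves, and the input function) is returned alongside
#' for testing.
#'
#' @param labels A [label_map()].
#' @param params_per_region Tibble with columns `label`, `K1`, `k2`, `k3`,
#'   `vb` covering every region.
#' @param aif_params A [feng_params()].
#' @param injections An [injection_schedule()] tibble.
#' @param schedule A [frame_schedule()] (default: canonical 60-min
#'   simulation schedule).
#' @param noise A [noise_config()]; `c = 0` gives a noiseless phantom.
#' @param voxel_size Voxel size in mm.
#' @param noise_dt_unit Frame-duration unit inside the noise SD (default
#'   `"s"`, matching the kinetic simulation study).
#' @return A list of class `phantom`: `image` (a [dynamic_image()]),
#'   `truth` (list of 3D maps `K1`, `k2`, `k3`, `vb`, `Ki`), `region_tacs`
#'   (noiseless per-region curves), `aif_params`, `injections`, `labels`.
#' @export
synth_phantom <- function(labels, params_per_region, aif_params, injections,
                          schedule = standard_protocol()$schedule,
                          noise = noise_config(),
                          voxel_size = c(4, 4, 5),
                          noise_dt_unit = c("s", "min")) {
  stopifnot(inherits(labels, "label_map"),
            all(c("label", "K1", "k2", "k3", "vb") %in%
                  names(params_per_region)))
  noise_dt_unit <- match.arg(noise_dt_unit)
  present <- setdiff(unique(as.integer(labels$labels)), 0L)
  if (!all(present %in% params_per_region$label))
    stop("every label needs kinetic parameters", call. = FALSE)
  dm3 <- dim(labels$labels)
  nf <- nrow(schedule)
  lab <- as.vector(labels$labels)
  vox <- matrix(0, length(lab), nf)
  truth <- list(K1 = array(NA_real_, dm3), k2 = array(NA_real_, dm3),
                k3 = array(NA_real_, dm3), vb = array(NA_real_, dm3),
                Ki = array(NA_real_, dm3))
  region_tacs <- list()
  for (i in seq_len(nrow(params_per_region))) {
    pr <- params_per_region[i, ]
    sel <- lab == pr$label
    if (!any(sel)) next
    p <- tcm_params(pr$K1, pr$k2, pr$k3, pr$vb)
    tac <- tac_2tcm(p, aif_params, injections, schedule)
    vox[sel, ] <- rep(tac$activity, each = sum(sel))
    truth$K1[sel] <- pr$K1; truth$k2[sel] <- pr$k2
    truth$k3[sel] <- pr$k3; truth$vb[sel] <- pr$vb
    truth$Ki[sel] <- if (pr$k2 + pr$k3 > 0) net_influx_rate(p) else 0
    region_tacs[[i]] <- dplyr::mutate(tac, label = pr$label, .before = 1)
  }
  if (noise$c > 0) {
    dt <- schedule$frame_duration * if (noise_dt_unit == "s") 60 else 1
    withr::with_seed(noise$seed, {
      sd <- sweep(sqrt(pmax(vox, 0)), 2L, sqrt(dt), "/") * noise$c
      vox <- vox + stats::rnorm(length(vox)) * sd
    })
  }
  img <- dynamic_image(array(vox, c(dm3, nf)), voxel_size, schedule)
  structure(list(image = img, truth = truth,
                 region_tacs = dplyr::bind_rows(region_tacs),
                 aif_params = aif_params, injections = injections,
                 labels = labels),
            class = "phantom")
}
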