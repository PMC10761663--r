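test_that("combined FWHM is the root sum of squares", {
  expect_equal(combined_fwhm(c(7, 0, 0)), 7)
  expect_equal(combined_fwhm(c(3, 4)), 5)
  # scanner + reconstruction + smoothing components
  expect_equal(combined_fwhm(c(4.37, 2, 4.11)), 6.3237, tolerance = 1e-4)
  expect_error(combined_fwhm(c(-1, 2)))
})

test_that("gaussian smoothing is identity at fwhm 0, flat-field invariant,
           and mass preserving", {
  ph <- small_phantom(noise_c = 0.3, seed = 4)
  img <- dynamic_image(ph$image$data[, , , 1:3, drop = FALSE],
                       ph$image$voxel_size, ph$image$schedule[1:3, ])
  expect_identical(gaussian_smooth(img, 0), img)
  flat <- dynamic_image(array(2.5, dim(img$data)), img$voxel_size,
                        img$schedule)
  sm_flat <- gaussian_smooth(flat, 8)
  expect_equal(sm_flat$data, flat$data, tolerance = 1e-12)
  sm <- gaussian_smooth(img, 4.11)
  # reflective boundaries preserve per-slice total activity
  s_before <- sum(img$data[, , 4, 2]); s_after <- sum(sm$data[, , 4, 2])
  expect_equal(s_after, s_before, tolerance = 1e-3)
  # smoothing strictly reduces the spread of the pure noise component
  # (smoothing is linear, so the noise component maps through it)
  clean <- small_phantom()
  noise3 <- img$data[, , , 2] - clean$image$data[, , , 2]
  nimg <- dynamic_image(array(noise3, c(dim(noise3), 1L)), img$voxel_size,
                        img$schedule[1, ])
  smn <- gaussian_smooth(nimg, 4.11)$data[, , , 1]
  expect_lt(sd(smn), sd(noise3))
})

test_that("spherical ROI extraction averages the right voxels", {
  ph <- small_phantom()
  img <- ph$image
  flat <- dynamic_image(array(7, dim(img$data)), img$voxel_size,
                        img$schedule)
  tac <- spherical_roi_mean(flat, c(40, 40, 30), 20)
  expect_equal(tac$activity, rep(7, nrow(img$schedule)))
  # a sphere smaller than a voxel hits exactly one voxel center
  one <- spherical_roi_mean(img, (c(5, 5, 5) - 1) * img$voxel_size, 3)
  expect_equal(one$activity, img$data[5, 5, 5, ])
  expect_error(spherical_roi_mean(img, c(-500, 0, 0), 4), "no voxel")
})

test_that("LV blood-pool ROI recovers the input function from a noisy
           phantom", {
  ph <- small_phantom(noise_c = 0.1, seed = 12)
  geo_center <- (c(5, 5, 5) - 1) * ph$image$voxel_size
  tac <- spherical_roi_mean(ph$image, geo_center, 10)
  truth <- sample_aif(mean_feng, proto$injections, proto$schedule)
  n_vox <- sum((ph$labels$labels == 4L)[
    (slice.index(ph$labels$labels, 1) - 5)^2 * ph$image$voxel_size[1]^2 +
    (slice.index(ph$labels$labels, 2) - 5)^2 * ph$image$voxel_size[2]^2 +
    (slice.index(ph$labels$labels, 3) - 5)^2 * ph$image$voxel_size[3]^2 <= 25])
  # per-frame deviation within 3 SE of the frame noise
  dt_s <- proto$schedule$frame_duration * 60
  se <- 0.1 * sqrt(pmax(truth$activity, 0) / dt_s) / sqrt(max(n_vox, 1))
  expect_true(all(abs(tac$activity - truth$activity) <= 3 * se + 1e-9))
})

test_that("per-region TACs match the generating curves", {
  ph <- small_phantom()
  tacs <- label_roi_tacs(ph$image, ph$labels)
  gm <- tacs[tacs$region == "gray_matter", ]
  truth_gm <- tac_2tcm(tcm_params(0.08, 0.11, 0.04), mean_feng,
                       proto$injections, proto$schedule)
  expect_equal(gm$activity, truth_gm$activity, tolerance = 1e-12)
  # blood pool (vb = 1) reproduces the input function to quadrature accuracy
  blood <- tacs[tacs$region == "blood_pool", ]
  truth_cp <- sample_aif(mean_feng, proto$injections, proto$schedule)
  expect_equal(blood$activity, truth_cp$activity, tolerance = 1e-4)
})

test_that("phantoms are reproducible and carry exact ground truth", {
  a <- small_phantom(noise_c = 0.2, seed = 8)
  b <- small_phantom(noise_c = 0.2, seed = 8)
  expect_identical(a$image$data, b$image$data)
  gm_ki <- a$truth$Ki[a$labels$labels == 1L][1]
  expect_equal(gm_ki, 0.08 * 0.04 / 0.15)   # 0.021333 ml/g/min
  # noiseless gray-matter voxel reproduces tac_2tcm exactly
  c0 <- small_phantom()
  idx <- which(c0$labels$labels == 1L, arr.ind = TRUE)[1, ]
  vox_tac <- c0$image$data[idx[1], idx[2], idx[3], ]
  truth <- tac_2tcm(tcm_params(0.08, 0.11, 0.04), mean_feng,
                    proto$injections, proto$schedule)$activity
  expect_identical(vox_tac, truth)
})

test_that("voxel-wise mapping recovers a noiseless phantom and respects a
           degenerate mask", {
  ph <- small_phantom()
  mask <- array(FALSE, dim(ph$labels$labels))
  idx <- which(ph$labels$labels == 1L)[1:4]
  mask[idx] <- TRUE
  idx2 <- which(ph$labels$labels == 2L)[1:4]
  mask[idx2] <- TRUE
  maps <- voxelwise_maps(ph$image, mean_feng, proto$injections, mask = mask)
  for (nm in c("K1", "k2", "k3", "Ki")) {
    rel <- abs(maps[[nm]][mask] - ph$truth[[nm]][mask]) /
      ph$truth[[nm]][mask]
    expect_lt(max(rel), 0.01)
    expect_true(all(is.na(maps[[nm]][!mask])))
  }
  one <- array(FALSE, dim(mask)); one[idx[1]] <- TRUE
  m1 <- voxelwise_maps(ph$image, mean_feng, proto$injections, mask = one)
  expect_equal(sum(!is.na(m1$K1)), 1L)
  expect_error(voxelwise_maps(ph$image, mean_feng, proto$injections,
                              mask = array(FALSE, dim(mask))), "empty")
})

test_that("NIfTI image, label map and parametric maps round-trip", {
  ph <- small_phantom(noise_c = 0.1, seed = 3)
  sub <- dynamic_image(ph$image$data[, , , 1:4, drop = FALSE],
                       ph$image$voxel_size, ph$image$schedule[1:4, ])
  f <- tempfile(fileext = ".nii.gz")
  write_dynamic_image(sub, f)
  back <- read_dynamic_image(f)
  expect_equal(back$data, unclass(sub$data), tolerance = 1e-12)
  expect_equal(back$voxel_size, sub$voxel_size)
  expect_equal(back$schedule, sub$schedule)

  fl <- tempfile(fileext = ".nii.gz")
  write_label_map(ph$labels, fl, voxel_size = ph$image$voxel_size)
  labs <- read_label_map(fl)
  expect_identical(labs$labels, unclass(ph$labels$labels))
  expect_equal(labs$regions$name, ph$labels$regions$name)

  mask <- array(FALSE, dim(ph$labels$labels))
  mask[which(ph$labels$labels == 2L)[1:2]] <- TRUE
  maps <- voxelwise_maps(ph$image, mean_feng, proto$injections, mask = mask)
  paths <- write_parametric_maps(maps, tempfile())
  k1 <- RNifti::readNifti(paste0(sub("_K1.*", "", paths[1]), "_K1.nii.gz"))
  expect_equal(as.numeric(k1[mask]), maps$K1[mask], tolerance = 1e-6)
})
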