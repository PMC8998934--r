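test_that("voxel volume arithmetic is exact and the truncation helper matches print style", {
  expect_identical(voxel_volume(20, 20, 256, 256, 0.8), 0.0048828125)
  expect_identical(format_voxel_volume(voxel_volume(20, 20, 256, 256, 0.8)),
                   "0.0048")
  expect_identical(voxel_volume(256, 256, 256, 256, 1.0), 1.0)
  expect_equal(voxel_volume(10, 20, 100, 200, 0.5), 0.005, tolerance = 1e-15)
  expect_error(voxel_volume(0, 20, 256, 256, 0.8), "positive")
  expect_error(voxel_volume(20, 20, 256, -1, 0.8), "positive")
})

test_that("segment_roi keeps the largest 8-connected in-band component", {
  img <- matrix(0, 10, 10)
  img[2:4, 2:4] <- 60          # 9-pixel block
  m <- segment_roi(img, roi_spec(0, 0, 0, 10, 10, 50, 70))
  expect_identical(sum(m), 9L)

  # two components, 5 and 3 pixels: only the larger survives
  img2 <- matrix(0, 10, 10)
  img2[2, 2:6] <- 60           # 5 pixels
  img2[8, 2:4] <- 60           # 3 pixels
  m2 <- segment_roi(img2, roi_spec(0, 0, 0, 10, 10, 50, 70))
  expect_identical(sum(m2), 5L)
  expect_true(all(m2[2, 2:6]))
  expect_false(any(m2[8, ]))

  # diagonal touch joins under 8-connectivity
  img3 <- matrix(0, 6, 6)
  img3[2, 2] <- 60; img3[3, 3] <- 60; img3[5, 5] <- 60
  m3 <- segment_roi(img3, roi_spec(0, 0, 0, 6, 6, 50, 70))
  expect_identical(sum(m3), 2L)

  # empty band: zero pixels plus a warning
  expect_warning(m4 <- segment_roi(img, roi_spec(0, 0, 0, 10, 10, 200, 300)),
                 "no pixels")
  expect_identical(sum(m4), 0L)
})

test_that("the threshold band is closed on both ends and box bounds are half-open", {
  img <- matrix(c(49.999, 50, 60, 70, 70.001, 0), 1, 6)
  m <- segment_roi(img, roi_spec(0, 0, 0, 1, 6, 50, 70))
  expect_identical(as.vector(m), c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  # box (0,0)-(1,3) covers columns 0..2 only
  m2 <- segment_roi(img, roi_spec(0, 0, 0, 1, 3, 50, 70))
  expect_identical(sum(m2), 2L)
})

test_that("segmentation is deterministic and ties break toward the box center", {
  img <- matrix(0, 11, 11)
  img[6, 5:6] <- 60            # 2 pixels near center (col 5.5 vs center 6)
  img[1, 1:2] <- 60            # 2 pixels in the corner
  m1 <- segment_roi(img, roi_spec(0, 0, 0, 11, 11, 50, 70))
  m2 <- segment_roi(img, roi_spec(0, 0, 0, 11, 11, 50, 70))
  expect_identical(m1, m2)
  expect_true(all(m1[6, 5:6]))
  expect_false(any(m1[1, ]))
})

test_that("measure_volume sums over slices and deduplicates overlapping ROIs", {
  voxvol <- voxel_volume(20, 20, 256, 256, 0.8)
  blank <- matrix(FALSE, 40, 40)
  m1000 <- blank; m1000[1:25, 1:40] <- TRUE   # 1000 pixels
  vm <- measure_volume(list(m1000), voxvol)
  expect_identical(vm$total_pixels, 1000L)
  expect_identical(vm$volume_mm3, 1000 * voxvol)
  expect_equal(vm$volume_mm3, 4.8828125)

  expect_identical(measure_volume(list(), voxvol)$volume_mm3, 0)

  # ROIs of 10 and 8 pixels sharing 4: union is 14
  a <- blank; a[1, 1:10] <- TRUE
  b <- blank; b[1, 7:14] <- TRUE
  expect_warning(vm2 <- measure_volume(list(list(a, b)), voxvol),
                 "share 4 pixel")
  expect_identical(vm2$total_pixels, 14L)
})

test_that("noiseless phantom volumetry recovers ground truth within boundary error", {
  s <- small_session(week = 6)
  sp <- s$spec
  voxvol <- voxel_volume(sp$fov[1], sp$fov[2], sp$matrix_size[1],
                         sp$matrix_size[2], sp$slice_thickness)
  avg <- compute_t2_average(s$stack)
  bands <- default_bands(sp)
  rois <- auto_tumor_rois(avg$pixels, bands$t2_average[1], bands$t2_average[2])
  vm <- measure_image_volume(avg$pixels, rois, voxvol, method = "t2_average")
  truth <- s$label_map$ground_truth_tumor_volume
  # boundary voxels: tumor voxels 8-adjacent (in-plane) to a non-tumor voxel
  lab <- s$label_map$labels
  n_boundary <- 0L
  for (sl in seq_len(dim(lab)[3])) {
    tum <- lab[, , sl] == 3
    if (!any(tum)) next
    inner <- tum
    nr <- nrow(tum); nc <- ncol(tum)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      shifted <- matrix(FALSE, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      shifted[rs, cs] <- tum[rs - dr, cs - dc]
      inner <- inner & shifted
    }
    n_boundary <- n_boundary + sum(tum & !inner)
  }
  expect_lte(abs(vm$volume_mm3 - truth), max(n_boundary, 1L) * voxvol)
  # in fact the noiseless band segmentation is pixel-exact here
  expect_identical(vm$total_pixels,
                   as.integer(sum(s$label_map$labels == 3)))
})

test_that("widening a nested band never shrinks the measured volume", {
  s <- small_session(week = 5)
  sp <- s$spec
  voxvol <- voxel_volume(sp$fov[1], sp$fov[2], sp$matrix_size[1],
                         sp$matrix_size[2], sp$slice_thickness)
  avg <- compute_t2_average(s$stack)$pixels
  tumor_val <- 100 * mean(exp(-c(45.8, 62.5, 79.2) / 68))
  widths <- c(0.5, 1, 2, 4, 8)
  vols <- vapply(widths, function(h) {
    rois <- auto_tumor_rois(avg, tumor_val - h, tumor_val + h)
    measure_image_volume(avg, rois, voxvol)$volume_mm3
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})
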