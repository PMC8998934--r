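#' Voxel volume from acquisition geometry
#'
#' In-plane pixel pitch is FOV divided by matrix size per axis; multiplied by
#' the slice thickness this gives the volume of one voxel.  The default
#' preclinical geometry (20 x 20 mm FOV, 256 x 256 matrix, 0.8 mm slices)
#' yields 0.0048828125 mm3, commonly quoted as 0.0048 mm3/voxel after
#' truncation to four decimals (see [format_voxel_volume()]).  All package
#' computations use the full-precision value.
#'
#' @param fov_x_mm,fov_y_mm field of view per axis, mm.
#' @param nx,ny matrix size per axis, pixels.
#' @param slice_thickness_mm slice thickness, mm.
#' @return voxel volume in mm3, full precision.
#' @examples
#' voxel_volume(20, 20, 256, 256, 0.8)              # 0.0048828125
#' format_voxel_volume(voxel_volume(20, 20, 256, 256, 0.8))  # "0.0048"
#' @export
voxel_volume <- function(fov_x_mm, fov_y_mm, nx, ny, slice_thickness_mm) {
  args <- c(fov_x_mm, fov_y_mm, nx, ny, slice_thickness_mm)
  if (any(!is.finite(args)) || any(args <= 0))
    stop_t2flux("all geometry arguments must be positive")
  (fov_x_mm / nx) * (fov_y_mm / ny) * slice_thickness_mm
}

#' @rdname voxel_volume
#' @param v voxel volume in mm3.
#' @param digits decimals kept by truncation (default 4).
#' @export
format_voxel_volume <- function(v, digits = 4) {
  formatC(truncate_decimals(v, digits), format = "f", digits = digits)
}

#' Region-of-interest specification for banded thresholding
#'
#' A rectangular box on one slice plus an intensity band.  Coordinates are
#' 0-based `(row, col)` with half-open bounds: the box covers rows
#' `row0 .. row1 - 1` and columns `col0 .. col1 - 1`.  Thresholds are in the
#' units of the image the ROI is applied to: gray intensity for T2-average
#' images, ms for T2 maps.  The band is closed on both ends.
#'
#' @param slice_index 0-based slice index.
#' @param row0,col0,row1,col1 half-open bounding box, 0-based.
#' @param lower_threshold,upper_threshold band limits, `lower < upper`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(slice_index, row0, col0, row1, col1,
                     lower_threshold, upper_threshold) {
  if (slice_index < 0) stop_t2flux("slice_index must be >= 0")
  if (row0 < 0 || col0 < 0 || row1 <= row0 || col1 <= col0)
    stop_t2flux("bounding box must be non-empty with row1 > row0, col1 > col0")
  if (!(lower_threshold < upper_threshold))
    stop_t2flux("lower_threshold must be strictly below upper_threshold")
  structure(list(slice_index = as.integer(slice_index),
                 row0 = as.integer(row0), col0 = as.integer(col0),
                 row1 = as.integer(row1), col1 = as.integer(col1),
                 lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold),
            class = "roi_spec")
}

# Label connected components of a logical matrix under 8-connectivity
# (edge or corner adjacency).  Two-pass breadth-first flood fill; labels are
# assigned in raster order (column-major as stored), so label order is
# deterministic.  Returns an integer matrix, 0 = background.
label_components8 <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  next_lab <- 0L
  queue <- integer(sum(mask))
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    next_lab <- next_lab + 1L
    lab[start] <- next_lab
    queue[1] <- start; head <- 1L; tail <- 1L
    while (head <= tail) {
      idx <- queue[head]; head <- head + 1L
      r <- ((idx - 1L) %% nr) + 1L
      cl <- ((idx - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- cl + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- next_lab
          tail <- tail + 1L
          queue[tail] <- j
        }
      }
    }
  }
  lab
}

#' Segment one ROI by banded thresholding and largest connected component
#'
#' Inside the ROI's bounding box, pixels with
#' `lower_threshold <= value <= upper_threshold` are binarized; of the
#' resulting 8-connected components only the largest is retained.  Ties for
#' largest are broken by smallest centroid distance to the box center, then
#' by lowest label, so the result is deterministic.  An empty band yields an
#' all-false mask and a warning.
#'
#' @param image_slice 2-D numeric matrix (one slice; gray intensities or ms).
#' @param roi an [roi_spec()] valid for this slice's extent.
#' @return logical matrix of the slice's full extent, `TRUE` on the retained
#'   component.
#' @examples
#' img <- matrix(0, 8, 8); img[3:5, 3:5] <- 60
#' m <- segment_roi(img, roi_spec(0, 0, 0, 8, 8, 50, 70))
#' sum(m)  # 9
#' @export
segment_roi <- function(image_slice, roi) {
  stopifnot(is.matrix(image_slice), inherits(roi, "roi_spec"))
  nr <- nrow(image_slice); nc <- ncol(image_slice)
  if (roi$row1 > nr || roi$col1 > nc)
    stop_t2flux(sprintf("ROI box (%d:%d, %d:%d) exceeds slice extent %d x %d",
                        roi$row0, roi$row1, roi$col0, roi$col1, nr, nc))
  rows <- (roi$row0 + 1L):roi$row1
  cols <- (roi$col0 + 1L):roi$col1
  sub <- image_slice[rows, cols, drop = FALSE]
  band <- !is.na(sub) & sub >= roi$lower_threshold & sub <= roi$upper_threshold
  out <- matrix(FALSE, nr, nc)
  if (!any(band)) {
    warn_t2flux(sprintf(
      "ROI on slice %d: threshold band [%g, %g] selected no pixels",
      roi$slice_index, roi$lower_threshold, roi$upper_threshold))
    return(out)
  }
  lab <- label_components8(band)
  sizes <- tabulate(lab)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: centroid closest to the box center, then lowest label
    ctr <- c((nrow(band) + 1) / 2, (ncol(band) + 1) / 2)
    d2 <- vapply(best, function(l) {
      ij <- which(lab == l, arr.ind = TRUE)
      sum((colMeans(ij) - ctr)^2)
    }, numeric(1))
    best <- best[order(d2, best)][1]
  }
  out[rows, cols] <- lab == best
  out
}

#' Assemble a tumor volume measurement from per-slice ROI masks
#'
#' Retained-component pixel counts are summed per slice over the slice's
#' ROIs and then over all tumor-affected slices; the total is multiplied by
#' the voxel volume.  Pixels covered by overlapping ROIs on one slice are
#' counted once (the masks are unioned) and a warning reports the overlap.
#'
#' @param masks list over slices; each element is a logical mask or a list
#'   of logical masks (one per ROI on that slice), all of one slice extent.
#' @param voxel_volume_mm3 volume per voxel, mm3 (see [voxel_volume()]).
#' @param animal_id,week,method provenance carried into the result.
#' @return An object of class `volume_measurement`: `animal_id`, `week`,
#'   `method`, `total_pixels`, `volume_mm3` (= total pixels x voxel volume,
#'   exact), `roi_pixels` (per-slice counts) and `voxel_volume_mm3`.
#' @export
measure_volume <- function(masks, voxel_volume_mm3,
                           animal_id = NA_character_, week = NA_integer_,
                           method = NA_character_) {
  if (voxel_volume_mm3 <= 0) stop_t2flux("voxel_volume_mm3 must be positive")
  slice_counts <- integer(length(masks))
  for (s in seq_along(masks)) {
    elt <- masks[[s]]
    if (is.null(elt)) next
    if (!is.list(elt)) elt <- list(elt)
    if (!length(elt)) next
    stopifnot(all(vapply(elt, is.logical, logical(1))))
    acc <- elt[[1]]
    n_indiv <- sum(acc)
    if (length(elt) > 1L) for (m in elt[-1]) {
      n_indiv <- n_indiv + sum(m)
      acc <- acc | m
    }
    if (n_indiv > sum(acc))
      warn_t2flux(sprintf(
        "slice %d: overlapping ROIs share %d pixel(s); counted once",
        s, n_indiv - sum(acc)))
    slice_counts[s] <- sum(acc)
  }
  total <- sum(slice_counts)
  structure(list(animal_id = animal_id, week = week, method = method,
                 total_pixels = total,
                 volume_mm3 = total * voxel_volume_mm3,
                 roi_pixels = slice_counts,
                 voxel_volume_mm3 = voxel_volume_mm3),
            class = "volume_measurement")
}

#' @export
print.volume_measurement <- function(x, ...) {
  cat(sprintf("Tumor volume: %.4f mm3 (%d pixels x %.10f mm3/voxel)%s\n",
              x$volume_mm3, x$total_pixels, x$voxel_volume_mm3,
              if (!is.na(x$method)) sprintf(" [%s]", x$method) else ""))
  invisible(x)
}

#' Derive one ROI per tumor-affected slice from an intensity band
#'
#' Convenience for phantom experiments and scripted runs: for every slice
#' with at least one in-band pixel, builds an [roi_spec()] whose box is the
#' padded bounding box of the in-band region.  This replaces the interactive
#' ROI placement of a reader with a declarative rule.
#'
#' @param image 3-D array (row, col, slice): a T2-average image or the
#'   `t2_ms` array of a T2 map (`NA`s are treated as out of band).
#' @param lower_threshold,upper_threshold band in image units.
#' @param pad pixels of padding around the bounding box.
#' @return list of [roi_spec()] objects (possibly empty).
#' @export
auto_tumor_rois <- function(image, lower_threshold, upper_threshold, pad = 2L) {
  stopifnot(length(dim(image)) == 3L, lower_threshold < upper_threshold)
  rois <- list()
  for (s in seq_len(dim(image)[3])) {
    sl <- image[, , s]
    inband <- which(!is.na(sl) & sl >= lower_threshold & sl <= upper_threshold,
                    arr.ind = TRUE)
    if (!nrow(inband)) next
    r0 <- max(min(inband[, 1]) - 1L - pad, 0L)
    c0 <- max(min(inband[, 2]) - 1L - pad, 0L)
    r1 <- min(max(inband[, 1]) + pad, nrow(sl))
    c1 <- min(max(inband[, 2]) + pad, ncol(sl))
    rois[[length(rois) + 1L]] <-
      roi_spec(s - 1L, r0, c0, r1, c1, lower_threshold, upper_threshold)
  }
  rois
}

#' Measure a tumor volume from a 3-D contrast image and a set of ROIs
#'
#' Applies [segment_roi()] to every ROI on its slice and accumulates the
#' result with [measure_volume()].
#'
#' @param image 3-D array (row, col, slice).
#' @param rois list of [roi_spec()] objects.
#' @param voxel_volume_mm3 volume per voxel, mm3.
#' @inheritParams measure_volume
#' @return A `volume_measurement`.
#' @export
measure_image_volume <- function(image, rois, voxel_volume_mm3,
                                 animal_id = NA_character_,
                                 week = NA_integer_,
                                 method = NA_character_) {
  stopifnot(length(dim(image)) == 3L)
  n_slices <- dim(image)[3]
  masks <- rep(list(list()), n_slices)
  for (roi in rois) {
    s <- roi$slice_index + 1L
    if (s > n_slices) stop_t2flux("ROI slice_index beyond image extent")
    masks[[s]] <- c(masks[[s]], list(segment_roi(image[, , s], roi)))
  }
  measure_volume(masks, voxel_volume_mm3, animal_id, week, method)
}
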