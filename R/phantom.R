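#' Digital-phantom specification
#'
#' Describes the acquisition geometry, tissue parameters and tumor growth
#' model of a synthetic multi-echo MRI cohort of an orthotopic brain tumor.
#' Defaults reproduce a typical preclinical 7 T protocol: a 20 x 20 mm field
#' of view mapped in a 256 x 256 matrix, 20 gap-free slices of 0.8 mm, and a
#' 10-echo train from 12.5 to 162.5 ms (two proton-density-weighted plus
#' eight T2-weighted echoes, spacing 16.67 ms).  Default tissue T2 values are
#' 47 ms for healthy brain, 68 ms for tumor and 125 ms for cerebrospinal
#' fluid; tumor volume grows exponentially from `v0_mm3` at week 1, with the
#' default rate anchored so that week-8 volume is 38 mm3.
#'
#' @param matrix_size integer vector of 2, in-plane pixels per axis.
#' @param n_slices number of slices.
#' @param fov field of view in mm per in-plane axis (length 2).
#' @param slice_thickness slice thickness in mm.
#' @param te_list echo times in ms, strictly increasing.
#' @param tissue_params named list mapping tissue class (`background`,
#'   `brain`, `csf`, `tumor`) to a list with elements `s0` (signal amplitude,
#'   arbitrary units) and `t2` (relaxation time, ms).
#' @param v0_mm3 tumor volume at week 1, mm3.
#' @param growth_rate exponential growth rate per week; tumor volume at week
#'   w is `v0_mm3 * exp(growth_rate * (w - 1))`.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (same arbitrary units as `s0`).
#' @param seed default integer seed for operations that accept one.
#'
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(matrix_size = c(64, 64), n_slices = 8)
#' spec$tissue_params$tumor$t2
#' @export
phantom_spec <- function(matrix_size = c(256L, 256L),
                         n_slices = 20L,
                         fov = c(20, 20),
                         slice_thickness = 0.8,
                         te_list = c(12.5, 29.2, 45.8, 62.5, 79.2,
                                     95.8, 112.5, 129.2, 145.8, 162.5),
                         tissue_params = list(
                           background = list(s0 = 0,   t2 = 1),
                           brain      = list(s0 = 100, t2 = 47),
                           csf        = list(s0 = 100, t2 = 125),
                           tumor      = list(s0 = 100, t2 = 68)),
                         v0_mm3 = 0.5,
                         growth_rate = log(38 / 0.5) / 7,
                         noise_sd = 0,
                         seed = 1L) {
  matrix_size <- as.integer(rep_len(matrix_size, 2L))
  fov <- rep_len(as.numeric(fov), 2L)
  if (any(matrix_size < 8L)) stop_t2flux("matrix_size must be at least 8 pixels per axis")
  if (n_slices < 1L) stop_t2flux("n_slices must be >= 1")
  if (any(fov <= 0) || slice_thickness <= 0)
    stop_t2flux("fov and slice_thickness must be positive")
  if (length(te_list) < 3L || any(te_list <= 0) || any(diff(te_list) <= 0))
    stop_t2flux("te_list must be >= 3 strictly increasing positive echo times")
  stopifnot(is.list(tissue_params), length(tissue_params) > 0)
  for (cls in names(tissue_params)) {
    p <- tissue_params[[cls]]
    if (!is.list(p) || is.null(p$s0) || is.null(p$t2))
      stop_t2flux("tissue_params$", cls, " must have elements s0 and t2")
    if (p$t2 <= 0) stop_t2flux("tissue_params$", cls, ": T2 must be > 0")
  }
  if (noise_sd < 0) stop_t2flux("noise_sd must be >= 0")
  if (v0_mm3 <= 0) stop_t2flux("v0_mm3 must be > 0")
  structure(list(
    matrix_size = matrix_size, n_slices = as.integer(n_slices),
    fov = fov, slice_thickness = slice_thickness,
    te_list = as.numeric(te_list), tissue_params = tissue_params,
    v0_mm3 = v0_mm3, growth_rate = growth_rate,
    noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Digital phantom specification\n")
  cat(sprintf("  matrix %d x %d, %d slices, FOV %g x %g mm, slice %g mm\n",
              x$matrix_size[1], x$matrix_size[2], x$n_slices,
              x$fov[1], x$fov[2], x$slice_thickness))
  cat(sprintf("  %d echoes: %s ms\n", length(x$te_list),
              paste(x$te_list, collapse = ", ")))
  for (cls in names(x$tissue_params))
    cat(sprintf("  %-10s S0 = %g, T2 = %g ms\n", cls,
                x$tissue_params[[cls]]$s0, x$tissue_params[[cls]]$t2))
  cat(sprintf("  tumor growth: V(w) = %g * exp(%.4f * (w - 1)) mm3; noise SD %g\n",
              x$v0_mm3, x$growth_rate, x$noise_sd))
  invisible(x)
}

# Tissue label codes used in label maps.
.tissue_codes <- c(background = 0L, brain = 1L, csf = 2L, tumor = 3L)

# Physical voxel-center coordinates (mm) for a spec, origin at FOV center.
.voxel_grid <- function(spec) {
  dx <- spec$fov[1] / spec$matrix_size[1]
  dy <- spec$fov[2] / spec$matrix_size[2]
  dz <- spec$slice_thickness
  list(
    x = (seq_len(spec$matrix_size[1]) - 0.5) * dx - spec$fov[1] / 2,
    y = (seq_len(spec$matrix_size[2]) - 0.5) * dy - spec$fov[2] / 2,
    z = (seq_len(spec$n_slices) - 0.5) * dz - spec$n_slices * dz / 2,
    dx = dx, dy = dy, dz = dz)
}

#' Tumor volume implied by the growth model at a given week
#'
#' @param spec a [phantom_spec()].
#' @param week session week (>= 1).
#' @return volume in mm3.
#' @export
tumor_volume_at_week <- function(spec, week) {
  stopifnot(inherits(spec, "phantom_spec"), week >= 1)
  spec$v0_mm3 * exp(spec$growth_rate * (week - 1))
}

#' Build the tissue label map for one imaging session
#'
#' Voxels are labelled background, brain (a centered ellipsoid), CSF (two
#' ventricle regions) or tumor.  The tumor occupies exactly
#' `round(V(week) / voxel_volume)` brain voxels nearest its seed point in
#' physical distance, so the recorded ground-truth volume is within half a
#' voxel volume of the growth model's request and is, by construction,
#' exactly the tumor voxel count times the voxel volume.
#'
#' @param spec a [phantom_spec()].
#' @param session_week imaging week, >= 1.
#' @return An object of class `label_map` with elements `labels` (integer
#'   array, row x col x slice; codes 0 background, 1 brain, 2 CSF, 3 tumor),
#'   `classes`, `session_week`, `ground_truth_tumor_volume` (mm3) and
#'   `voxel_volume_mm3`.
#' @examples
#' lm1 <- build_label_map(phantom_spec(matrix_size = c(64, 64), n_slices = 8), 1)
#' lm1$ground_truth_tumor_volume
#' @export
build_label_map <- function(spec, session_week) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (session_week < 1) stop_t2flux("session_week must be >= 1")
  g <- .voxel_grid(spec)
  nx <- spec$matrix_size[1]; ny <- spec$matrix_size[2]; nz <- spec$n_slices

  labels <- array(.tissue_codes[["background"]], dim = c(nx, ny, nz))
  # brain: centered ellipsoid with semi-axes at 80% of the half-extents
  ax <- 0.40 * spec$fov[1]; ay <- 0.45 * spec$fov[2]
  az <- 0.45 * nz * g$dz
  X <- array(g$x, dim = c(nx, ny, nz))
  Y <- array(rep(g$y, each = nx), dim = c(nx, ny, nz))
  Z <- array(rep(g$z, each = nx * ny), dim = c(nx, ny, nz))
  brain <- (X / ax)^2 + (Y / ay)^2 + (Z / az)^2 <= 1
  labels[brain] <- .tissue_codes[["brain"]]

  # two lateral-ventricle CSF regions: small ellipsoids left/right of midline
  vx <- 0.12 * spec$fov[1]; vy <- 0.20 * spec$fov[2]; vz <- 0.18 * nz * g$dz
  cx <- 0.18 * spec$fov[1]
  for (s in c(-1, 1)) {
    vent <- ((X - s * cx) / vx)^2 + (Y / vy)^2 + (Z / vz)^2 <= 1
    labels[vent & brain] <- .tissue_codes[["csf"]]
  }

  # tumor: nearest-brain-voxel blob around a posterior seed point
  vol_target <- tumor_volume_at_week(spec, session_week)
  voxvol <- g$dx * g$dy * g$dz
  n_target <- max(1L, as.integer(round(vol_target / voxvol)))
  eligible <- which(labels == .tissue_codes[["brain"]])
  if (n_target > length(eligible))
    stop_t2flux(sprintf(
      "tumor volume %.2f mm3 at week %d exceeds available brain volume %.2f mm3",
      vol_target, session_week, length(eligible) * voxvol))
  seed_pt <- c(0, 0.20 * spec$fov[2], 0)
  d2 <- (X[eligible] - seed_pt[1])^2 + (Y[eligible] - seed_pt[2])^2 +
        (Z[eligible] - seed_pt[3])^2
  take <- eligible[order(d2)][seq_len(n_target)]
  labels[take] <- .tissue_codes[["tumor"]]

  structure(list(
    labels = labels, classes = .tissue_codes,
    session_week = as.integer(session_week),
    ground_truth_tumor_volume = n_target * voxvol,
    voxel_volume_mm3 = voxvol,
    geometry = list(matrix_size = spec$matrix_size, n_slices = nz,
                    fov = spec$fov, slice_thickness = spec$slice_thickness)),
    class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$classes, labels = names(x$classes)))
  cat(sprintf("Tissue label map, week %d: %s\n", x$session_week,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  ground-truth tumor volume %.4f mm3 (voxel %.10f mm3)\n",
              x$ground_truth_tumor_volume, x$voxel_volume_mm3))
  invisible(x)
}

#' Render a multi-echo image stack from a label map
#'
#' Forward simulation of the mono-exponential spin-echo signal: each voxel of
#' tissue class c takes intensity `S0(c) * exp(-TE / T2(c))` at every echo
#' time, plus additive Gaussian noise of standard deviation `spec$noise_sd`
#' (a high-SNR approximation to Rician magnitude noise).
#'
#' @param label_map a [build_label_map()] result.
#' @param spec the [phantom_spec()] providing tissue parameters, echo times
#'   and noise level.
#' @param seed integer seed; the rendering is bit-reproducible given the seed.
#' @return An [echo_stack()] object.
#' @examples
#' sp <- phantom_spec(matrix_size = c(32, 32), n_slices = 4)
#' st <- render_echo_stack(build_label_map(sp, 1), sp, seed = 7)
#' dim(st$intensities)
#' @export
render_echo_stack <- function(label_map, spec, seed = spec$seed) {
  stopifnot(inherits(label_map, "label_map"), inherits(spec, "phantom_spec"))
  present <- sort(unique(as.vector(label_map$labels)))
  known <- .tissue_codes[names(spec$tissue_params)]
  if (!all(present %in% known))
    stop_t2flux("label map contains classes without tissue_params")
  dims <- dim(label_map$labels)
  n_echo <- length(spec$te_list)
  s0_lut <- t2_lut <- numeric(max(known) + 1L)
  for (cls in names(spec$tissue_params)) {
    code <- .tissue_codes[[cls]]
    s0_lut[code + 1L] <- spec$tissue_params[[cls]]$s0
    t2_lut[code + 1L] <- spec$tissue_params[[cls]]$t2
  }
  s0_vox <- s0_lut[label_map$labels + 1L]
  t2_vox <- t2_lut[label_map$labels + 1L]
  intens <- array(0, dim = c(dims, n_echo))
  for (e in seq_len(n_echo))
    intens[, , , e] <- s0_vox * exp(-spec$te_list[e] / t2_vox)
  if (spec$noise_sd > 0)
    intens <- intens + with_seed(seed,
      array(stats::rnorm(length(intens), 0, spec$noise_sd), dim = dim(intens)))
  echo_stack(intens, spec$te_list,
             fov = spec$fov, slice_thickness = spec$slice_thickness)
}

#' Simulate bioluminescence total flux from tumor volume
#'
#' Draws total flux (photons/s) from the power law `flux = a * V^b` with
#' log-normal scatter: `log10(flux) = log10_intercept + slope * log10(V) + e`,
#' `e ~ Normal(0, log_resid_sd)`.  Default coefficients are the calibration
#' `log10(flux) = 5.81 + 1.04 * log10(V)`.
#'
#' @param volume_mm3 tumor volume(s), mm3, all > 0.
#' @param log10_intercept intercept on the log10 scale (log10 of flux at
#'   1 mm3).
#' @param slope power-law exponent.
#' @param log_resid_sd standard deviation of the log10 residual (>= 0).
#' @param seed integer seed.
#' @return numeric vector of fluxes in photons/s.
#' @examples
#' simulate_flux(10, seed = 1)            # about 7.1e6 p/s
#' simulate_flux(1, log_resid_sd = 0, seed = 1)  # exactly 10^5.81
#' @export
simulate_flux <- function(volume_mm3, log10_intercept = 5.81, slope = 1.04,
                          log_resid_sd = 0.05, seed = 1L) {
  if (any(!is.finite(volume_mm3)) || any(volume_mm3 <= 0))
    stop_t2flux("volume_mm3 must be positive and finite")
  if (log_resid_sd < 0) stop_t2flux("log_resid_sd must be >= 0")
  eps <- if (log_resid_sd > 0)
    with_seed(seed, stats::rnorm(length(volume_mm3), 0, log_resid_sd))
  else rep(0, length(volume_mm3))
  10^(log10_intercept + slope * log10(volume_mm3) + eps)
}

#' Simulate a survival cohort with known group medians
#'
#' Times to endpoint are drawn from a log-logistic distribution whose median
#' equals the requested group median (sampled as
#' `exp(rlogis(n, log(median), 1/shape))`, an exact inverse-CDF identity).
#' Animals surviving past `censor_day` are censored there, mirroring
#' symptom-free long-term survivors euthanized at a fixed study end.
#'
#' @param group_medians named numeric vector, group label -> median survival
#'   in days (> 0).
#' @param n_per_group animals per group (>= 2).
#' @param censor_day administrative censoring day (default 139).
#' @param shape log-logistic shape parameter; larger is tighter around the
#'   median (default 6).
#' @param seed integer seed.
#' @return data.frame with columns `animal_id`, `group`, `day`, `event`
#'   (1 = endpoint reached, 0 = censored), one row per animal.
#' @examples
#' tab <- simulate_survival_cohort(c(sham = 44, treated = 66), 8, seed = 1)
#' table(tab$group, tab$event)
#' @export
simulate_survival_cohort <- function(group_medians, n_per_group,
                                     censor_day = 139, shape = 6, seed = 1L) {
  if (is.null(names(group_medians)) || any(!nzchar(names(group_medians))))
    stop_t2flux("group_medians must be a named vector")
  if (any(group_medians <= 0)) stop_t2flux("all group medians must be > 0")
  if (n_per_group < 2) stop_t2flux("n_per_group must be >= 2")
  if (shape <= 0) stop_t2flux("shape must be > 0")
  with_seed(seed, {
    out <- lapply(names(group_medians), function(grp) {
      t_raw <- exp(stats::rlogis(n_per_group,
                                 location = log(group_medians[[grp]]),
                                 scale = 1 / shape))
      event <- as.integer(t_raw <= censor_day)
      data.frame(
        animal_id = sprintf("%s_%02d", grp, seq_len(n_per_group)),
        group = grp,
        day = pmin(t_raw, censor_day),
        event = event,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
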