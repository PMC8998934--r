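#' Write a multi-echo stack as NIfTI plus JSON sidecar
#'
#' The 4-D intensity array goes to `<prefix>.nii` (4th dimension = echo);
#' acquisition metadata that NIfTI does not carry (the echo-time list) goes
#' to `<prefix>.json` as `{te_ms, fov_mm, slice_thickness_mm}`.
#'
#' @param stack an [echo_stack()].
#' @param prefix output path without extension.
#' @return the two paths written, invisibly.
#' @export
write_echo_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "echo_stack"))
  nii <- paste0(prefix, ".nii")
  js <- paste0(prefix, ".json")
  d <- dim(stack$intensities)
  pix <- c(stack$geometry$fov / d[1:2], stack$geometry$slice_thickness)
  img <- RNifti::asNifti(stack$intensities, pixdim = pix)
  RNifti::writeNifti(img, nii)
  jsonlite::write_json(list(te_ms = stack$te_ms,
                            fov_mm = stack$geometry$fov,
                            slice_thickness_mm = stack$geometry$slice_thickness),
                       js, auto_unbox = FALSE, digits = NA)
  invisible(c(nii, js))
}

#' Read a multi-echo stack written by [write_echo_stack()]
#'
#' @param prefix path without extension (expects `<prefix>.nii` and
#'   `<prefix>.json`).
#' @return an [echo_stack()].
#' @export
read_echo_stack <- function(prefix) {
  nii <- paste0(prefix, ".nii")
  js <- paste0(prefix, ".json")
  if (!file.exists(nii)) stop_t2flux("missing image file: ", nii)
  if (!file.exists(js)) stop_t2flux("missing JSON sidecar: ", js)
  arr <- .plain_array(RNifti::readNifti(nii))
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (length(dim(arr)) != 4L)
    stop_t2flux(sprintf("expected a 4-D stack, found %d dimension(s)",
                        length(dim(arr))))
  echo_stack(arr, meta$te_ms, fov = meta$fov_mm,
             slice_thickness = meta$slice_thickness_mm)
}

# drop NIfTI header attributes, keeping a plain numeric array
.plain_array <- function(img) {
  array(as.numeric(img), dim = dim(img))
}

#' Validate an on-disk stack against the multi-echo contract
#'
#' Checks that the sidecar's echo count matches the image's 4th dimension,
#' that echo times are strictly increasing, and that all voxels are finite;
#' the first violated invariant is reported by name (with voxel coordinates
#' for non-finite values).
#'
#' @param prefix path without extension.
#' @return the validated [echo_stack()] (errors otherwise).
#' @export
validate_stack <- function(prefix) {
  nii <- paste0(prefix, ".nii")
  js <- paste0(prefix, ".json")
  if (!file.exists(nii)) stop_t2flux("missing image file: ", nii)
  if (!file.exists(js)) stop_t2flux("missing JSON sidecar: ", js)
  arr <- .plain_array(RNifti::readNifti(nii))
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (length(dim(arr)) != 4L)
    stop_t2flux(sprintf("expected a 4-D stack, found %d dimension(s)",
                        length(dim(arr))))
  if (dim(arr)[4] != length(meta$te_ms))
    stop_t2flux(sprintf(
      "echo count mismatch: image has %d echoes, sidecar lists %d echo times",
      dim(arr)[4], length(meta$te_ms)))
  # echo_stack() re-checks monotone TEs and finiteness with coordinates
  echo_stack(arr, meta$te_ms, fov = meta$fov_mm,
             slice_thickness = meta$slice_thickness_mm)
}

#' Write a label map as an integer NIfTI volume
#'
#' @param label_map a [build_label_map()] result.
#' @param path output `.nii` path.
#' @export
write_label_map <- function(label_map, path) {
  stopifnot(inherits(label_map, "label_map"))
  g <- label_map$geometry
  pix <- c(g$fov / g$matrix_size, g$slice_thickness)
  img <- RNifti::asNifti(label_map$labels + 0L, pixdim = pix,
                         datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects everything a full phantom-to-report run needs.  Band thresholds
#' for volumetry are given per contrast method; defaults place the band
#' midway between the tumor class and its neighbors (brain below, CSF
#' above) for the default tissue parameters.
#'
#' @param out_dir output directory (created if absent).
#' @param spec a [phantom_spec()] (cohort geometry, tissue, growth, noise).
#' @param n_animals animals in the imaging cohort.
#' @param weeks imaging weeks (sessions per animal).
#' @param methods contrast methods to run: subset of
#'   `c("t2_average", "t2_map")`.
#' @param bands named list of `c(lower, upper)` per method, in image units
#'   (intensity for `t2_average`, ms for `t2_map`).
#' @param flux list with `log10_intercept`, `slope`, `log_resid_sd` for the
#'   simulated bioluminescence arm.
#' @param correlation_weeks weeks entering the flux-volume calibration.
#' @param survival_medians named vector of group median survival (days).
#' @param control control group label for survival comparisons.
#' @param censor_day administrative censoring day.
#' @param seed master integer seed; all per-session seeds derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       spec = phantom_spec(),
                       n_animals = 4L,
                       weeks = 1:8,
                       methods = c("t2_average", "t2_map"),
                       bands = NULL,
                       flux = list(log10_intercept = 5.81, slope = 1.04,
                                   log_resid_sd = 0.05),
                       correlation_weeks = 1:8,
                       survival_medians = c(sham = 44, treated = 66),
                       control = "sham",
                       censor_day = 139,
                       seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  methods <- match.arg(methods, c("t2_average", "t2_map"), several.ok = TRUE)
  if (is.null(bands)) bands <- default_bands(spec)
  if (!all(methods %in% names(bands)))
    stop_t2flux("bands must be given for every requested method")
  if (!length(correlation_weeks)) stop_t2flux("correlation week range is empty")
  if (!(control %in% names(survival_medians)))
    stop_t2flux("control must be one of the survival groups")
  structure(list(out_dir = out_dir, spec = spec,
                 n_animals = as.integer(n_animals), weeks = as.integer(weeks),
                 methods = methods, bands = bands, flux = flux,
                 correlation_weeks = as.integer(correlation_weeks),
                 survival_medians = survival_medians, control = control,
                 censor_day = censor_day, seed = as.integer(seed)),
            class = "run_config")
}

#' Threshold bands bracketing the tumor class of a phantom
#'
#' For each contrast method, the band runs from midway between the brain
#' and tumor values to midway between the tumor and CSF values, computed
#' from the spec's tissue parameters: T2 times for the `t2_map` method,
#' mean echo intensity over the T2-average echo subset for `t2_average`.
#'
#' @param spec a [phantom_spec()].
#' @param te_subset_ms echoes of the T2-average image.
#' @return named list with `t2_map` and `t2_average` bands `c(lower, upper)`.
#' @export
default_bands <- function(spec, te_subset_ms = c(45.8, 62.5, 79.2)) {
  tp <- spec$tissue_params
  t2s <- vapply(tp[c("brain", "tumor", "csf")], function(p) p$t2, numeric(1))
  avg <- vapply(tp[c("brain", "tumor", "csf")], function(p)
    mean(p$s0 * exp(-te_subset_ms / p$t2)), numeric(1))
  list(t2_map = unname(c(mean(t2s[c("brain", "tumor")]),
                         mean(t2s[c("tumor", "csf")]))),
       t2_average = unname(c(mean(avg[c("brain", "tumor")]),
                             mean(avg[c("tumor", "csf")]))))
}

# derive a per-(animal, week) seed below 2^31 from the master seed
.session_seed <- function(seed, animal, week, salt = 0L) {
  (seed * 7919L + animal * 1009L + week * 101L + salt) %% 2147483647L
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognized top-level keys mirror the [run_config()] arguments; `spec`
#' sub-keys mirror [phantom_spec()] arguments.  Unknown keys are an error
#' (fail-fast before any compute).
#'
#' @param path YAML file.
#' @param out_dir override for the configured output directory.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stop_t2flux("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("out_dir", "spec", "n_animals", "weeks", "methods", "bands",
             "flux", "correlation_weeks", "survival_medians", "control",
             "censor_day", "seed")
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop_t2flux("unknown config key(s): ", paste(extra, collapse = ", "))
  spec <- if (is.null(y$spec)) phantom_spec()
          else do.call(phantom_spec, y$spec)
  args <- y[setdiff(names(y), "spec")]
  args$spec <- spec
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (is.null(args$out_dir)) stop_t2flux("config must set out_dir")
  if (!is.null(args$survival_medians))
    args$survival_medians <- unlist(args$survival_medians)
  if (!is.null(args$bands)) args$bands <- lapply(args$bands, unlist)
  if (!is.null(args$methods)) args$methods <- unlist(args$methods)
  do.call(run_config, args)
}

#' Run the full phantom-to-report pipeline
#'
#' Stages, in order: (1) phantom rendering — one multi-echo stack per
#' (animal, week), written as NIfTI + sidecar and re-validated from disk;
#' (2) relaxometry — T2 map and T2-average image per session; (3) volumetry
#' — banded-threshold segmentation per requested method, volumes appended
#' to `volumes.csv`; (4) method comparison — Bland-Altman between the two
#' methods when both are run; (5) photometry — simulated three-exposure BLI
#' measurements processed to net and week-1-normalized flux (`flux.csv`);
#' (6) calibration — log-log fit of flux on volume over the configured week
#' range (`calibration.json`, `residuals.csv`); (7) survival — simulated
#' cohort, KM summaries and pairwise tests (`survival.csv`,
#' `survival_report.json`).  A fixed seed yields bit-identical outputs; the
#' returned report carries per-stage record counts, collected warnings and
#' MD5 checksums of every file written.
#'
#' @param config a [run_config()].
#' @return the run report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- config$spec
  warnings_log <- character()
  note <- function(w) warnings_log[[length(warnings_log) + 1L]] <<- w

  voxvol <- voxel_volume(spec$fov[1], spec$fov[2],
                         spec$matrix_size[1], spec$matrix_size[2],
                         spec$slice_thickness)
  vol_rows <- list(); truth_rows <- list(); bli_rows <- list()

  for (a in seq_len(config$n_animals)) {
    for (w in config$weeks) {
      lm_ <- build_label_map(spec, w)
      stack <- render_echo_stack(lm_, spec,
                                 seed = .session_seed(config$seed, a, w))
      prefix <- file.path(config$out_dir,
                          sprintf("animal%02d_week%02d", a, w))
      write_echo_stack(stack, prefix)
      stack <- validate_stack(prefix)

      images <- list()
      if ("t2_average" %in% config$methods)
        images$t2_average <- compute_t2_average(stack)$pixels
      if ("t2_map" %in% config$methods)
        images$t2_map <- compute_t2_map(stack)$t2_ms

      for (m in names(images)) {
        band <- config$bands[[m]]
        rois <- auto_tumor_rois(images[[m]], band[1], band[2])
        vm <- withCallingHandlers(
          measure_image_volume(images[[m]], rois, voxvol,
                               animal_id = sprintf("animal%02d", a),
                               week = w, method = m),
          warning = function(cnd) {
            note(conditionMessage(cnd)); invokeRestart("muffleWarning")
          })
        vol_rows[[length(vol_rows) + 1L]] <- data.frame(
          animal_id = vm$animal_id, week = w, method = m,
          pixels = vm$total_pixels, volume_mm3 = vm$volume_mm3,
          stringsAsFactors = FALSE)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        animal_id = sprintf("animal%02d", a), week = w,
        true_volume_mm3 = lm_$ground_truth_tumor_volume,
        stringsAsFactors = FALSE)

      # simulated three-exposure BLI session driven by the true volume
      fl <- config$flux
      sd_bli <- .session_seed(config$seed, a, w, salt = 5000L)
      fluxes <- simulate_flux(rep(lm_$ground_truth_tumor_volume, 3),
                              fl$log10_intercept, fl$slope,
                              fl$log_resid_sd, seed = sd_bli)
      bkg <- with_seed(sd_bli + 1L, stats::runif(3, 50, 200))
      bli_rows[[length(bli_rows) + 1L]] <- data.frame(
        animal_id = sprintf("animal%02d", a), week = w,
        exposure_label = c("60s", "30s", "auto"),
        roi_flux = fluxes + bkg, bkg_flux = bkg,
        stringsAsFactors = FALSE)
    }
  }
  volumes <- do.call(rbind, vol_rows)
  truth <- do.call(rbind, truth_rows)
  bli <- do.call(rbind, bli_rows)
  write.csv(volumes, file.path(config$out_dir, "volumes.csv"),
            row.names = FALSE)
  write.csv(bli, file.path(config$out_dir, "bli.csv"), row.names = FALSE)

  # method comparison
  agreement <- NULL
  if (all(c("t2_average", "t2_map") %in% config$methods)) {
    wide <- merge(
      volumes[volumes$method == "t2_map",
              c("animal_id", "week", "volume_mm3")],
      volumes[volumes$method == "t2_average",
              c("animal_id", "week", "volume_mm3")],
      by = c("animal_id", "week"), suffixes = c("_map", "_avg"))
    ba <- bland_altman(wide$volume_mm3_map, wide$volume_mm3_avg,
                       session_id = paste(wide$animal_id, wide$week))
    agreement <- list(n = ba$n, mean_difference = ba$mean_difference,
                      sd_difference = ba$sd_difference,
                      lower = ba$lower, upper = ba$upper,
                      t = ba$t, df = ba$df, p = ba$p)
    jsonlite::write_json(agreement,
                         file.path(config$out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }

  # photometry
  flux_series <- withCallingHandlers(process_bli(bli), warning = function(cnd) {
    note(conditionMessage(cnd)); invokeRestart("muffleWarning")
  })
  write.csv(flux_series, file.path(config$out_dir, "flux.csv"),
            row.names = FALSE)

  # calibration on the primary method's volumes
  prim <- if ("t2_average" %in% config$methods) "t2_average" else "t2_map"
  cal_in <- merge(
    volumes[volumes$method == prim & volumes$week %in% config$correlation_weeks,
            c("animal_id", "week", "volume_mm3")],
    flux_series[flux_series$week %in% config$correlation_weeks,
                c("animal_id", "week", "net_flux")],
    by = c("animal_id", "week"))
  n_excluded <- sum(volumes$method == prim) - nrow(cal_in)
  if (n_excluded > 0)
    note(sprintf("calibration: %d session(s) outside week range or unmatched",
                 n_excluded))
  usable <- cal_in$volume_mm3 > 0 & cal_in$net_flux > 0
  if (any(!usable))
    note(sprintf("calibration: %d session(s) with empty segmentation excluded",
                 sum(!usable)))
  cal_in <- cal_in[usable, , drop = FALSE]
  fit <- loglog_fit(cal_in$volume_mm3, cal_in$net_flux)
  resid <- flux_residuals(cal_in$net_flux,
                          predict_flux(cal_in$volume_mm3, fit))
  jsonlite::write_json(list(intercept = fit$intercept, slope = fit$slope,
                            a = fit$a, r_squared = fit$r_squared,
                            spearman_rho = fit$spearman_rho,
                            p = fit$p_value, n = fit$n),
                       file.path(config$out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(cbind(cal_in[c("animal_id", "week")], resid),
            file.path(config$out_dir, "residuals.csv"), row.names = FALSE)

  # survival arm
  surv_tab <- simulate_survival_cohort(
    config$survival_medians, n_per_group = max(6L, config$n_animals),
    censor_day = config$censor_day,
    seed = .session_seed(config$seed, 0L, 0L, salt = 9000L))
  write.csv(surv_tab, file.path(config$out_dir, "survival.csv"),
            row.names = FALSE)
  srep <- survival_report(surv_tab, config$control)
  jsonlite::write_json(
    list(control = config$control,
         medians = lapply(srep$groups, function(k) k$median),
         tests = srep$tests),
    file.path(config$out_dir, "survival_report.json"),
    auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  files <- files[!grepl("report\\.json$", files)]
  checksums <- tools::md5sum(files)
  names(checksums) <- basename(names(checksums))
  report <- list(
    counts = list(sessions = config$n_animals * length(config$weeks),
                  volumes = nrow(volumes),
                  flux_timepoints = nrow(flux_series),
                  calibration_pairs = fit$n,
                  survival_records = nrow(surv_tab)),
    agreement = agreement,
    calibration = list(intercept = fit$intercept, slope = fit$slope,
                       r_squared = fit$r_squared),
    survival = list(medians = lapply(srep$groups, function(k) k$median)),
    warnings = warnings_log,
    checksums = as.list(checksums))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
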