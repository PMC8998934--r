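#' Calibrate total flux against tumor volume on the log-log scale
#'
#' Fits ordinary least squares of `log10(flux)` on `log10(volume)`, the
#' linearization of the power law `flux = a * volume^b` (so the intercept is
#' `log10(a)` and the slope is the exponent `b`).  Alongside the fit it
#' reports R-squared, an overall-fit F-test p value (for one predictor,
#' identical to the slope t-test), and Spearman's rank correlation with its
#' two-sided p (midranks for ties).
#'
#' @param volumes tumor volumes, mm3, all > 0, length >= 3.
#' @param fluxes paired total fluxes, photons/s, all > 0.
#' @return An object of class `flux_calibration` with elements `intercept`
#'   (log10 a), `slope` (b), `a` (photons/s at 1 mm3), `r_squared`,
#'   `p_value` (regression F test), `spearman_rho`, `spearman_p`, `n`,
#'   `log10_volume`, `log10_flux` and the underlying `lm` fit.
#' @examples
#' v <- c(1, 5, 20)
#' loglog_fit(v, 10^(5.81 + 1.04 * log10(v)))  # recovers 5.81, 1.04
#' @export
loglog_fit <- function(volumes, fluxes) {
  if (length(volumes) != length(fluxes))
    stop_t2flux("volumes and fluxes must have equal length")
  if (length(volumes) < 3L) stop_t2flux("at least 3 pairs are required")
  bad <- which(!(volumes > 0) | !(fluxes > 0))
  if (length(bad))
    stop_t2flux(sprintf(
      "non-positive value at record %d (volume = %g, flux = %g): %s",
      bad[1], volumes[bad[1]], fluxes[bad[1]],
      "log-log calibration requires positive values"))
  lx <- log10(volumes); ly <- log10(fluxes)
  fit <- stats::lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))  # noiseless data triggers a perfect-fit note
  r2 <- sm$r.squared
  if (is.nan(r2)) r2 <- 0  # constant response: no variance to explain
  p_f <- if (sm$sigma == 0 || is.nan(sm$coefficients[2, 4])) {
    # perfect or degenerate fit: F statistic is not finite
    if (r2 == 1) 0 else NA_real_
  } else sm$coefficients[2, 4]
  sp <- suppressWarnings(
    stats::cor.test(volumes, fluxes, method = "spearman", exact = FALSE))
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    a = 10^unname(stats::coef(fit)[1]),
    r_squared = r2, p_value = p_f,
    spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
    n = length(volumes),
    log10_volume = lx, log10_flux = ly, lm_fit = fit),
    class = "flux_calibration")
}

#' @export
print.flux_calibration <- function(x, ...) {
  cat(sprintf("Flux-volume calibration (n = %d): log10(flux) = %.2f + %.2f * log10(V)\n",
              x$n, x$intercept, x$slope))
  cat(sprintf("  power law: flux = %.3g * V^%.2f p/s\n", x$a, x$slope))
  cat(sprintf("  R^2 = %.3f (F-test p = %.3g); Spearman rho = %.3f (p = %.3g)\n",
              x$r_squared, x$p_value, x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' @export
summary.flux_calibration <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.flux_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.flux_calibration <- function(object, ...) {
  stats::residuals(object$lm_fit)
}

#' Predicted total flux for a tumor volume under a calibration
#'
#' Inverse transform of the log-log fit: `flux = a * volume^b`.
#'
#' @param volume tumor volume(s), mm3, > 0.
#' @param fit a [loglog_fit()] result.
#' @return expected flux, photons/s.
#' @export
predict_flux <- function(volume, fit) {
  stopifnot(inherits(fit, "flux_calibration"))
  if (any(volume <= 0)) stop_t2flux("volume must be > 0")
  fit$a * volume^fit$slope
}

#' @export
predict.flux_calibration <- function(object, volume, ...) {
  predict_flux(volume, object)
}

#' Absolute and relative residuals of observed versus expected flux
#'
#' Absolute residual = observed - expected (photons/s); relative residual =
#' absolute / observed (dimensionless).  A zero observed value leaves the
#' relative residual `NA`.
#'
#' @param observed observed fluxes, photons/s.
#' @param expected paired expected fluxes (e.g. from [predict_flux()]).
#' @return data.frame with columns `observed`, `expected`, `abs_residual`,
#'   `rel_residual`, plus attributes `mean_abs` and `mean_rel` (the summary
#'   lines drawn on residual plots).
#' @examples
#' flux_residuals(200, 150)  # abs 50, rel 0.25
#' @export
flux_residuals <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop_t2flux("observed and expected must have equal length")
  abs_r <- observed - expected
  rel_r <- ifelse(observed != 0, abs_r / observed, NA_real_)
  if (any(observed == 0))
    warn_t2flux("zero observed flux: relative residual undefined there")
  out <- data.frame(observed = observed, expected = expected,
                    abs_residual = abs_r, rel_residual = rel_r)
  attr(out, "mean_abs") <- mean(abs_r)
  attr(out, "mean_rel") <- mean(rel_r, na.rm = TRUE)
  out
}

#' Scatter plot of the calibration with the fitted power law
#'
#' @param x a `flux_calibration`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.flux_calibration <- function(x, ...) {
  graphics::plot(x$log10_volume, x$log10_flux,
                 xlab = "log10 tumor volume (mm3)",
                 ylab = "log10 total flux (p/s)", ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  invisible(x)
}
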