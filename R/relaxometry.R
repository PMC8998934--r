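#' Multi-echo image stack
#'
#' Container for a multi-slice multi-echo MRI acquisition: a 4-D intensity
#' array with axes (row, col, slice, echo) and the echo-time metadata needed
#' for relaxometry.
#'
#' @param intensities 4-D numeric array (row, col, slice, echo); all finite.
#' @param te_ms echo times in ms, one per echo index, strictly increasing.
#' @param fov field of view in mm (length 2).
#' @param slice_thickness slice thickness in mm.
#' @return An object of class `echo_stack`.
#' @export
echo_stack <- function(intensities, te_ms, fov, slice_thickness) {
  if (!is.array(intensities) || length(dim(intensities)) != 4L)
    stop_t2flux("intensities must be a 4-D array (row, col, slice, echo)")
  if (dim(intensities)[4] != length(te_ms))
    stop_t2flux(sprintf("echo dimension (%d) does not match te_ms length (%d)",
                        dim(intensities)[4], length(te_ms)))
  if (any(diff(te_ms) <= 0) || any(te_ms <= 0))
    stop_t2flux("te_ms must be strictly increasing and positive")
  if (!all(is.finite(intensities))) {
    bad <- which(!is.finite(intensities), arr.ind = TRUE)[1, ]
    stop_t2flux(sprintf(
      "non-finite intensity at (row %d, col %d, slice %d, echo %d)",
      bad[1], bad[2], bad[3], bad[4]))
  }
  fov <- rep_len(as.numeric(fov), 2L)
  if (any(fov <= 0) || slice_thickness <= 0)
    stop_t2flux("fov and slice_thickness must be positive")
  structure(list(intensities = intensities, te_ms = as.numeric(te_ms),
                 geometry = list(fov = fov, slice_thickness = slice_thickness)),
            class = "echo_stack")
}

#' @export
print.echo_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("Multi-echo stack: %d x %d x %d slices x %d echoes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  TE = %s ms\n", paste(x$te_ms, collapse = ", ")))
  cat(sprintf("  FOV %g x %g mm, slice %g mm\n",
              x$geometry$fov[1], x$geometry$fov[2], x$geometry$slice_thickness))
  invisible(x)
}

#' Fit the mono-exponential T2 decay for one pixel
#'
#' Estimates `(S0, T2)` minimizing the sum of squared errors of
#' `S(TE) = S0 * exp(-TE / T2)` against the observed echo intensities, by
#' derivative-free Nelder-Mead simplex search initialized from a log-linear
#' regression of `log(S)` on TE over the positive intensities.  Fits whose T2
#' falls outside the validity window, or whose signal is degenerate (all
#' non-positive, or non-decaying), are returned with `defined = FALSE`
#' rather than raising an error, so whole-image mapping never aborts.
#'
#' @param intensities observed intensity at each echo.
#' @param te_ms echo times in ms, strictly increasing, length >= 3.
#' @param t2_window admissible (min, max] T2 range in ms; fits outside are
#'   flagged undefined.  Default (0, 2000].
#' @param reltol relative SSE convergence tolerance of the simplex search.
#' @param maxit iteration cap per pixel.
#' @return list with `s0`, `t2_ms`, `sse` and logical `defined`; `s0` and
#'   `t2_ms` are `NA` when `defined` is `FALSE`.
#' @examples
#' te <- c(12.5, 29.2, 45.8, 62.5, 79.2, 95.8, 112.5, 129.2, 145.8, 162.5)
#' fit_pixel_decay(100 * exp(-te / 68), te)   # recovers S0 = 100, T2 = 68
#' @export
fit_pixel_decay <- function(intensities, te_ms,
                            t2_window = c(0, 2000),
                            reltol = 1e-10, maxit = 10000L) {
  if (length(te_ms) < 3L)
    stop_t2flux("at least 3 echoes are required to fit the decay")
  if (length(intensities) != length(te_ms))
    stop_t2flux("intensities and te_ms must have equal length")
  if (any(diff(te_ms) <= 0)) stop_t2flux("te_ms must be strictly increasing")

  undefined <- list(s0 = NA_real_, t2_ms = NA_real_, sse = NA_real_,
                    defined = FALSE)
  pos <- intensities > 0
  if (sum(pos) < 2L) return(undefined)

  # log-linear initialization: log S = log S0 - TE / T2
  cf <- stats::lm.fit(cbind(1, te_ms[pos]), log(intensities[pos]))$coefficients
  s0_init <- exp(cf[1])
  t2_init <- if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else t2_window[2]
  t2_init <- min(max(t2_init, 1e-3), t2_window[2])

  sse_fn <- function(par) {
    if (par[1] < 0 || par[2] <= 0) return(Inf)
    sum((intensities - par[1] * exp(-te_ms / par[2]))^2)
  }
  opt <- stats::optim(c(s0_init, t2_init), sse_fn, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  s0 <- opt$par[1]; t2 <- opt$par[2]
  if (!is.finite(t2) || t2 <= t2_window[1] || t2 > t2_window[2] ||
      !is.finite(s0) || s0 <= 0)
    return(undefined)
  list(s0 = unname(s0), t2_ms = unname(t2), sse = unname(opt$value),
       defined = TRUE)
}

# Robust per-stack noise-floor estimate from the four corner patches of the
# image (air outside the head): the median, over corner pixels, of each
# pixel's maximum intensity across echoes, times 3.  A tissue pixel's max
# echo intensity must clear this to be fitted.  Returns 0 for a noiseless
# stack.
.noise_floor <- function(stack, patch_frac = 0.1) {
  d <- dim(stack$intensities)
  k1 <- max(2L, floor(d[1] * patch_frac))
  k2 <- max(2L, floor(d[2] * patch_frac))
  rows <- c(seq_len(k1), d[1] - seq_len(k1) + 1L)
  cols <- c(seq_len(k2), d[2] - seq_len(k2) + 1L)
  corners <- stack$intensities[rows, cols, , , drop = FALSE]
  cd <- dim(corners)
  pixmax <- apply(matrix(corners, nrow = prod(cd[1:3])), 1, max)
  3 * stats::median(pixmax)
}

#' Compute a pixel-wise T2 relaxation map
#'
#' Applies [fit_pixel_decay()] to every pixel of the stack (or of the mask),
#' using all echoes, and assembles T2, S0 and SSE images.  Pixels whose
#' maximum echo intensity does not exceed the noise floor (3 x a robust
#' background estimate from the corner patches of the first echo image) are
#' flagged undefined without fitting; per-pixel fit failures likewise become
#' undefined flags, never errors.
#'
#' @param stack an [echo_stack()].
#' @param mask optional logical array (row, col, slice) restricting the fit.
#' @param noise_floor override for the automatic noise-floor estimate (in
#'   intensity units); pixels with max echo intensity `<=` this are skipped.
#' @param display_clamp_ms rendering cap carried in the result (values above
#'   it map to the top color when plotted; stored values are never altered).
#' @param ... passed to [fit_pixel_decay()].
#' @return An object of class `t2_map` with arrays `t2_ms`, `s0`, `sse`
#'   (all `NA` where undefined), logical `defined`, and metadata.
#' @export
compute_t2_map <- function(stack, mask = NULL, noise_floor = NULL,
                           display_clamp_ms = 120, ...) {
  stopifnot(inherits(stack, "echo_stack"))
  d <- dim(stack$intensities)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  if (!identical(dim(mask), d))
    stop_t2flux("mask shape does not match the stack's spatial shape")
  if (is.null(noise_floor)) noise_floor <- .noise_floor(stack)

  n_vox <- prod(d)
  flat <- matrix(stack$intensities, nrow = n_vox)   # voxel x echo
  vmax <- flat[, 1]
  for (e in seq_len(ncol(flat))[-1]) vmax <- pmax(vmax, flat[, e])
  fit_idx <- which(as.vector(mask) & vmax > noise_floor)

  t2 <- s0 <- sse <- rep(NA_real_, n_vox)
  defined <- rep(FALSE, n_vox)
  for (i in fit_idx) {
    f <- fit_pixel_decay(flat[i, ], stack$te_ms, ...)
    if (f$defined) {
      t2[i] <- f$t2_ms; s0[i] <- f$s0; sse[i] <- f$sse
      defined[i] <- TRUE
    }
  }
  structure(list(
    t2_ms = array(t2, d), s0 = array(s0, d), sse = array(sse, d),
    defined = array(defined, d),
    display_clamp_ms = display_clamp_ms,
    noise_floor = noise_floor,
    te_ms = stack$te_ms, geometry = stack$geometry),
    class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  d <- dim(x$t2_ms)
  cat(sprintf("T2 map: %d x %d x %d slices; %d/%d pixels defined\n",
              d[1], d[2], d[3], sum(x$defined), prod(d)))
  if (any(x$defined))
    cat(sprintf("  T2 median %.1f ms (IQR %.1f-%.1f); display clamp %g ms\n",
                stats::median(x$t2_ms[x$defined]),
                stats::quantile(x$t2_ms[x$defined], 0.25),
                stats::quantile(x$t2_ms[x$defined], 0.75),
                x$display_clamp_ms))
  invisible(x)
}

#' @export
summary.t2_map <- function(object, ...) {
  v <- object$t2_ms[object$defined]
  out <- list(n_defined = sum(object$defined),
              n_total = length(object$defined),
              quartiles = if (length(v)) stats::quantile(v, c(.25, .5, .75))
                          else NULL)
  class(out) <- "summary.t2_map"
  out
}

#' @export
print.summary.t2_map <- function(x, ...) {
  cat(sprintf("T2 map summary: %d of %d pixels defined\n",
              x$n_defined, x$n_total))
  if (!is.null(x$quartiles))
    cat(sprintf("  T2 quartiles: %.2f / %.2f / %.2f ms\n",
                x$quartiles[1], x$quartiles[2], x$quartiles[3]))
  invisible(x)
}

#' Plot one slice of a T2 map with the display clamp applied
#'
#' Rendering only: values above `display_clamp_ms` saturate at the top of
#' the color scale; the stored map is untouched.
#'
#' @param x a `t2_map`.
#' @param slice slice index (1-based).
#' @param ... passed to [graphics::image()].
#' @export
plot.t2_map <- function(x, slice = 1L, ...) {
  img <- x$t2_ms[, , slice]
  img[!x$defined[, , slice]] <- 0
  img <- pmin(img, x$display_clamp_ms)
  graphics::image(img, zlim = c(0, x$display_clamp_ms), useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = sprintf("T2 map, slice %d (clamp %g ms)",
                                 slice, x$display_clamp_ms), ...)
  invisible(x)
}

#' Compute a T2-average contrast image
#'
#' Pixel-wise arithmetic mean of the echo images at the requested echo
#' times; by default the three mid-train echoes 45.8, 62.5 and 79.2 ms,
#' chosen to reduce image noise while keeping T2-weighted tumor contrast.
#'
#' @param stack an [echo_stack()].
#' @param te_subset_ms echo times to average; each must be present in the
#'   stack metadata (matched within `tol` ms).
#' @param tol TE matching tolerance in ms.
#' @return An object of class `t2_average`: list with `pixels` (row, col,
#'   slice array), `te_subset_ms`, `window` (display span, `NULL` until set)
#'   and `geometry`.
#' @export
compute_t2_average <- function(stack, te_subset_ms = c(45.8, 62.5, 79.2),
                               tol = 1e-6) {
  stopifnot(inherits(stack, "echo_stack"))
  idx <- vapply(te_subset_ms, function(te) {
    hit <- which(abs(stack$te_ms - te) <= tol)
    if (length(hit) != 1L)
      stop_t2flux(sprintf("echo time %g ms not in stack (available: %s)",
                          te, paste(stack$te_ms, collapse = ", ")))
    hit
  }, integer(1))
  sel <- stack$intensities[, , , idx, drop = FALSE]
  d <- dim(stack$intensities)[1:3]
  avg <- array(rowMeans(matrix(sel, ncol = length(idx))), dim = d)
  structure(list(pixels = avg, te_subset_ms = stack$te_ms[idx],
                 window = NULL, geometry = stack$geometry),
            class = "t2_average")
}

#' @export
print.t2_average <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("T2 average image: %d x %d x %d slices (echoes %s ms)\n",
              d[1], d[2], d[3], paste(x$te_subset_ms, collapse = ", ")))
  invisible(x)
}
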