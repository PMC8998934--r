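#' Paired one-sample t-test on method differences
#'
#' Tests whether the mean of paired differences is zero:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p from the t distribution.  Sample SD uses the `n - 1` divisor.
#'
#' @param differences numeric vector of paired differences, length >= 2.
#' @return list with `t`, `df`, `p`; `t` and `p` are `NA` (with a warning)
#'   when the differences have zero variance.
#' @examples
#' paired_t_test(c(1, 2, 3))  # t = 3.464, df = 2
#' @export
paired_t_test <- function(differences) {
  n <- length(differences)
  if (n < 2L) stop_t2flux("at least 2 paired differences are required")
  s <- stats::sd(differences)
  if (s == 0) {
    warn_t2flux("zero-variance differences: t statistic undefined")
    return(list(t = NA_real_, df = n - 1L, p = NA_real_))
  }
  tval <- mean(differences) / (s / sqrt(n))
  list(t = tval, df = n - 1L,
       p = 2 * stats::pt(-abs(tval), df = n - 1L))
}

#' Bland-Altman agreement analysis between two volumetry methods
#'
#' For paired tumor volumes from the T2-map and T2-average contrast methods,
#' computes per-pair differences (map minus average) and means, the mean
#' difference, its sample SD (divisor `n - 1`), the limits of agreement
#' `mean +/- 1.96 * SD`, and a two-sided paired t-test of zero mean
#' difference.
#'
#' @param volume_map volumes from the T2-map method, mm3.
#' @param volume_average paired volumes from the T2-average method, mm3.
#' @param session_id optional identifiers, carried into the result.
#' @return An object of class `bland_altman` with elements `differences`,
#'   `means`, `mean_difference`, `sd_difference`, `lower`, `upper`, `t`,
#'   `df`, `p`, `n`.
#' @examples
#' ba <- bland_altman(c(10, 14), c(8, 10))
#' c(ba$mean_difference, ba$lower, ba$upper)
#' @export
bland_altman <- function(volume_map, volume_average, session_id = NULL) {
  if (length(volume_map) != length(volume_average))
    stop_t2flux("paired volume vectors must have equal length")
  n <- length(volume_map)
  if (n < 2L) stop_t2flux("at least 2 pairs are required")
  if (any(volume_map < 0) || any(volume_average < 0))
    stop_t2flux("volumes must be >= 0")
  d <- volume_map - volume_average
  m <- (volume_map + volume_average) / 2
  sd_d <- stats::sd(d)
  tt <- if (sd_d == 0) list(t = NA_real_, df = n - 1L, p = NA_real_)
        else paired_t_test(d)
  structure(list(
    differences = d, means = m,
    mean_difference = mean(d), sd_difference = sd_d,
    lower = mean(d) - 1.96 * sd_d, upper = mean(d) + 1.96 * sd_d,
    t = tt$t, df = tt$df, p = tt$p, n = n,
    session_id = session_id),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d pairs)\n", x$n))
  cat(sprintf("  mean difference %.4f, SD %.4f\n",
              x$mean_difference, x$sd_difference))
  cat(sprintf("  limits of agreement [%.4f, %.4f]\n", x$lower, x$upper))
  if (is.na(x$t))
    cat("  paired t-test: undefined (zero-variance differences)\n")
  else
    cat(sprintf("  paired t-test: t(%d) = %.2f, p = %.2f\n", x$df, x$t, x$p))
  invisible(x)
}

#' Bland-Altman plot: differences against pair means
#'
#' Reference lines mark the mean difference and the limits of agreement.
#'
#' @param x a [bland_altman()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "mean of methods (mm3)",
                 ylab = "T2 map - T2 average (mm3)", ...)
  graphics::abline(h = c(x$mean_difference, x$lower, x$upper),
                   lty = c(1, 2, 2), col = c("black", "red", "red"))
  invisible(x)
}
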