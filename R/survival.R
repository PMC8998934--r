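#' Kaplan-Meier summary for one group
#'
#' Product-limit estimate of the survival function under right-censoring
#' (via [survival::survfit()]), with the median defined as the first time at
#' which the estimated survival fraction falls to 0.5 or below — the "half
#' the mice still alive" convention.  If the curve never reaches 0.5 the
#' median is `NA`.  The plain sample median of event times is reported as a
#' secondary summary.
#'
#' @param time times to endpoint or censoring, days, > 0 (or >= 0 for
#'   administratively censored-at-entry records).
#' @param event 1/TRUE if the endpoint was reached, 0/FALSE if censored.
#' @param group optional group label carried into the result.
#' @return An object of class `km_summary`: `group`, `n`, `n_events`,
#'   `time` and `surv` (the step function), `median` (KM median, days),
#'   `sample_median_events` (median of uncensored times).
#' @examples
#' km_curve(c(10, 20, 30), c(1, 1, 1))$median  # 20
#' @export
km_curve <- function(time, event, group = NA_character_) {
  if (!length(time)) stop_t2flux("at least one record is required")
  if (length(time) != length(event))
    stop_t2flux("time and event must have equal length")
  event <- as.integer(as.logical(event))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- km_median(sf$time, sf$surv)
  structure(list(group = group, n = length(time), n_events = sum(event),
                 time = sf$time, surv = sf$surv, median = med,
                 sample_median_events =
                   if (any(event == 1L)) stats::median(time[event == 1L])
                   else NA_real_),
            class = "km_summary")
}

# First time at which the survival step function is <= 0.5; NA if never.
km_median <- function(time, surv) {
  hit <- which(surv <= 0.5)
  if (!length(hit)) NA_real_ else time[hit[1]]
}

#' @export
print.km_summary <- function(x, ...) {
  cat(sprintf("Kaplan-Meier%s: n = %d, events = %d, median survival = %s d\n",
              if (!is.na(x$group)) sprintf(" [%s]", x$group) else "",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Plot a Kaplan-Meier step curve
#'
#' @param x a `km_summary`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.km_summary <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = "days", ylab = "survival fraction", ylim = c(0, 1),
                 main = if (!is.na(x$group)) x$group else "Kaplan-Meier", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank comparison of two survival
#' curves (via [survival::survdiff()]).  If either group has no events the
#' statistic is undefined and `NA` is returned with a warning.
#'
#' @param time_a,event_a times and event flags of group A.
#' @param time_b,event_b times and event flags of group B.
#' @return list with `chisq`, `df` (= 1) and two-sided `p`.
#' @export
logrank <- function(time_a, event_a, time_b, event_b) {
  event_a <- as.integer(as.logical(event_a))
  event_b <- as.integer(as.logical(event_b))
  if (!length(time_a) || !length(time_b))
    stop_t2flux("both groups need at least one record")
  if (sum(event_a) == 0L || sum(event_b) == 0L) {
    warn_t2flux("log-rank undefined: a group has zero events")
    return(list(chisq = NA_real_, df = 1L, p = NA_real_))
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chisq = unname(sd_$chisq), df = 1L,
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Two-sided Mann-Whitney U test on survival times
#'
#' Exact p by enumeration of rank assignments when the combined sample size
#' is at most 20 and there are no ties; otherwise the normal approximation
#' with tie correction (no continuity correction), matching common
#' statistical-package defaults.  Censoring indicators are ignored, i.e. the
#' test treats the recorded days as observed times.
#'
#' @param times_a,times_b survival times of the two groups, days.
#' @return list with `U` (number of (a, b) pairs with a > b, counting ties
#'   as 1/2 — the Mann-Whitney U of group A), and two-sided `p`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney <- function(times_a, times_b) {
  if (!length(times_a) || !length(times_b))
    stop_t2flux("both groups must be non-empty")
  n <- length(times_a) + length(times_b)
  ties <- anyDuplicated(c(times_a, times_b)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    times_a, times_b, exact = (n <= 20 && !ties), correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Percent enhancement of median survival
#'
#' `100 * (median_treated - median_control) / median_control`, rounded to
#' the nearest integer with halves away from zero.  Undefined (`NA`) medians
#' propagate.
#'
#' @param median_treated,median_control median survival in days, > 0.
#' @return integer percent (possibly negative), or `NA`.
#' @examples
#' percent_enhancement(66, 44)  # 50
#' percent_enhancement(73, 59)  # 24
#' @export
percent_enhancement <- function(median_treated, median_control) {
  if (is.na(median_treated) || is.na(median_control)) return(NA_real_)
  if (median_treated <= 0 || median_control <= 0)
    stop_t2flux("medians must be > 0")
  round_half_away(100 * (median_treated - median_control) / median_control)
}

#' Group-wise survival report with pairwise tests against a control
#'
#' Builds a [km_curve()] per group and, for every non-control group, the
#' log-rank test, the Mann-Whitney test on recorded days, and the percent
#' enhancement of the KM median relative to the control group.
#'
#' @param table data.frame with columns `animal_id`, `group`, `day`, `event`
#'   (as produced by [simulate_survival_cohort()]).
#' @param control control group label, present in `table$group`.
#' @return list with `groups` (named list of `km_summary`) and `tests`
#'   (data.frame: group, n, median, vs-control log-rank chisq and p,
#'   Mann-Whitney U and p, percent enhancement).
#' @export
survival_report <- function(table, control) {
  need <- c("animal_id", "group", "day", "event")
  if (!all(need %in% names(table)))
    stop_t2flux("table must have columns ", paste(need, collapse = ", "))
  if (!(control %in% table$group))
    stop_t2flux(sprintf("control group '%s' not present", control))
  groups <- split(table, table$group)
  kms <- lapply(names(groups), function(g)
    km_curve(groups[[g]]$day, groups[[g]]$event, group = g))
  names(kms) <- names(groups)
  ctrl <- groups[[control]]
  others <- setdiff(names(groups), control)
  tests <- do.call(rbind, lapply(others, function(g) {
    lr <- logrank(groups[[g]]$day, groups[[g]]$event, ctrl$day, ctrl$event)
    mw <- mann_whitney(groups[[g]]$day, ctrl$day)
    data.frame(group = g, n = nrow(groups[[g]]),
               km_median = kms[[g]]$median,
               logrank_chisq = lr$chisq, logrank_p = lr$p,
               mw_U = mw$U, mw_p = mw$p,
               pct_enhancement = percent_enhancement(
                 kms[[g]]$median, kms[[control]]$median),
               stringsAsFactors = FALSE)
  }))
  list(groups = kms, control = control, tests = tests)
}
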