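#' Net bioluminescence flux after background subtraction
#'
#' Subtracts the caudal background region's total flux from the tumor ROI's
#' total flux.  A non-positive difference (background exceeding the ROI,
#' possible at very low tumor burden) is clamped to `floor` photons/s with a
#' warning, so downstream log transforms stay defined.
#'
#' @param roi_flux ROI total flux, photons/s, >= 0.
#' @param bkg_flux background total flux, photons/s, >= 0.
#' @param floor clamp floor in photons/s (default 1).
#' @return net flux in photons/s (vectorized).
#' @examples
#' net_flux(5e6, 1e6)  # 4e6
#' @export
net_flux <- function(roi_flux, bkg_flux, floor = 1) {
  if (any(roi_flux < 0) || any(bkg_flux < 0))
    stop_t2flux("fluxes must be >= 0")
  net <- roi_flux - bkg_flux
  if (any(net < floor)) {
    warn_t2flux(sprintf(
      "%d measurement(s) with background >= ROI flux clamped to %g p/s",
      sum(net < floor), floor))
    net <- pmax(net, floor)
  }
  net
}

#' Best-of-three exposure selection
#'
#' Each imaging timepoint is measured up to three times (60 s, 30 s and auto
#' exposure); total flux in photons/s is exposure-normalized, so the highest
#' net flux of the set is taken as the timepoint's value.
#'
#' @param net_fluxes net fluxes of one timepoint (1 to 3 values), photons/s.
#' @return the maximum, photons/s.
#' @export
best_of_three <- function(net_fluxes) {
  if (!length(net_fluxes)) stop_t2flux("no measurements for this timepoint")
  if (length(net_fluxes) > 3L)
    stop_t2flux("more than 3 measurements for one timepoint")
  max(net_fluxes)
}

#' Normalize a longitudinal flux series to its week-1 value
#'
#' Relative flux at week w is `net(w) / net(1)`; week 1 must be present (no
#' silent re-baselining to the earliest available week).
#'
#' @param net_fluxes per-week net fluxes, photons/s.
#' @param weeks corresponding week numbers.
#' @param animal_id identifier carried into the result.
#' @return An object of class `flux_series`: data.frame with columns
#'   `animal_id`, `week`, `net_flux`, `relative_flux` (week 1 = 1).
#' @examples
#' normalize_series(c(9e4, 2.205e7), weeks = c(1, 8))
#' @export
normalize_series <- function(net_fluxes, weeks, animal_id = NA_character_) {
  if (length(net_fluxes) != length(weeks))
    stop_t2flux("net_fluxes and weeks must have equal length")
  if (anyDuplicated(weeks)) stop_t2flux("duplicate weeks in series")
  i1 <- which(weeks == 1)
  if (!length(i1))
    stop_t2flux("week-1 measurement missing: cannot normalize series")
  base <- net_fluxes[i1]
  if (base <= 1) stop_t2flux("week-1 net flux is at or below the clamp floor")
  out <- data.frame(animal_id = animal_id, week = weeks,
                    net_flux = net_fluxes,
                    relative_flux = net_fluxes / base,
                    stringsAsFactors = FALSE)
  out <- out[order(out$week), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("flux_series", "data.frame")
  out
}

#' Process a raw BLI measurement table into per-week flux series
#'
#' For each (animal, week): subtracts background per measurement
#' ([net_flux()]), keeps the best of the up-to-three exposures
#' ([best_of_three()]), then normalizes each animal's series to week 1
#' ([normalize_series()]).
#'
#' @param measurements data.frame with columns `animal_id`, `week`,
#'   `roi_flux`, `bkg_flux` (and optionally `exposure_label`).
#' @return data.frame with columns `animal_id`, `week`, `net_flux`,
#'   `relative_flux`.
#' @export
process_bli <- function(measurements) {
  need <- c("animal_id", "week", "roi_flux", "bkg_flux")
  if (!all(need %in% names(measurements)))
    stop_t2flux("measurements must have columns ",
                paste(need, collapse = ", "))
  nets <- net_flux(measurements$roi_flux, measurements$bkg_flux)
  key <- interaction(measurements$animal_id, measurements$week, drop = TRUE)
  if (any(tabulate(key) > 3L))
    stop_t2flux("more than 3 measurements for one (animal, week)")
  best <- tapply(nets, key, best_of_three)
  ids <- tapply(as.character(measurements$animal_id), key, `[`, 1L)
  wks <- tapply(measurements$week, key, `[`, 1L)
  per_tp <- data.frame(animal_id = as.character(ids),
                       week = as.numeric(wks),
                       net_flux = as.numeric(best),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(per_tp, per_tp$animal_id), function(a) {
    normalize_series(a$net_flux, a$week, animal_id = a$animal_id[1])
  }))
  rownames(out) <- NULL
  out
}
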