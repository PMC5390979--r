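# Fishing-event detection from GPS tracks and validation of the effort
# surface against observed per-cell fishing frequency. Fishing shows up as
# sustained low-speed runs (gear deployed/retrieved); thresholds are
# heuristics and deliberately visible in every call.

#' Track constructor
#'
#' @param t timestamps (numeric seconds or POSIXct), strictly increasing
#' @param x,y projected coordinates (meters)
#' @param vessel_id single vessel identifier
#' @return a `pfe_track` data.frame (vessel_id, t, x, y)
#' @export
track <- function(t, x, y, vessel_id = "v1") {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (length(t) < 2) stop("a track needs at least 2 points")
  t <- as.numeric(t)
  if (any(diff(t) < 0)) stop("timestamps must be increasing")
  structure(data.frame(vessel_id = vessel_id, t = t,
                       x = as.numeric(x), y = as.numeric(y)),
            class = c("pfe_track", "data.frame"))
}

#' Per-segment speeds of a track
#'
#' @param trk a [track()]
#' @return numeric vector of length n-1: straight-line distance over elapsed
#'   time (m/s) between consecutive fixes
#' @export
compute_speeds <- function(trk) {
  dt <- diff(trk$t)
  if (any(dt == 0)) stop("duplicate timestamps in track")
  sqrt(diff(trk$x)^2 + diff(trk$y)^2) / dt
}

#' Detect fishing events in a track
#'
#' A fishing event is a maximal run of at least `min_points` consecutive
#' segments whose speed does not exceed `speed_max`. The event location is
#' the midpoint between the run's first and last fix. The defaults
#' (1 m/s, about 2 knots, and 3 segments) are heuristics to be tuned per
#' gear type; presets for gillnets and trawlers are in
#' [fishing_speed_profile()].
#'
#' @param trk a [track()]
#' @param speed_max maximum speed (m/s, > 0) for a segment to count as fishing
#' @param min_points minimum number of consecutive low-speed segments (>= 2)
#' @return data.frame (possibly 0-row): vessel_id, start (first fix index),
#'   end (last fix index), x, y (event midpoint), n_segments
#' @export
detect_fishing_events <- function(trk, speed_max = 1.0, min_points = 3) {
  if (speed_max <= 0) stop("speed_max must be positive")
  if (min_points < 2) stop("min_points must be >= 2")
  sp <- compute_speeds(trk)
  low <- sp <= speed_max
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_points
  if (!any(keep)) {
    return(data.frame(vessel_id = character(0), start = integer(0),
                      end = integer(0), x = numeric(0), y = numeric(0),
                      n_segments = integer(0)))
  }
  s <- starts[keep]; e <- ends[keep] + 1L  # fix indices bounding the run
  data.frame(vessel_id = trk$vessel_id[1], start = s, end = e,
             x = (trk$x[s] + trk$x[e]) / 2, y = (trk$y[s] + trk$y[e]) / 2,
             n_segments = e - s)
}

#' Speed-threshold presets per gear type
#'
#' @param gear "gillnet" or "trawler"
#' @return list(speed_max, min_points) for [detect_fishing_events()]
#' @export
fishing_speed_profile <- function(gear = c("gillnet", "trawler")) {
  gear <- match.arg(gear)
  switch(gear,
         gillnet = list(speed_max = 1.0, min_points = 3),
         trawler = list(speed_max = 2.0, min_points = 5))
}

#' Count fishing events per grid cell
#'
#' @param events event table(s) from [detect_fishing_events()] (a data.frame
#'   or list of them)
#' @param grid a [build_grid()] result
#' @return [cell_values()] of integer event counts (cells without events are
#'   present with count 0); events outside the grid are dropped with a warning
#' @export
events_per_cell <- function(events, grid) {
  if (is.list(events) && !is.data.frame(events))
    events <- do.call(rbind, events)
  if (nrow(events) == 0)
    return(cell_values(grid$cell_id, rep(0, nrow(grid)), units = "events"))
  idx <- .grid_index(grid, events$x, events$y)
  known <- !is.na(idx$cell_id) & idx$cell_id %in% grid$cell_id
  if (any(!known))
    warning(sum(!known), " event(s) outside the grid dropped")
  counts <- table(factor(idx$cell_id[known], levels = grid$cell_id))
  cell_values(grid$cell_id, as.integer(counts), units = "events")
}

#' Validate the effort surface against observed fishing frequency
#'
#' Ordinary least squares of per-cell fishing frequency on PFE (with
#' intercept) plus a Pearson correlation, mirroring how a track-derived
#' ground truth is compared with the prediction. Cells outside the 95%
#' prediction interval of the fit are flagged as outliers (e.g. cells where
#' fish are cleaned en route to port, mimicking a fishing stop).
#'
#' @param pfe a [compute_pfe()] surface (or any [cell_values()])
#' @param frequency [cell_values()] of per-cell fishing-event counts
#' @param level prediction-interval coverage (default 0.95)
#' @return a `pfe_validation` list: slope, intercept, r2, F, p, pearson_rho,
#'   df (n - 2), n, outlier_cells, fit (the lm object)
#' @export
validate_pfe <- function(pfe, frequency, level = 0.95) {
  d <- .join_cells(frequency, pfe)      # a = frequency, b = pfe
  if (nrow(d) < 3) stop("need at least 3 shared cells")
  if (stats::sd(d$b) == 0) stop("constant PFE: regression undefined")
  fit <- stats::lm(a ~ b, data = d)
  s <- summary(fit)
  # prediction limits evaluated at the observed efforts, by design
  pi_ <- suppressWarnings(
    stats::predict(fit, interval = "prediction", level = level))
  outliers <- d$cell_id[d$a < pi_[, "lwr"] | d$a > pi_[, "upr"]]
  fstat <- s$fstatistic
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = s$r.squared,
    F = unname(fstat[1]),
    p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    pearson_rho = stats::cor(d$b, d$a),
    df = nrow(d) - 2L, n = nrow(d),
    outlier_cells = outliers, fit = fit), class = "pfe_validation")
}

#' @export
print.pfe_validation <- function(x, ...) {
  cat(sprintf("PFE validation: r2 = %.2f, p = %.3g, rho = %.2f, df = %d\n",
              x$r2, x$p, x$pearson_rho, x$df))
  if (length(x$outlier_cells))
    cat("  cells outside the 95% prediction limits:",
        paste(x$outlier_cells, collapse = ", "), "\n")
  invisible(x)
}
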