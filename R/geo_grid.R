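# Area of influence, analysis grid, and assignment of point observations
# to grid cells. All geometry is in projected meters; cell indices are
# 0-based, row-major (row along y, col along x).

#' Coastline constructor
#'
#' A coastline is an ordered polyline of projected coordinates (meters).
#' Geographic input must be projected first with [project_geometry()].
#'
#' @param x,y numeric vectors of projected coordinates in meters, or a
#'   2-column matrix/data.frame passed as `x`
#' @return a `pfe_coastline` (data.frame with columns x, y)
#' @export
coastline <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 2)
    y <- x[, 2]; x <- x[, 1]
  }
  if (length(x) == 0) stop("coastline must be non-empty")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("coastline has non-finite coordinates")
  structure(data.frame(x = as.numeric(x), y = as.numeric(y)),
            class = c("pfe_coastline", "data.frame"))
}

#' Point observations constructor
#'
#' @param x,y projected coordinates (meters)
#' @param value non-negative observation values (persons, boats or tonnes)
#' @param id optional identifiers
#' @param units units tag carried through the pipeline
#' @return a `pfe_points` data.frame
#' @export
point_observations <- function(x, y, value, id = NULL, units = "value") {
  stopifnot(length(x) == length(y), length(x) == length(value))
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite coordinates")
  if (any(!is.finite(value)) || any(value < 0)) stop("values must be finite and >= 0")
  out <- data.frame(x = as.numeric(x), y = as.numeric(y), value = as.numeric(value))
  if (!is.null(id)) out$id <- id
  structure(out, units = units, class = c("pfe_points", "data.frame"))
}

#' Cell-values constructor
#'
#' A sparse mapping from grid cell id to a non-negative scalar.
#'
#' @param cell_id integer cell ids
#' @param value non-negative finite values
#' @param units units tag ("persons", "boats", "tonnes", "PFE", ...)
#' @return a `pfe_cell_values` data.frame with columns cell_id, value
#' @export
cell_values <- function(cell_id, value, units = "value") {
  stopifnot(length(cell_id) == length(value))
  if (anyDuplicated(cell_id)) stop("duplicate cell ids")
  if (any(!is.finite(value)) || any(value < 0)) stop("values must be finite and >= 0")
  structure(data.frame(cell_id = as.integer(cell_id), value = as.numeric(value)),
            units = units, class = c("pfe_cell_values", "data.frame"))
}

#' Build the area of influence by buffering a coastline
#'
#' The area of influence is the region within `distance_km` of the coastline
#' (the mean distance travelled by fishers to their grounds; 75 km here).
#' By default the buffer is two-sided; when a `land` polygon is supplied the
#' land side is excluded, giving a seaward-only buffer.
#'
#' @param coast a [coastline()] in projected meters
#' @param distance_km buffer distance in km (> 0); default 75
#' @param land optional land polygon (2-column matrix, projected meters)
#'   subtracted from the buffer
#' @return a `pfe_aoi` object (coastline, distance, optional land mask,
#'   bounding box of the unclipped buffer)
#' @export
buffer_seaward <- function(coast, distance_km = 75, land = NULL) {
  if (!inherits(coast, "pfe_coastline")) coast <- coastline(coast)
  if (!is.numeric(distance_km) || length(distance_km) != 1 || distance_km <= 0)
    stop("distance_km must be a single positive number")
  if (!is.null(land)) {
    land <- as.matrix(land)
    if (ncol(land) != 2 || nrow(land) < 3) stop("land must be a polygon (>= 3 x,y rows)")
  }
  bb <- .bbox_of(as.matrix(coast))
  d <- distance_km * 1000
  structure(list(coastline = coast, seaward_buffer_km = distance_km,
                 land = land,
                 bbox = c(bb[1] - d, bb[2] - d, bb[3] + d, bb[4] + d)),
            class = "pfe_aoi")
}

#' @export
print.pfe_aoi <- function(x, ...) {
  bb <- x$bbox / 1000
  cat("Area of influence: coastline of", nrow(x$coastline), "vertices,",
      x$seaward_buffer_km, "km buffer",
      if (is.null(x$land)) "(two-sided)" else "(land-masked)", "\n")
  cat(sprintf("  bbox %.1f x %.1f km\n", bb[3] - bb[1], bb[4] - bb[2]))
  invisible(x)
}

#' Membership test for the area of influence
#'
#' @param aoi a `pfe_aoi`
#' @param x,y projected coordinates (meters)
#' @return logical vector: within the buffer distance of the coastline and
#'   (if a land mask is present) not on land
#' @export
aoi_contains <- function(aoi, x, y) {
  d <- .polyline_dist(x, y, as.matrix(aoi$coastline))
  ok <- d <= aoi$seaward_buffer_km * 1000
  if (!is.null(aoi$land) && any(ok))
    ok[ok] <- !.in_polygon(x[ok], y[ok], aoi$land)
  ok
}

#' Area of the area-of-influence polygon
#'
#' Computed by counting pixel centers inside the region on a regular lattice;
#' the discretization error shrinks with `res_km`.
#'
#' @param aoi a `pfe_aoi`
#' @param res_km lattice resolution in km (default 1)
#' @return area in km2
#' @export
aoi_area <- function(aoi, res_km = 1) {
  bb <- aoi$bbox
  res <- res_km * 1000
  xs <- seq(bb[1] + res / 2, bb[3], by = res)
  ys <- seq(bb[2] + res / 2, bb[4], by = res)
  total <- 0
  # row-banded to bound memory on large extents
  for (yy in ys) {
    total <- total + sum(aoi_contains(aoi, xs, rep(yy, length(xs))))
  }
  total * res_km^2
}

#' Select communities within an inland buffer of the coastline
#'
#' Keeps the communities likely tied to the local fishing industry: those
#' within `inland_km` of the coast (closed boundary: exactly `inland_km`
#' away is retained).
#'
#' @param communities a [point_observations()] of community populations
#' @param coast a [coastline()]
#' @param inland_km buffer distance in km, default 5
#' @return the retained subset of `communities`
#' @export
select_coastal_communities <- function(communities, coast, inland_km = 5) {
  if (!inherits(coast, "pfe_coastline")) coast <- coastline(coast)
  d <- .polyline_dist(communities$x, communities$y, as.matrix(coast))
  keep <- d <= inland_km * 1000
  out <- communities[keep, , drop = FALSE]
  attr(out, "units") <- attr(communities, "units")
  class(out) <- class(communities)
  out
}

#' Build the analysis grid over the area of influence
#'
#' Lays an axis-aligned grid of square cells of area `cell_area_km2`
#' (default 500), anchored at the minimum corner of the area-of-influence
#' bounding box, and keeps only cells intersecting the area of influence.
#' Intersection with the buffer is an exact rectangle-to-polyline distance
#' test; a land mask, when present, is applied through a lattice of sample
#' points per cell.
#'
#' @param aoi a `pfe_aoi`
#' @param cell_area_km2 cell area in km2 (> 0); default 500
#' @param land_samples per-axis count of sample points used for the land
#'   mask test (only when the aoi carries a land polygon)
#' @return a `pfe_grid`: data.frame of cells (cell_id, row, col, bounds,
#'   centroid) with grid metadata in attributes
#' @export
build_grid <- function(aoi, cell_area_km2 = 500, land_samples = 7) {
  if (!inherits(aoi, "pfe_aoi")) stop("aoi must come from buffer_seaward()")
  if (!is.numeric(cell_area_km2) || cell_area_km2 <= 0)
    stop("cell_area_km2 must be positive")
  side <- sqrt(cell_area_km2) * 1000
  bb <- aoi$bbox
  ncol_ <- max(1L, as.integer(ceiling((bb[3] - bb[1]) / side)))
  nrow_ <- max(1L, as.integer(ceiling((bb[4] - bb[2]) / side)))
  coast <- as.matrix(aoi$coastline)
  dmax <- aoi$seaward_buffer_km * 1000

  # vectorized prefilter on centroid distance: a cell certainly intersects
  # the buffer when its centroid is within dmax - half_diag of the
  # coastline, certainly not when beyond dmax + half_diag; only the
  # boundary-ambiguous band needs the exact rectangle test
  all_rows <- rep(seq_len(nrow_) - 1L, each = ncol_)
  all_cols <- rep(seq_len(ncol_) - 1L, times = nrow_)
  cxs <- bb[1] + all_cols * side + side / 2
  cys <- bb[2] + all_rows * side + side / 2
  cdist <- .polyline_dist(cxs, cys, coast)
  half_diag <- side * sqrt(2) / 2
  status <- ifelse(cdist <= dmax - half_diag, TRUE,
                   ifelse(cdist > dmax + half_diag, FALSE, NA))
  for (k in which(is.na(status))) {
    xmin <- bb[1] + all_cols[k] * side; ymin <- bb[2] + all_rows[k] * side
    status[k] <- .rect_polyline_dist(xmin, ymin, xmin + side, ymin + side,
                                     coast) <= dmax
  }
  if (!is.null(aoi$land)) {
    for (k in which(status)) {
      sx <- seq(bb[1] + all_cols[k] * side, bb[1] + (all_cols[k] + 1) * side,
                length.out = land_samples)
      sy <- seq(bb[2] + all_rows[k] * side, bb[2] + (all_rows[k] + 1) * side,
                length.out = land_samples)
      pts <- expand.grid(x = sx, y = sy)
      if (!any(aoi_contains(aoi, pts$x, pts$y))) status[k] <- FALSE
    }
  }
  rows <- all_rows[status]; cols <- all_cols[status]
  cells <- data.frame(
    cell_id = rows * ncol_ + cols + 1L,
    row = rows, col = cols,
    xmin = bb[1] + cols * side, ymin = bb[2] + rows * side)
  cells$xmax <- cells$xmin + side
  cells$ymax <- cells$ymin + side
  cells$cx <- cells$xmin + side / 2
  cells$cy <- cells$ymin + side / 2
  structure(cells,
            origin = c(bb[1], bb[2]), side_m = side,
            nrow = nrow_, ncol = ncol_, cell_area_km2 = cell_area_km2,
            class = c("pfe_grid", "data.frame"))
}

#' @export
print.pfe_grid <- function(x, ...) {
  cat("Analysis grid:", nrow(x), "cells of", attr(x, "cell_area_km2"),
      "km2 (side", round(attr(x, "side_m") / 1000, 2), "km),",
      attr(x, "nrow"), "x", attr(x, "ncol"), "lattice\n")
  invisible(x)
}

# 0-based (row, col) of points in a grid's lattice; points exactly on a
# shared cell edge go to the lower index; NA outside the lattice extent.
.grid_index <- function(grid, x, y) {
  o <- attr(grid, "origin"); side <- attr(grid, "side_m")
  col <- as.integer(ceiling((x - o[1]) / side) - 1L)
  row <- as.integer(ceiling((y - o[2]) / side) - 1L)
  col[x == o[1]] <- 0L
  row[y == o[2]] <- 0L
  col[col < 0L | col >= attr(grid, "ncol")] <- NA
  row[row < 0L | row >= attr(grid, "nrow")] <- NA
  list(row = row, col = col,
       cell_id = row * attr(grid, "ncol") + col + 1L)
}

#' Assign point observations to grid-cell centroids
#'
#' Sums the values of all points falling in each retained grid cell — the
#' "raw data" stage of the pipeline. Points on a shared cell edge go to the
#' cell with the lower (row, col) index; points outside every retained cell
#' are dropped and reported via attributes.
#'
#' @param points a [point_observations()]
#' @param grid a [build_grid()] result
#' @param complete if TRUE, cells receiving no points are present with
#'   value 0 instead of absent
#' @return [cell_values()] with attributes `dropped_n` and `dropped_value`
#' @export
points_to_cell_centroids <- function(points, grid, complete = FALSE) {
  idx <- .grid_index(grid, points$x, points$y)
  known <- !is.na(idx$cell_id) & idx$cell_id %in% grid$cell_id
  dropped_n <- sum(!known)
  dropped_value <- sum(points$value[!known])
  sums <- tapply(points$value[known], idx$cell_id[known], sum)
  ids <- as.integer(names(sums)); vals <- as.numeric(sums)
  if (complete) {
    miss <- setdiff(grid$cell_id, ids)
    ids <- c(ids, miss); vals <- c(vals, rep(0, length(miss)))
    ord <- order(ids); ids <- ids[ord]; vals <- vals[ord]
  }
  out <- cell_values(ids, vals, units = attr(points, "units"))
  attr(out, "dropped_n") <- dropped_n
  attr(out, "dropped_value") <- dropped_value
  out
}
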