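# Quadratic (Epanechnikov) kernel density surfaces at 1 km2 resolution,
# aggregated to grid-cell means. Two normalizations are available:
#
#  * mass_conserving (default): each point of value u spreads
#    u * (2 / (pi h^2)) * (1 - r^2/h^2) per km2 over the disc r <= h, so the
#    surface integrates back to the input total (boats stay boats);
#  * literal_1d: the 1-D textbook normalization u * (0.75 / h) *
#    (1 - r^2/h^2), proportional to the first on the kernel support.

#' Quadratic (Epanechnikov) kernel shape
#'
#' The unitless kernel weight 0.75 * (1 - (r/h)^2) for r <= h, 0 beyond;
#' maximal (0.75) at the point itself.
#'
#' @param r distance(s) >= 0
#' @param h bandwidth (> 0), same units as `r`
#' @return kernel weights in [0, 0.75]
#' @export
#' @examples
#' kernel_shape(0, 75)      # 0.75
#' kernel_shape(37.5, 75)   # 0.5625
kernel_shape <- function(r, h) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0) stop("h must be positive")
  if (any(r < 0)) stop("r must be >= 0")
  ifelse(r <= h, 0.75 * (1 - (r / h)^2), 0)
}

.kde_coef <- function(mode, h_km) {
  switch(mode,
         mass_conserving = 2 / (pi * h_km^2),
         literal_1d = 0.75 / h_km,
         stop("unknown KDE mode: ", mode))
}

#' Spread point observations into a density raster
#'
#' Every point of value u contributes a radially decreasing quadratic bump
#' of support `h_km` centered at the point; pixel values are sums over
#' points, expressed in input units per km2. The raster covers `extent`
#' padded by one bandwidth so interior kernels are never clipped.
#'
#' @param points a [point_observations()]
#' @param extent a `pfe_aoi`, `pfe_grid`, or numeric `c(xmin, ymin, xmax,
#'   ymax)` in projected meters; must cover all points
#' @param h_km kernel bandwidth (search radius) in km, default 75
#' @param res_km pixel size in km, default 1 (must not exceed `h_km`)
#' @param mode `"mass_conserving"` (default) or `"literal_1d"`
#' @return a `pfe_raster`: list with `origin` (min corner, m), `res_km`,
#'   `nx`, `ny`, `values` (ny x nx matrix, row = y band), `units`,
#'   `n_points`, and `mass_outside_frac` (share of kernel mass beyond the
#'   raster, a boundary-loss diagnostic; mass-conserving mode only)
#' @export
density_surface <- function(points, extent, h_km = 75, res_km = 1,
                            mode = c("mass_conserving", "literal_1d")) {
  mode <- match.arg(mode)
  if (h_km <= 0 || res_km <= 0) stop("h_km and res_km must be positive")
  if (res_km > h_km) stop("res_km must not exceed h_km")
  bb <- if (inherits(extent, "pfe_aoi")) extent$bbox
        else if (inherits(extent, "pfe_grid"))
          c(attr(extent, "origin"),
            attr(extent, "origin") + c(attr(extent, "ncol"), attr(extent, "nrow")) *
              attr(extent, "side_m"))
        else as.numeric(extent)
  if (length(bb) != 4) stop("extent must resolve to c(xmin, ymin, xmax, ymax)")
  h <- h_km * 1000; res <- res_km * 1000
  x0 <- bb[1] - h; y0 <- bb[2] - h
  nx <- as.integer(ceiling((bb[3] + h - x0) / res))
  ny <- as.integer(ceiling((bb[4] + h - y0) / res))
  vals <- matrix(0, nrow = ny, ncol = nx)
  coef <- .kde_coef(mode, h_km)

  if (nrow(points) == 0) {
    warning("no input points: returning an all-zero density surface")
  } else {
    if (any(points$x < bb[1] | points$x > bb[3] |
            points$y < bb[2] | points$y > bb[4]))
      warning("some points fall outside the stated extent")
    xc <- x0 + (seq_len(nx) - 0.5) * res
    yc <- y0 + (seq_len(ny) - 0.5) * res
    for (p in seq_len(nrow(points))) {
      px <- points$x[p]; py <- points$y[p]; u <- points$value[p]
      jr <- which(abs(xc - px) <= h)
      ir <- which(abs(yc - py) <= h)
      if (length(jr) == 0 || length(ir) == 0) next
      r2 <- outer((yc[ir] - py)^2, (xc[jr] - px)^2, "+")
      w <- 1 - r2 / (h * h)
      w[w < 0] <- 0
      vals[ir, jr] <- vals[ir, jr] + u * coef * w
    }
  }
  out <- list(origin = c(x0, y0), res_km = res_km, nx = nx, ny = ny,
              values = vals, units = paste0(attr(points, "units"), " per km2"),
              n_points = nrow(points), mode = mode, h_km = h_km)
  if (mode == "mass_conserving") {
    total_in <- sum(points$value)
    out$mass_outside_frac <-
      if (total_in > 0) max(0, 1 - sum(vals) * res_km^2 / total_in) else 0
  }
  structure(out, class = "pfe_raster")
}

#' @export
print.pfe_raster <- function(x, ...) {
  cat("Density raster:", x$ny, "x", x$nx, "pixels at", x$res_km,
      "km,", x$n_points, "points,", x$mode, "kernel (h =", x$h_km, "km)\n")
  if (!is.null(x$mass_outside_frac))
    cat(sprintf("  kernel mass outside raster: %.2f%%\n", 100 * x$mass_outside_frac))
  invisible(x)
}

#' Aggregate a density raster to grid-cell values
#'
#' Assigns each pixel to the cell containing its center (ties to the lower
#' (row, col) index, matching point assignment) and returns per-cell means
#' of the pixel densities; `output = "cell_total"` rescales the mean density
#' by the cell area, turning densities back into per-cell totals.
#'
#' @param raster a [density_surface()] result
#' @param grid a [build_grid()] result; the raster must cover it
#' @param output `"mean_density"` (input units per km2) or `"cell_total"`
#' @return [cell_values()] over the grid's cells; cells covered by no pixel
#'   center are absent, with a warning
#' @export
aggregate_mean <- function(raster, grid, output = c("mean_density", "cell_total")) {
  output <- match.arg(output)
  res <- raster$res_km * 1000
  xc <- raster$origin[1] + (seq_len(raster$nx) - 0.5) * res
  yc <- raster$origin[2] + (seq_len(raster$ny) - 0.5) * res
  px <- rep(xc, each = raster$ny)
  py <- rep(yc, times = raster$nx)
  idx <- .grid_index(grid, px, py)
  keep <- !is.na(idx$cell_id) & idx$cell_id %in% grid$cell_id
  means <- tapply(as.vector(raster$values)[keep], idx$cell_id[keep], mean)
  ids <- as.integer(names(means)); vals <- as.numeric(means)
  if (length(ids) < nrow(grid))
    warning(nrow(grid) - length(ids), " grid cell(s) covered by no pixel center")
  units <- raster$units
  if (output == "cell_total") {
    vals <- vals * attr(grid, "cell_area_km2")
    units <- sub(" per km2$", "", units)
  }
  cell_values(ids, vals, units = units)
}
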