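# Readers and writers for the pipeline's plain-text formats: CSV point
# tables and cell values, GeoJSON/WKT coastlines, GeoJSON grids, ESRI ASCII
# rasters, CSV/GPX tracks, JSON reports.

#' Read a point-observation table from CSV
#'
#' Accepts either projected columns `x,y` (meters) or geographic `lon,lat`
#' (auto-projected to UTM). A `value` column is required; `id` is optional.
#' Rows with missing coordinates or negative/non-finite values are rejected
#' with their line numbers.
#'
#' @param path CSV file
#' @param projected TRUE when columns are x,y in meters
#' @param zone UTM zone for geographic input (default: auto)
#' @param units units tag for the resulting observations
#' @return a [point_observations()]
#' @export
read_points_csv <- function(path, projected = FALSE, zone = NULL,
                            units = "value") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  if (nrow(d) == 0) stop("empty file: ", path)
  need <- if (projected) c("x", "y", "value") else c("lon", "lat", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  cx <- d[[need[1]]]; cy <- d[[need[2]]]; v <- d$value
  bad <- !is.finite(cx) | !is.finite(cy) | !is.finite(v) | v < 0
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed row(s) in ", path,
            " (lines ", paste(which(bad) + 1, collapse = ", "), ")")
    cx <- cx[!bad]; cy <- cy[!bad]; v <- v[!bad]; d <- d[!bad, , drop = FALSE]
  }
  if (length(v) == 0) stop("no valid rows in ", path)
  if (!projected) {
    pr <- project_geometry(cx, cy, zone = zone)
    cx <- pr$x; cy <- pr$y
  }
  point_observations(cx, cy, v, id = d$id, units = units)
}

#' Write / read cell values as CSV (columns cell_id, value)
#' @param cv a [cell_values()]
#' @param path CSV file
#' @return `read_cell_values_csv` returns a [cell_values()]
#' @export
write_cell_values_csv <- function(cv, path) {
  utils::write.csv(as.data.frame(cv)[, c("cell_id", "value")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_values_csv
#' @param units units tag applied on read
#' @export
read_cell_values_csv <- function(path, units = "value") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  if (!all(c("cell_id", "value") %in% names(d)))
    stop("expected columns cell_id, value in ", path)
  cell_values(d$cell_id, d$value, units = units)
}

#' Read a coastline from GeoJSON or WKT
#'
#' Understands GeoJSON LineString/Polygon geometries (bare, as a Feature or
#' inside a FeatureCollection; polygons contribute their outer ring) and
#' WKT `LINESTRING (...)` / `POLYGON ((...))` text. Geographic coordinates
#' are projected to UTM.
#'
#' @param path file path
#' @param projected TRUE when coordinates are already in meters
#' @param zone UTM zone for geographic input (default: auto)
#' @return a [coastline()] in projected meters
#' @export
read_coastline <- function(path, projected = FALSE, zone = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  coords <- if (grepl("^\\s*\\{", txt)) .coords_from_geojson(txt)
            else .coords_from_wkt(txt)
  if (projected) return(coastline(coords))
  pr <- project_geometry(coords[, 1], coords[, 2], zone = zone)
  coastline(pr$x, pr$y)
}

.coords_from_geojson <- function(txt) {
  g <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  geom <- switch(g$type %||% "",
                 FeatureCollection = g$features[[1]]$geometry,
                 Feature = g$geometry,
                 g)
  coords <- switch(geom$type %||% "",
                   LineString = geom$coordinates,
                   Polygon = geom$coordinates[[1]],
                   stop("unsupported GeoJSON geometry: ", geom$type))
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

.coords_from_wkt <- function(txt) {
  m <- regmatches(txt, regexpr("(?i)(linestring|polygon)\\s*\\(+([^)]*)",
                               txt, perl = TRUE))
  if (length(m) == 0) stop("unrecognized WKT: expected LINESTRING or POLYGON")
  body <- sub("(?i)^(linestring|polygon)\\s*\\(+", "", m, perl = TRUE)
  pairs <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
  do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a grid as GeoJSON polygons
#'
#' One Feature per cell with `cell_id`, `row`, `col` properties, in
#' projected coordinates.
#'
#' @param grid a [build_grid()] result
#' @param path output file
#' @export
write_grid_geojson <- function(grid, path) {
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid[i, ]
    ring <- list(c(r$xmin, r$ymin), c(r$xmax, r$ymin),
                 c(r$xmax, r$ymax), c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    list(type = "Feature",
         properties = list(cell_id = r$cell_id, row = r$row, col = r$col),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a density raster as ESRI ASCII grid
#' @param raster a [density_surface()] result
#' @param path output file (.asc)
#' @export
write_raster_ascii <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cellsize <- raster$res_km * 1000
  writeLines(c(paste("ncols", raster$nx),
               paste("nrows", raster$ny),
               paste("xllcorner", raster$origin[1]),
               paste("yllcorner", raster$origin[2]),
               paste("cellsize", cellsize),
               "NODATA_value -9999"), con)
  # ESRI ASCII rows run north to south
  for (i in rev(seq_len(raster$ny)))
    writeLines(paste(format(raster$values[i, ], trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' @rdname write_raster_ascii
#' @export
read_raster_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  val <- function(k) as.numeric(hdr[[which(vapply(hdr, `[`, "", 1) == k)]][2])
  nx <- as.integer(val("ncols")); ny <- as.integer(val("nrows"))
  m <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE),
              nrow = ny, ncol = nx, byrow = TRUE)
  structure(list(origin = c(val("xllcorner"), val("yllcorner")),
                 res_km = val("cellsize") / 1000, nx = nx, ny = ny,
                 values = m[rev(seq_len(ny)), , drop = FALSE],
                 units = "per km2", n_points = NA_integer_,
                 mode = "unknown", h_km = NA_real_),
            class = "pfe_raster")
}

#' Read vessel tracks from CSV
#'
#' Expects columns `vessel_id`, `timestamp` (ISO-8601 or numeric seconds)
#' and either `x,y` (meters) or `lon,lat`.
#'
#' @param path CSV file
#' @param projected TRUE when columns are x,y in meters
#' @param zone UTM zone for geographic input
#' @return list of [track()] objects, one per vessel
#' @export
read_tracks_csv <- function(path, projected = FALSE, zone = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  need <- c("vessel_id", "timestamp", if (projected) c("x", "y") else c("lon", "lat"))
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tt <- suppressWarnings(as.numeric(d$timestamp))
  if (anyNA(tt)) tt <- as.numeric(as.POSIXct(d$timestamp, tz = "UTC"))
  if (anyNA(tt)) stop("unparseable timestamps")
  if (!projected) {
    pr <- project_geometry(d$lon, d$lat, zone = zone)
    d$x <- pr$x; d$y <- pr$y
  }
  lapply(split(seq_len(nrow(d)), d$vessel_id), function(i) {
    i <- i[order(tt[i])]
    track(tt[i], d$x[i], d$y[i], vessel_id = d$vessel_id[i[1]])
  })
}

#' Read vessel tracks from GPX
#'
#' Each `<trk>` becomes one track; fixes come from `<trkpt>` lat/lon/time.
#'
#' @param path GPX file
#' @param zone UTM zone (default: auto)
#' @return list of [track()] objects
#' @export
read_tracks_gpx <- function(path, zone = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  if (length(trks) == 0) stop("no <trk> elements in ", path)
  out <- lapply(seq_along(trks), function(k) {
    pts <- xml2::xml_find_all(trks[[k]], ".//trkpt")
    lat <- as.numeric(xml2::xml_attr(pts, "lat"))
    lon <- as.numeric(xml2::xml_attr(pts, "lon"))
    tt <- as.numeric(as.POSIXct(xml2::xml_text(xml2::xml_find_all(pts, "time")),
                                format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    name <- xml2::xml_text(xml2::xml_find_first(trks[[k]], "name"))
    if (is.na(name) || name == "") name <- paste0("trk", k)
    pr <- project_geometry(lon, lat, zone = zone)
    track(tt, pr$x, pr$y, vessel_id = name)
  })
  stats::setNames(out, vapply(out, function(t) t$vessel_id[1], ""))
}

#' Write vessel tracks to CSV (projected coordinates)
#' @param tracks list of [track()] objects
#' @param path output file
#' @export
write_tracks_csv <- function(tracks, path) {
  d <- do.call(rbind, lapply(tracks, function(t)
    data.frame(vessel_id = t$vessel_id, timestamp = t$t, x = t$x, y = t$y)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
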