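# The umbrella pipeline: grid -> KDE -> allometry -> PFE -> catch fit ->
# capacity -> (optional) track validation, with every stage's artifacts
# written to an output directory and a single JSON summary.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the study defaults; any
#' default the caller did not set explicitly is recorded in the summary's
#' `defaults_used` field for auditability.
#'
#' @param seaward_buffer_km area-of-influence buffer (default 75)
#' @param inland_buffer_km coastal-community buffer (default 5)
#' @param cell_area_km2 grid cell area (default 500)
#' @param kde_h_km KDE bandwidth (default 75)
#' @param kde_res_km KDE resolution (default 1)
#' @param kde_mode "mass_conserving" or "literal_1d"
#' @param through_origin,offset allometric-fit controls
#' @param fixed_m use this exponent instead of the fitted one (e.g. 0.43)
#' @param n_draws,draw_size catch-fit resampling sizes
#' @param seed root seed for all randomness
#' @param mantel_permutations per-draw Mantel permutations (0 disables)
#' @param speed_max,min_points fishing-event detection thresholds
#' @param observed_fleet observed boats for the capacity report (default:
#'   the summed boat-count input)
#' @return a `pfe_config` list
#' @export
pipeline_config <- function(seaward_buffer_km = 75, inland_buffer_km = 5,
                            cell_area_km2 = 500,
                            kde_h_km = 75, kde_res_km = 1,
                            kde_mode = "mass_conserving",
                            through_origin = TRUE, offset = 1,
                            fixed_m = NULL,
                            n_draws = 500, draw_size = 250, seed = 1,
                            mantel_permutations = 0,
                            speed_max = 1.0, min_points = 3,
                            observed_fleet = NULL) {
  user_set <- names(match.call())[-1]
  cfg <- as.list(environment())
  cfg$user_set <- NULL
  for (nm in names(cfg))
    if (!is.null(cfg[[nm]]) && !is.numeric(cfg[[nm]]) && !is.character(cfg[[nm]]) &&
        !is.logical(cfg[[nm]])) stop("invalid config entry: ", nm)
  num <- vapply(cfg, function(v) is.numeric(v) && length(v) == 1, logical(1))
  bad <- names(cfg)[num & vapply(cfg, function(v) is.numeric(v) && any(v <= 0), logical(1))]
  bad <- setdiff(bad, c("mantel_permutations", "observed_fleet", "seed"))
  if (length(bad)) stop("config values must be positive: ", paste(bad, collapse = ", "))
  structure(c(cfg, list(defaults_used = setdiff(names(cfg), user_set))),
            class = "pfe_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "]: ", conditionMessage(e), call. = FALSE))
}

#' Run the full effort-estimation pipeline
#'
#' Executes, in order: coastal-community selection, area-of-influence
#' buffering, gridding, kernel density surfaces for population and boats
#' (and landings when given), the boats-population allometric fit, the PFE
#' surface, the resampled catch-effort fit with capacity diagnostics, and —
#' when tracks are given — event detection and validation of PFE against
#' per-cell fishing frequency. Deterministic for a fixed config seed.
#'
#' @param coast a [coastline()] (projected)
#' @param communities,boats [point_observations()] (projected)
#' @param landings optional mean annual landings (tonnes): either
#'   [point_observations()] at reporting offices (spread over the area of
#'   influence by KDE, as for the other inputs) or ready-made per-cell
#'   [cell_values()] (used as-is)
#' @param tracks optional list of [track()] objects
#' @param config a [pipeline_config()]
#' @param out_dir optional directory for artifacts (grid GeoJSON, cell-value
#'   CSVs, per-draw CSV, summary JSON)
#' @return a `pfe_pipeline` list with all intermediate objects and a
#'   `summary` list (m, K, b, capacity figures, validation statistics)
#' @export
run_pipeline <- function(coast, communities, boats, landings = NULL,
                         tracks = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  cfg <- config
  coastal <- .stage("communities",
    select_coastal_communities(communities, coast, cfg$inland_buffer_km))
  aoi <- .stage("aoi", buffer_seaward(coast, cfg$seaward_buffer_km))
  grid <- .stage("grid", build_grid(aoi, cfg$cell_area_km2))

  kde_cells <- function(pts) {
    r <- density_surface(pts, aoi, h_km = cfg$kde_h_km,
                         res_km = cfg$kde_res_km, mode = cfg$kde_mode)
    list(raster = r, cells = aggregate_mean(r, grid, output = "cell_total"))
  }
  pop <- .stage("kde_population", kde_cells(coastal))
  bts <- .stage("kde_boats", kde_cells(boats))

  fit_m <- .stage("allometry",
    fit_power_law(bts$cells, pop$cells, through_origin = cfg$through_origin,
                  offset = cfg$offset))
  m_used <- if (!is.null(cfg$fixed_m)) cfg$fixed_m else fit_m$m
  pfe <- .stage("pfe", compute_pfe(bts$cells, pop$cells, m_used))

  catch_fit <- capacity <- catch_cells <- NULL
  if (!is.null(landings)) {
    catch_cells <- if (inherits(landings, "pfe_cell_values")) landings
                   else .stage("kde_catch", kde_cells(landings)$cells)
    cents <- data.frame(cell_id = grid$cell_id, x = grid$cx, y = grid$cy)
    catch_fit <- .stage("catch_fit",
      fit_catch_model(pfe, catch_cells, n_draws = cfg$n_draws,
                      draw_size = cfg$draw_size, seed = cfg$seed,
                      centroids = if (cfg$mantel_permutations > 0) cents,
                      mantel_permutations = cfg$mantel_permutations))
    observed <- if (!is.null(cfg$observed_fleet)) cfg$observed_fleet
                else sum(boats$value)
    capacity <- .stage("capacity",
      capacity_report(catch_fit, n_cells = nrow(grid),
                      cell_area_km2 = cfg$cell_area_km2,
                      observed_fleet = observed))
  }

  validation <- events <- NULL
  if (!is.null(tracks)) {
    events <- .stage("events", do.call(rbind, lapply(tracks, function(t)
      detect_fishing_events(t, cfg$speed_max, cfg$min_points))))
    freq <- .stage("events", events_per_cell(events, grid))
    # compare only within the tracked region (the cells the vessels could
    # have fished), not across the whole area of influence
    tx <- unlist(lapply(tracks, `[[`, "x")); ty <- unlist(lapply(tracks, `[[`, "y"))
    side <- attr(grid, "side_m")
    in_box <- grid$cx >= min(tx) - side & grid$cx <= max(tx) + side &
              grid$cy >= min(ty) - side & grid$cy <= max(ty) + side
    tracked <- freq[freq$cell_id %in% grid$cell_id[in_box], , drop = FALSE]
    class(tracked) <- class(freq); attr(tracked, "units") <- "events"
    validation <- .stage("validation", validate_pfe(pfe, tracked))
  }

  summary <- list(
    n_cells = nrow(grid), cell_area_km2 = cfg$cell_area_km2,
    area_km2 = nrow(grid) * cfg$cell_area_km2,
    n_communities_coastal = nrow(coastal),
    total_population = sum(coastal$value), total_boats = sum(boats$value),
    m = m_used, m_fitted = fit_m$m, m_se = fit_m$se_m, allometry_r2 = fit_m$r2,
    K = catch_fit$K %||% NA_real_, b = catch_fit$b %||% NA_real_,
    catch_r2 = catch_fit$r2 %||% NA_real_,
    pfe_inflection = capacity$pfe_inflection %||% NA_real_,
    catch_at_inflection = capacity$catch_at_inflection %||% NA_real_,
    fleet_capacity = capacity$fleet_capacity %||% NA_integer_,
    excess_boats = capacity$excess_boats %||% NA_integer_,
    excess_percent = capacity$excess_percent %||% NA_real_,
    validation_r2 = validation$r2 %||% NA_real_,
    validation_rho = validation$pearson_rho %||% NA_real_,
    seed = cfg$seed, defaults_used = cfg$defaults_used)

  res <- structure(list(
    config = cfg, aoi = aoi, grid = grid,
    population_cells = pop$cells, boats_cells = bts$cells,
    catch_cells = catch_cells, allometry = fit_m, pfe = pfe,
    catch_fit = catch_fit, capacity = capacity,
    events = events, validation = validation, summary = summary),
    class = "pfe_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_grid_geojson(grid, file.path(out_dir, "grid.geojson"))
    write_cell_values_csv(pop$cells, file.path(out_dir, "population_cells.csv"))
    write_cell_values_csv(bts$cells, file.path(out_dir, "boats_cells.csv"))
    write_cell_values_csv(pfe, file.path(out_dir, "pfe_cells.csv"))
    if (!is.null(catch_cells))
      write_cell_values_csv(catch_cells, file.path(out_dir, "catch_cells.csv"))
    if (!is.null(catch_fit))
      utils::write.csv(catch_fit$per_draw,
                       file.path(out_dir, "catch_fit_draws.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.pfe_pipeline <- function(x, ...) {
  s <- x$summary
  cat("PFE pipeline:", s$n_cells, "cells,", s$n_communities_coastal,
      "coastal communities\n")
  cat(sprintf("  m = %.3f (fitted %.3f +/- %.3f, r2 = %.2f)\n",
              s$m, s$m_fitted, s$m_se, s$allometry_r2))
  if (is.finite(s$K))
    cat(sprintf("  K = %.0f, b = %.1f -> capacity %d boats (excess %d, %d%%)\n",
                s$K, s$b, s$fleet_capacity, s$excess_boats, s$excess_percent))
  if (is.finite(s$validation_r2))
    cat(sprintf("  validation: r2 = %.2f, rho = %.2f\n",
                s$validation_r2, s$validation_rho))
  invisible(x)
}
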