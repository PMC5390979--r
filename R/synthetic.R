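# Synthetic study regions with the statistical structure the method
# assumes: a curved coastline, lognormal community populations within the
# coastal strip, boat counts following a noisy power law of population,
# landings following the saturating catch-effort curve with multiplicative
# noise, and GPS tracks with embedded low-speed fishing events. Everything
# is reproducible from the scenario seed.

#' Define a synthetic study scenario
#'
#' Defaults emulate a Gulf-of-California-scale study region: a coastline of
#' 1,000 km whose 75 km area of influence holds on the order of 500 cells
#' of 500 km2, some 150 coastal communities with lognormal populations
#' (median ~ e^8 = 3,000 people, camps to cities, totalling ~1.4 million as
#' in the Gulf of California), boats scaling as
#' population^0.43 with 30% lognormal scatter, and landings saturating with
#' K = 2204 t/cell/yr and b = 47.
#'
#' @param seed integer root seed (all generators derive from it)
#' @param coast_length_km coastline length
#' @param coast_amplitude_km amplitude of the coastline's large-scale bends
#' @param coast_wavelength_km wavelength of the bends
#' @param n_communities number of coastal communities (>= 2)
#' @param pop_meanlog,pop_sdlog lognormal population parameters (natural log)
#' @param m_true true allometric exponent
#' @param sigma_b sd of the lognormal boats-count noise (log scale)
#' @param K_true,b_true true catch-model parameters
#' @param sigma_c sd of the multiplicative catch noise (log scale)
#' @param n_vessels,events_per_vessel track-generation sizes
#' @param fishing_speed,cruise_speed vessel speeds (m/s)
#' @param track_dt seconds between GPS fixes
#' @param fishing_fixes low-speed fixes per fishing event
#' @return a `pfe_scenario` list
#' @export
pfe_scenario <- function(seed = 1,
                         coast_length_km = 1000, coast_amplitude_km = 80,
                         coast_wavelength_km = 450,
                         n_communities = 150,
                         pop_meanlog = 8, pop_sdlog = 1.5,
                         m_true = 0.43, sigma_b = 0.3,
                         K_true = 2204, b_true = 47, sigma_c = 0.3,
                         n_vessels = 40, events_per_vessel = 3,
                         fishing_speed = 0.5, cruise_speed = 5,
                         track_dt = 60, fishing_fixes = 7) {
  stopifnot(sigma_b >= 0, sigma_c >= 0, K_true > 0, b_true > 0,
            n_communities >= 2, fishing_speed > 0, cruise_speed > 0)
  structure(as.list(environment()), class = "pfe_scenario")
}

# coastline geometry shared by the generators: a north-running sinusoid in
# projected meters (a plausible UTM frame)
.scenario_coastline <- function(sc) {
  t <- seq(0, sc$coast_length_km, length.out = 251) * 1000
  coastline(x = 5e5 + sc$coast_amplitude_km * 1000 *
                  sin(2 * pi * t / (sc$coast_wavelength_km * 1000)),
            y = 3e6 + t)
}

# latent community state shared by the region and track generators, fully
# determined by the scenario seed
.region_latent <- function(sc) {
  set.seed(sc$seed)
  L <- sc$coast_length_km * 1000
  t_m <- sort(stats::runif(sc$n_communities, 0, L))
  inland <- stats::runif(sc$n_communities, 200, 4800)   # within the 5 km strip
  offshore <- stats::runif(sc$n_communities, 200, 2000) # boats in the water
  pop <- round(stats::rlnorm(sc$n_communities, sc$pop_meanlog, sc$pop_sdlog))
  boats <- round(pop^sc$m_true * exp(stats::rnorm(sc$n_communities, 0, sc$sigma_b)))
  list(t_m = t_m, cp = .coast_point(sc, t_m), inland = inland,
       offshore = offshore, pop = pop, boats = boats)
}

# unit tangent/normal of the coastline at parameter positions t (meters)
.coast_point <- function(sc, t_m) {
  A <- sc$coast_amplitude_km * 1000
  w <- 2 * pi / (sc$coast_wavelength_km * 1000)
  x <- 5e5 + A * sin(w * t_m)
  y <- 3e6 + t_m
  dx <- A * w * cos(w * t_m); dy <- 1
  nrm <- sqrt(dx^2 + dy^2)
  # normal pointing to +x side (taken as land)
  list(x = x, y = y, nx = dy / nrm, ny = -dx / nrm)
}

#' Generate a synthetic region: coastline, communities and boat counts
#'
#' Communities sit within the 5 km coastal strip on the land side, uniformly
#' spread along the coast; populations are lognormal; each community's boat
#' count is round(population^m_true * e^eps) with eps ~ N(0, sigma_b^2),
#' observed at an in-water point just off the community.
#'
#' @param sc a [pfe_scenario()]
#' @return list: coastline ([coastline()]), communities, boats
#'   (both [point_observations()])
#' @export
generate_region <- function(sc) {
  if (!inherits(sc, "pfe_scenario")) stop("sc must be a pfe_scenario")
  lat <- .region_latent(sc)
  cp <- lat$cp; pop <- lat$pop; boats <- lat$boats
  inland <- lat$inland; offshore <- lat$offshore
  list(
    coastline = .scenario_coastline(sc),
    communities = point_observations(
      x = cp$x + inland * cp$nx, y = cp$y + inland * cp$ny,
      value = pop, id = sprintf("com%03d", seq_along(pop)),
      units = "persons"),
    boats = point_observations(
      x = cp$x - offshore * cp$nx, y = cp$y - offshore * cp$ny,
      value = boats, id = sprintf("com%03d", seq_along(pop)),
      units = "boats"))
}

#' Generate synthetic landings from an effort surface
#'
#' catch = K_true * exp(-b_true / pfe) * exp(eta), eta ~ N(0, sigma_c^2);
#' cells with pfe = 0 land nothing.
#'
#' @param pfe [cell_values()] of effort
#' @param K_true,b_true true curve parameters (> 0)
#' @param sigma_c multiplicative noise sd on the natural-log scale (>= 0)
#' @param seed integer seed
#' @return [cell_values()] of tonnes per cell per yr
#' @export
generate_catch <- function(pfe, K_true, b_true, sigma_c, seed) {
  stopifnot(K_true > 0, b_true > 0, sigma_c >= 0)
  set.seed(seed)
  eta <- stats::rnorm(nrow(pfe), 0, sigma_c)
  mu <- predict_catch(pfe$value, K_true, b_true)
  cell_values(pfe$cell_id, mu * exp(eta) * (pfe$value > 0), units = "tonnes")
}

#' Generate GPS tracks with known embedded fishing events
#'
#' Each vessel leaves a port community (sampled in proportion to community
#' boat counts, so track density follows local effort), cruises offshore at
#' `cruise_speed`, performs `events_per_vessel` low-speed fishing events
#' (`fishing_fixes` fixes at `fishing_speed`) at separate grounds, and
#' returns. Cruise legs are snapped to whole cruise-speed steps so the only
#' low-speed segments are the labeled fishing ones.
#'
#' @param sc a [pfe_scenario()]
#' @param grid a [build_grid()] result used to label ground-truth cells
#' @return list: tracks (list of [track()]), truth (data.frame vessel_id,
#'   event, x, y, cell_id of each embedded event)
#' @export
generate_tracks <- function(sc, grid) {
  lat <- .region_latent(sc)
  set.seed(sc$seed + 101L)
  dt <- sc$track_dt
  cruise_step <- sc$cruise_speed * dt
  fish_step <- sc$fishing_speed * dt
  tracks <- vector("list", sc$n_vessels)
  truth <- list()
  # vessels depart where the boats are: ports sampled in proportion to the
  # community boat counts, so fishing frequency tracks local effort
  port_com <- sample.int(sc$n_communities, sc$n_vessels, replace = TRUE,
                         prob = lat$boats + 1)
  for (v in seq_len(sc$n_vessels)) {
    port <- .coast_point(sc, lat$t_m[port_com[v]])
    pos <- c(port$x, port$y)
    pts <- matrix(pos, ncol = 2)
    # grounds progressively further offshore (the -normal, water side)
    for (ev in seq_len(sc$events_per_vessel)) {
      off <- stats::runif(1, 5000, 40000)
      along <- stats::rnorm(1, 0, 5000)
      ground <- c(port$x - off * port$nx + along * -port$ny,
                  port$y - off * port$ny + along * port$nx)
      d <- ground - pos
      n_steps <- max(2L, as.integer(round(sqrt(sum(d^2)) / cruise_step)))
      ground <- pos + d / sqrt(sum(d^2)) * n_steps * cruise_step
      leg <- cbind(seq(pos[1], ground[1], length.out = n_steps + 1),
                   seq(pos[2], ground[2], length.out = n_steps + 1))[-1, , drop = FALSE]
      pts <- rbind(pts, leg)
      pos <- ground
      # fishing: slow drift in one random direction
      ang <- stats::runif(1, 0, 2 * pi)
      drift <- cbind(pos[1] + cumsum(rep(cos(ang) * fish_step, sc$fishing_fixes)),
                     pos[2] + cumsum(rep(sin(ang) * fish_step, sc$fishing_fixes)))
      first_fix <- pos
      pts <- rbind(pts, drift)
      pos <- drift[nrow(drift), ]
      mid <- (first_fix + pos) / 2
      truth[[length(truth) + 1]] <- data.frame(
        vessel_id = sprintf("v%02d", v), event = ev, x = mid[1], y = mid[2])
    }
    # return leg
    d <- c(port$x, port$y) - pos
    n_steps <- max(2L, as.integer(round(sqrt(sum(d^2)) / cruise_step)))
    home <- pos + d / sqrt(sum(d^2)) * n_steps * cruise_step
    leg <- cbind(seq(pos[1], home[1], length.out = n_steps + 1),
                 seq(pos[2], home[2], length.out = n_steps + 1))[-1, , drop = FALSE]
    pts <- rbind(pts, leg)
    tracks[[v]] <- track(t = seq_len(nrow(pts)) * dt, x = pts[, 1], y = pts[, 2],
                         vessel_id = sprintf("v%02d", v))
  }
  truth <- do.call(rbind, truth)
  idx <- .grid_index(grid, truth$x, truth$y)
  truth$cell_id <- ifelse(!is.na(idx$cell_id) & idx$cell_id %in% grid$cell_id,
                          idx$cell_id, NA_integer_)
  list(tracks = tracks, truth = truth)
}
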