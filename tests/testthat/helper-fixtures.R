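# Shared in-code fixtures: tiny geometries and surfaces built fresh per run.

# a disc-shaped area of influence around a single "coast" point
disc_aoi <- function(radius_km = 25, x = 0, y = 0) {
  buffer_seaward(coastline(x, y), distance_km = radius_km)
}

# a straight east-west coastline of the given length (meters origin at 0,0)
straight_coast <- function(length_km = 100, n = 11) {
  coastline(seq(0, length_km * 1000, length.out = n), rep(0, n))
}

# small grid fully covering a disc AoI
small_grid <- function(radius_km = 25, cell_area_km2 = 100) {
  build_grid(disc_aoi(radius_km), cell_area_km2)
}

# cell_values from named vectors
cv <- function(ids, vals, units = "value") cell_values(ids, vals, units)

# lognormal effort surface spanning the catch curve's rising and plateau parts
lognormal_pfe <- function(n, seed, meanlog = log(20), sdlog = 1) {
  set.seed(seed)
  cell_values(seq_len(n), stats::rlnorm(n, meanlog, sdlog), units = "PFE")
}

# independent brute-force through-origin slope: sum(xy)/sum(x^2) by loop
brute_origin_slope <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + x[i] * y[i]
    den <- den + x[i] * x[i]
  }
  num / den
}

# independent Mantel statistic: Pearson r between lower triangles
brute_mantel_r <- function(res, loc) {
  dr <- as.vector(stats::dist(res))
  dg <- as.vector(stats::dist(loc))
  stats::cor(dg, dr)
}
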