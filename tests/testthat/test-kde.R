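test_that("the quadratic kernel has the textbook shape", {
  expect_equal(kernel_shape(0, 75), 0.75)
  expect_equal(kernel_shape(75, 75), 0)
  expect_equal(kernel_shape(37.5, 75), 0.5625)   # 0.75 * (1 - 0.25)
  expect_equal(kernel_shape(100, 75), 0)
  expect_error(kernel_shape(1, 0), "positive")
  expect_error(kernel_shape(-1, 1), ">= 0")
})

test_that("mass-conserving surfaces integrate back to the input total", {
  pts <- point_observations(0, 0, 100, units = "boats")
  r <- density_surface(pts, extent = c(-80e3, -80e3, 80e3, 80e3),
                       h_km = 75, res_km = 1)
  expect_equal(sum(r$values) * r$res_km^2, 100, tolerance = 0.01)
  expect_true(all(r$values >= 0))
  # multiple weighted points, interior
  set.seed(4)
  pts2 <- point_observations(runif(5, -10e3, 10e3), runif(5, -10e3, 10e3),
                             c(7, 0, 3.5, 120, 9), units = "persons")
  r2 <- density_surface(pts2, extent = c(-20e3, -20e3, 20e3, 20e3),
                        h_km = 20, res_km = 1)
  expect_equal(sum(r2$values) * 1, sum(pts2$value), tolerance = 0.01)
  expect_lt(r2$mass_outside_frac, 0.01)
})

test_that("surfaces are linear in the input and peak at the point", {
  # extent chosen so (0, 0) is a pixel center
  ext <- c(-50.5e3, -50.5e3, 50e3, 50e3)
  one <- density_surface(point_observations(0, 0, 1), ext, h_km = 75)
  two <- density_surface(point_observations(c(0, 0), c(0, 0), c(1, 1)), ext,
                         h_km = 75)
  expect_equal(two$values, 2 * one$values)
  # closed-form peak density 2 / (pi h^2)
  expect_equal(max(one$values), 2 / (pi * 75^2), tolerance = 1e-12)
  # radial monotonicity along a pixel row through the point
  i0 <- which(abs(one$origin[2] + (seq_len(one$ny) - 0.5) * 1000) < 1)
  j0 <- which(abs(one$origin[1] + (seq_len(one$nx) - 0.5) * 1000) < 1)
  row_right <- one$values[i0, j0:one$nx]
  expect_true(all(diff(row_right) <= 1e-15))
})

test_that("translation by one pixel shifts the surface by one pixel", {
  ext <- c(-30e3, -30e3, 30e3, 30e3)
  a <- density_surface(point_observations(0, 0, 5), ext, h_km = 20)
  b <- density_surface(point_observations(1000, 0, 5), ext, h_km = 20)
  expect_equal(a$values[, 2:(a$nx - 1)], b$values[, 3:b$nx], tolerance = 1e-12)
})

test_that("literal_1d mode is proportional to mass_conserving for one point", {
  ext <- c(-30e3, -30e3, 30e3, 30e3)
  mc <- density_surface(point_observations(0, 0, 10), ext, h_km = 20,
                        mode = "mass_conserving")
  pl <- density_surface(point_observations(0, 0, 10), ext, h_km = 20,
                        mode = "literal_1d")
  ratio <- (2 / (pi * 20^2)) / (0.75 / 20)
  on_support <- pl$values > 0
  expect_equal(mc$values[on_support], ratio * pl$values[on_support],
               tolerance = 1e-12)
})

test_that("empty input yields a zero raster with a warning", {
  expect_warning(
    r <- density_surface(point_observations(numeric(0), numeric(0), numeric(0)),
                         c(0, 0, 10e3, 10e3), h_km = 10),
    "no input points")
  expect_true(all(r$values == 0))
})

test_that("cell aggregation is the arithmetic mean, rescalable to totals", {
  g <- small_grid(25, 100)
  pts <- point_observations(0, 0, 50, units = "boats")
  r <- density_surface(pts, disc_aoi(25), h_km = 25, res_km = 1)
  # constant raster: every cell mean equals the constant
  r$values[] <- 3.5
  m <- aggregate_mean(r, g)
  expect_true(all(abs(m$value - 3.5) < 1e-12))
  tot <- aggregate_mean(r, g, output = "cell_total")
  expect_true(all(abs(tot$value - 3.5 * 100) < 1e-10))
  # zero raster
  r$values[] <- 0
  expect_true(all(aggregate_mean(r, g)$value == 0))
  # aggregated KDE totals conserve mass over a grid covering the support
  gg <- build_grid(disc_aoi(40), 100)
  rr <- density_surface(pts, disc_aoi(40), h_km = 25, res_km = 1)
  agg <- aggregate_mean(rr, gg, output = "cell_total")
  expect_equal(sum(agg$value), 50, tolerance = 0.02)
})
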