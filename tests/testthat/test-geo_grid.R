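test_that("buffering a point coast gives a disc of the right area", {
  a <- disc_aoi(75)
  expect_equal(aoi_area(a), pi * 75^2, tolerance = 0.005)
  expect_error(buffer_seaward(coastline(0, 0), 0), "positive")
  expect_error(buffer_seaward(coastline(0, 0), -3), "positive")
})

test_that("a land mask turns the buffer one-sided", {
  # 100 km segment, 10 km buffer, land = the y > 0 half-plane: the seaward
  # side is a 100 x 10 rectangle plus two quarter-discs
  coast <- straight_coast(100)
  land <- rbind(c(-200e3, 0), c(300e3, 0), c(300e3, 200e3), c(-200e3, 200e3))
  a <- buffer_seaward(coast, 10, land = land)
  expect_equal(aoi_area(a, res_km = 0.5), 100 * 10 + pi * 100 / 2,
               tolerance = 0.01)
  expect_true(all(aoi_contains(a, c(50e3, 50e3), c(-5e3, -9.9e3))))
  expect_false(any(aoi_contains(a, c(50e3, 50e3), c(5e3, 9.9e3))))
})

test_that("coastal community selection applies a closed 5 km boundary", {
  coast <- straight_coast(100)
  pts <- point_observations(x = rep(50e3, 3), y = c(3e3, 6e3, 5e3),
                            value = c(10, 20, 30), units = "persons")
  kept <- select_coastal_communities(pts, coast, inland_km = 5)
  expect_equal(kept$value, c(10, 30))   # 3 km and exactly 5 km retained
  # monotone in the buffer distance
  for (km in c(1, 2, 4, 8)) {
    small <- select_coastal_communities(pts, coast, km)
    big <- select_coastal_communities(pts, coast, km + 1)
    expect_true(all(small$value %in% big$value))
  }
})

test_that("grid construction anchors at the bbox corner and keeps intersecting cells", {
  # AoI bbox exactly 2x2 cells of 500 km2: disc radius = cell side
  side_km <- sqrt(500)
  g4 <- build_grid(disc_aoi(side_km), 500)
  expect_equal(nrow(g4), 4)
  expect_equal(attr(g4, "origin"), c(-side_km, -side_km) * 1000)
  # AoI strictly inside one cell
  g1 <- build_grid(disc_aoi(10), 500)
  expect_equal(nrow(g1), 1)
  # square 50 km AoI bbox (buffered square-perimeter coast) with side
  # 22.3607 km -> ceil(50 / 22.3607) = 3 per axis, all 9 cells touch the AoI
  sq <- coastline(rbind(c(-15e3, -15e3), c(15e3, -15e3), c(15e3, 15e3),
                        c(-15e3, 15e3), c(-15e3, -15e3)))
  g9 <- build_grid(buffer_seaward(sq, 10), 500)
  expect_equal(nrow(g9), 9)
  expect_error(build_grid(disc_aoi(10), -5), "positive")
  expect_error(build_grid(disc_aoi(10), 0), "positive")
})

test_that("grid construction is deterministic and all cells touch the AoI", {
  sc <- pfe_scenario(seed = 3, coast_length_km = 200, n_communities = 20)
  reg <- generate_region(sc)
  aoi <- buffer_seaward(reg$coastline, 75)
  g1 <- build_grid(aoi, 500)
  g2 <- build_grid(aoi, 500)
  expect_identical(g1, g2)
  dmax <- aoi$seaward_buffer_km * 1000
  for (i in seq_len(nrow(g1))) {
    d <- pfe:::.rect_polyline_dist(g1$xmin[i], g1$ymin[i], g1$xmax[i],
                                   g1$ymax[i], as.matrix(aoi$coastline))
    expect_lte(d, dmax)
  }
  expect_false(anyDuplicated(g1$cell_id) > 0)
})

test_that("point-to-cell assignment sums values and reports drops exactly", {
  g <- small_grid(25, 100)   # 10 km cells over a 50 km box
  pts <- point_observations(x = c(-21e3, -22e3, 60e3), y = c(-21e3, -22e3, 0),
                            value = c(3, 4, 99), units = "boats")
  cvv <- points_to_cell_centroids(pts, g)
  expect_equal(nrow(cvv), 1)
  expect_equal(cvv$value, 7)             # additivity in one cell
  expect_equal(attr(cvv, "dropped_n"), 1)
  expect_equal(attr(cvv, "dropped_value"), 99)
  expect_equal(sum(cvv$value), sum(pts$value) - attr(cvv, "dropped_value"))
  # no points
  none <- points_to_cell_centroids(
    point_observations(numeric(0), numeric(0), numeric(0)), g)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "dropped_n"), 0)
})

test_that("points on a shared cell edge go to the lower (row, col) cell", {
  g <- small_grid(25, 100)
  o <- attr(g, "origin"); side <- attr(g, "side_m")
  # exactly on the vertical edge between col 0 and col 1, interior of row 1
  p_edge <- point_observations(o[1] + side, o[2] + 1.5 * side, 1)
  cvv <- points_to_cell_centroids(p_edge, g)
  expect_equal(g$col[match(cvv$cell_id, g$cell_id)], 0)
  expect_equal(g$row[match(cvv$cell_id, g$cell_id)], 1)
  # exactly on the grid origin corner -> cell (0, 0)
  p0 <- point_observations(o[1], o[2], 1)
  cv0 <- points_to_cell_centroids(p0, g)
  expect_equal(g$row[match(cv0$cell_id, g$cell_id)], 0)
  expect_equal(g$col[match(cv0$cell_id, g$cell_id)], 0)
})

test_that("conservation: cell sums equal input totals minus drops on random data", {
  set.seed(11)
  g <- small_grid(25, 100)
  for (rep in 1:5) {
    pts <- point_observations(runif(40, -60e3, 60e3), runif(40, -60e3, 60e3),
                              rpois(40, 10))
    cvv <- points_to_cell_centroids(pts, g)
    expect_equal(sum(cvv$value) + attr(cvv, "dropped_value"), sum(pts$value))
  }
})
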