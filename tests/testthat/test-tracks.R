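test_that("segment speeds are distance over elapsed time", {
  tk <- track(t = c(0, 100), x = c(0, 1000), y = c(0, 0))
  expect_equal(compute_speeds(tk), 10)
  tk2 <- track(t = c(0, 60, 120), x = c(0, 0, 0), y = c(0, 0, 0))
  expect_equal(compute_speeds(tk2), c(0, 0))
  # right-angle path with equal legs and intervals -> equal speeds
  tk3 <- track(t = c(0, 60, 120), x = c(0, 600, 600), y = c(0, 0, 600))
  expect_equal(compute_speeds(tk3)[1], compute_speeds(tk3)[2])
  expect_error(compute_speeds(track(t = c(0, 0, 10), x = 1:3, y = 1:3)),
               "duplicate")
  expect_error(track(t = c(10, 0), x = 1:2, y = 1:2), "increasing")
  expect_error(track(t = 1, x = 1, y = 1), "at least 2")
})

test_that("event detection finds maximal qualifying low-speed runs", {
  dt <- 60
  mk <- function(speeds) {   # path with prescribed segment speeds
    track(t = seq(0, by = dt, length.out = length(speeds) + 1),
          x = cumsum(c(0, speeds * dt)), y = 0 * c(0, speeds))
  }
  expect_equal(nrow(detect_fishing_events(mk(rep(5, 8)), 1, 3)), 0)
  # two separated qualifying runs
  two <- mk(c(5, 5, .5, .5, .5, 5, 5, .4, .4, .4, .4, 5))
  ev <- detect_fishing_events(two, 1, 3)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$n_segments, c(3, 4))
  # a run one segment short of the threshold does not qualify
  short <- mk(c(5, .5, .5, 5))
  expect_equal(nrow(detect_fishing_events(short, 1, 3)), 0)
  expect_equal(nrow(detect_fishing_events(short, 1, 2)), 1)
  expect_error(detect_fishing_events(two, 0, 3), "positive")
  expect_error(detect_fishing_events(two, 1, 1), ">= 2")
})

test_that("detection is invariant to translation and rotation", {
  set.seed(31)
  speeds <- c(5, .5, .5, .5, 5, 5, .3, .3, .3, .3, 5)
  ang <- cumsum(runif(length(speeds), -0.5, 0.5))
  steps <- cbind(cos(ang), sin(ang)) * speeds * 60
  xy <- rbind(c(0, 0), apply(steps, 2, cumsum))
  tk <- track(seq(0, by = 60, length.out = nrow(xy)), xy[, 1], xy[, 2])
  n0 <- nrow(detect_fishing_events(tk, 1, 3))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy2 <- sweep(xy %*% R, 2, c(5e5, -3e4), "+")
  tk2 <- track(tk$t, xy2[, 1], xy2[, 2])
  expect_equal(nrow(detect_fishing_events(tk2, 1, 3)), n0)
  expect_equal(detect_fishing_events(tk2, 1, 3)$n_segments,
               detect_fishing_events(tk, 1, 3)$n_segments)
})

test_that("raising speed_max never loses qualifying segments", {
  set.seed(32)
  speeds <- runif(50, 0, 6)
  tk <- track(seq(0, by = 60, length.out = 51),
              cumsum(c(0, speeds * 60)), rep(0, 51))
  n_seg <- function(sm) sum(detect_fishing_events(tk, sm, 2)$n_segments)
  thresholds <- seq(0.5, 6, by = 0.5)
  counts <- vapply(thresholds, n_seg, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("per-cell event counts are conserved and use the shared tie rule", {
  g <- small_grid(25, 100)
  ev <- data.frame(vessel_id = "v", start = 1, end = 2,
                   x = c(-21e3, -21e3, -21e3, 5e3, 99e5),
                   y = c(-21e3, -20e3, -22e3, 5e3, 0), n_segments = 3)
  expect_warning(fc <- events_per_cell(ev, g), "outside")
  expect_equal(sum(fc$value), nrow(ev) - 1)
  expect_equal(fc$value[match(g$cell_id[g$row == 0 & g$col == 0], fc$cell_id)], 3)
  none <- events_per_cell(ev[0, ], g)
  expect_true(all(none$value == 0))
  # edge event follows the lower (row, col) rule
  o <- attr(g, "origin"); side <- attr(g, "side_m")
  ev_edge <- data.frame(vessel_id = "v", start = 1, end = 2,
                        x = o[1] + side, y = o[2] + 1.5 * side, n_segments = 3)
  fce <- events_per_cell(ev_edge, g)
  hit <- fce$cell_id[fce$value == 1]
  expect_equal(g$col[match(hit, g$cell_id)], 0)
})

test_that("validation regression reproduces known relationships", {
  pv <- cv(1:30, seq(1, 30), "PFE")
  # frequency exactly equal to PFE
  v1 <- validate_pfe(pv, cv(1:30, seq(1, 30), "events"))
  expect_equal(v1$r2, 1, tolerance = 1e-12)
  expect_equal(v1$pearson_rho, 1, tolerance = 1e-12)
  expect_equal(v1$df, 28L)
  expect_length(v1$outlier_cells, 0)
  # perfectly decreasing frequency -> rho = -1
  v2 <- validate_pfe(pv, cv(1:30, 31 - seq(1, 30), "events"))
  expect_equal(v2$pearson_rho, -1, tolerance = 1e-12)
  expect_error(validate_pfe(cv(1:5, rep(2, 5)), cv(1:5, 1:5)), "constant")
  expect_error(validate_pfe(cv(1:2, 1:2), cv(1:2, 1:2)), "at least 3")
})

test_that("the OLS slope concentrates around truth across replicates", {
  ok <- logical(200)
  set.seed(33)
  for (i in 1:200) {
    x <- runif(30, 0, 10)
    y <- pmax(2 * x + rnorm(30, 0, 1), 0)
    v <- validate_pfe(cv(1:30, x), cv(1:30, y))
    ok[i] <- v$slope >= 1.8 && v$slope <= 2.2
  }
  expect_gte(mean(ok), 0.95)
})
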