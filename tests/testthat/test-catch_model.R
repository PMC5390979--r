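test_that("the catch curve has the saturating form and limits", {
  expect_equal(predict_catch(23.5, 2204, 47), 2204 * exp(-2), tolerance = 1e-12)
  expect_equal(predict_catch(47, 2204, 47), 2204 * exp(-1), tolerance = 1e-12)
  expect_equal(predict_catch(0, 2204, 47), 0)
  expect_equal(predict_catch(1e12, 2204, 47), 2204, tolerance = 1e-6)
  pfe_grid_vals <- seq(1, 300, by = 0.5)
  cc <- predict_catch(pfe_grid_vals, 2204, 47)
  expect_true(all(diff(cc) > 0))            # strictly increasing
  expect_true(all(cc < 2204))               # bounded by K
  expect_error(predict_catch(10, -1, 5), "positive")
  expect_error(predict_catch(-1, 1, 5), ">= 0")
})

test_that("the inflection sits at b/2, confirmed by a numeric grid oracle", {
  expect_equal(inflection_point(47), 23.5)
  expect_equal(inflection_point(2), 1)
  expect_error(inflection_point(0), "positive")
  # dense numeric second derivative of K * exp(-b/x) for b = 10
  x <- seq(0.5, 30, by = 1e-4)
  f <- 1000 * exp(-10 / x)
  d2 <- diff(f, differences = 2)
  sign_change <- which(diff(sign(d2)) != 0)[1]
  expect_equal(x[sign_change + 1], inflection_point(10), tolerance = 1e-3)
  # curvature: convex below b/2, concave above
  expect_true(all(d2[x[2:(length(x) - 1)] < 4.9] > 0))
  expect_true(all(d2[x[2:(length(x) - 1)] > 5.1] < 0))
})

test_that("noiseless data reproduce (K, b) to machine-level accuracy", {
  pv <- lognormal_pfe(300, seed = 1)
  cc <- generate_catch(pv, 1000, 20, sigma_c = 0, seed = 1)
  fit <- fit_catch_model(pv, cc, n_draws = 10, draw_size = 250, seed = 2)
  expect_equal(fit$K, 1000, tolerance = 1e-6)
  expect_equal(fit$b, 20, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(nrow(fit$per_draw), 10)
  # log-form fit and arithmetic curve agree on the data
  expect_equal(predict_catch(pv$value, fit$K, fit$b), cc$value, tolerance = 1e-6)
})

test_that("the ln no-offset mode is exactly linear in 1/pfe", {
  pv <- lognormal_pfe(300, seed = 3)
  cc <- generate_catch(pv, 500, 30, sigma_c = 0, seed = 3)
  fit <- fit_catch_model(pv, cc, n_draws = 5, draw_size = 200, seed = 4,
                         transform = "ln")
  expect_equal(fit$K, 500, tolerance = 1e-9)
  expect_equal(fit$b, 30, tolerance = 1e-9)
})

test_that("resampling honors its preconditions and bookkeeping", {
  pv <- lognormal_pfe(100, seed = 5)
  cc <- generate_catch(pv, 1000, 20, 0.1, seed = 5)
  expect_error(fit_catch_model(pv, cc, n_draws = 5, draw_size = 250, seed = 1),
               "exceeds")
  expect_error(fit_catch_model(pv, cc, n_draws = 5, draw_size = 50),
               "seed is required")
  # zero-pfe cells are excluded and counted
  pv0 <- cell_values(1:101, c(pv$value, 0), units = "PFE")
  cc0 <- cell_values(1:101, c(cc$value, 0), units = "tonnes")
  fit <- fit_catch_model(pv0, cc0, n_draws = 5, draw_size = 50, seed = 9)
  expect_equal(fit$n_zero_pfe, 1)
  expect_equal(fit$n_cells_used, 100)
  # same seed, same result
  fit2 <- fit_catch_model(pv0, cc0, n_draws = 5, draw_size = 50, seed = 9)
  expect_identical(fit$per_draw, fit2$per_draw)
})

test_that("the mean K estimate falls inside its own averaged CI", {
  # moderate noise, study-sized data: the reported interval should cover
  # the truth in most replicates
  hits <- logical(20)
  for (i in 1:20) {
    pv <- lognormal_pfe(565, seed = 200 + i)
    cc <- generate_catch(pv, 2204, 47, 0.3, seed = 300 + i)
    fit <- fit_catch_model(pv, cc, n_draws = 30, draw_size = 250, seed = i)
    hits[i] <- fit$ci_K[1] <= 2204 && 2204 <= fit$ci_K[2]
  }
  expect_gte(mean(hits), 0.9)
})

test_that("Mantel statistic matches a brute-force oracle and flags structure", {
  # residual dissimilarities exactly equal to geographic distances -> r = 1
  loc <- cbind(c(0, 1, 3, 7), 0)
  res <- c(0, 1, 3, 7)
  mt <- mantel_test(res, loc, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_equal(mt$r, brute_mantel_r(res, loc), tolerance = 1e-12)
  expect_error(mantel_test(rep(1, 5), cbind(1:5, 0)), "constant")
  expect_error(mantel_test(1:3, cbind(1:3, 0)), "at least 4")
})

test_that("4-point Mantel p equals full enumeration of the 24 permutations", {
  set.seed(21)
  loc <- cbind(runif(4), runif(4))
  res <- rnorm(4)
  # brute-force enumeration: all 4! relabelings of the residuals
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  r_obs <- brute_mantel_r(res, loc)
  r_all <- apply(perms, 1, function(p) brute_mantel_r(res[p], loc))
  p_exact <- sum(r_all >= r_obs - 1e-12) / nrow(perms)
  # permutation test over the same complete set (identity excluded from the
  # permutation rows; the +1/+1 convention restores it)
  non_id <- perms[apply(perms, 1, function(p) any(p != 1:4)), ]
  mt <- mantel_test(res, loc, n_perm = non_id)
  expect_equal(mt$p, (1 + sum(r_all[apply(perms, 1, function(p) any(p != 1:4))] >=
                                r_obs - 1e-12)) / 24, tolerance = 1e-12)
  expect_equal(mt$p, p_exact, tolerance = 1e-12)
})

test_that("capacity arithmetic chains K, b, cells and fleets correctly", {
  rep1 <- capacity_report(list(K = 2204, b = 47), n_cells = 565,
                          observed_fleet = 17839)
  expect_equal(rep1$pfe_inflection, 23.5)
  expect_equal(rep1$area_km2, 282500)
  expect_equal(rep1$fleet_capacity, 13277L)
  expect_equal(rep1$excess_boats, 4562)
  expect_equal(rep1$excess_percent, 34)
  # break-even fleet
  rep2 <- capacity_report(list(K = 2204, b = 47), n_cells = 565,
                          observed_fleet = 13277)
  expect_equal(rep2$excess_boats, 0)
  expect_equal(rep2$excess_percent, 0)
  expect_error(capacity_report(list(K = 10, b = 1e-4), n_cells = 1,
                               observed_fleet = 5), "zero")
  expect_error(capacity_report(list(K = -1, b = 2), 10, observed_fleet = 1),
               "positive")
})
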