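# Saturating catch-effort model: catch = K * exp(-b / PFE), with K the
# maximum total catch per cell and b the scaling (slope) parameter. Fitted
# by resampled nonlinear least squares on log10(x+1)-transformed data
# (multiplicative error), with an optional Mantel check for spatial
# autocorrelation of the residuals in every draw.

#' Predicted catch at a given effort
#'
#' @param pfe effort value(s) >= 0; the pfe = 0 limit returns 0
#' @param K maximum total catch (tonnes per cell per yr, > 0)
#' @param b scaling parameter (PFE units, > 0)
#' @return tonnes per cell per yr, strictly increasing in pfe, bounded by K
#' @export
#' @examples
#' predict_catch(23.5, K = 2204, b = 47) # 298.28, the plateau-onset catch
predict_catch <- function(pfe, K, b) {
  if (K <= 0 || b <= 0) stop("K and b must be positive")
  if (any(pfe < 0)) stop("pfe must be >= 0")
  out <- ifelse(pfe > 0, K * exp(-b / pfe), 0)
  as.numeric(out)
}

#' Inflection (plateau-onset) effort of the catch curve
#'
#' The root of the second derivative of K * exp(-b/PFE) with respect to PFE:
#' gains in catch accelerate below b/2 and decelerate above it, marking
#' where diminishing returns begin.
#'
#' @param b scaling parameter (> 0)
#' @return PFE at the inflection, b/2
#' @export
#' @examples
#' inflection_point(47) # 23.5 boats per cell
inflection_point <- function(b) {
  if (!is.numeric(b) || length(b) != 1 || b <= 0) stop("b must be positive")
  b / 2
}

# single-draw fit of the transformed model; returns K, b, Wald CIs and the
# transformed-scale residuals, or NULL when the optimizer fails
.fit_catch_draw <- function(pfe, y, transform) {
  if (transform == "log10_plus1") {
    # start from the linear approximation log10(catch+1) ~ a + c/pfe
    lf <- stats::lm(y ~ I(1 / pfe))
    K0 <- max(10^stats::coef(lf)[1] - 1, 1e-6)
    b0 <- max(-stats::coef(lf)[2] * log(10), 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ log10(K * exp(-b / pfe) + 1),
                        start = list(K = K0, b = b0),
                        lower = c(1e-9, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    est <- stats::coef(fit)
    se <- summary(fit)$coefficients[, 2]
    tq <- stats::qt(0.975, df = length(y) - 2)
    list(K = unname(est["K"]), b = unname(est["b"]),
         ci_K = unname(est["K"] + c(-1, 1) * tq * se["K"]),
         ci_b = unname(est["b"] + c(-1, 1) * tq * se["b"]),
         resid = as.numeric(stats::resid(fit)))
  } else {
    # ln transform, no offset: exactly linear in 1/pfe
    lf <- stats::lm(y ~ I(1 / pfe))
    ci <- suppressMessages(stats::confint(lf))
    K <- exp(unname(stats::coef(lf)[1])); b <- -unname(stats::coef(lf)[2])
    if (!is.finite(K) || !is.finite(b) || b <= 0) return(NULL)
    list(K = K, b = b,
         ci_K = exp(unname(ci[1, ])), ci_b = sort(-unname(ci[2, ])),
         resid = as.numeric(stats::resid(lf)))
  }
}

#' Fit the saturating catch-effort model by resampled nonlinear regression
#'
#' Draws `n_draws` subsamples of `draw_size` cells (without replacement
#' within a draw), fits catch = K * exp(-b/PFE) to each by nonlinear least
#' squares on the transformed scale — log10(catch + 1) against
#' log10(K * exp(-b/pfe) + 1), the multiplicative-error form — and reports
#' the final K, b and 95% confidence limits as the means of the per-draw
#' estimates and per-draw Wald limits. Subsampling decorrelates neighboring
#' cells; when centroids are supplied, each draw's residuals are screened
#' for spatial autocorrelation with a Mantel test.
#'
#' Cells with pfe = 0 are excluded (the model is undefined there); their
#' count is recorded. Draws whose optimizer fails are dropped; more than
#' `max_drop_frac` failures aborts the fit.
#'
#' @param pfe,catch [cell_values()] on shared cell ids
#' @param n_draws number of random draws (default 500)
#' @param draw_size cells per draw (default 250)
#' @param seed integer seed (mandatory: resampling must be reproducible)
#' @param transform `"log10_plus1"` (default; the +1 avoids log-zero) or
#'   `"ln"` (natural log, no offset, requires positive catch)
#' @param centroids optional data.frame (cell_id, x, y) of projected cell
#'   centroids enabling the per-draw Mantel test
#' @param mantel_permutations permutations per per-draw Mantel test
#'   (default 99; only used when `centroids` is given)
#' @param max_drop_frac maximum tolerated fraction of failed draws
#' @return a `pfe_catch_fit` list: K, b, ci_K, ci_b, r2 (of the arithmetic
#'   curve against all data), per_draw data.frame, n_draws, draw_size,
#'   n_cells_used, n_zero_pfe, n_dropped_draws, transform, seed
#' @export
fit_catch_model <- function(pfe, catch, n_draws = 500, draw_size = 250,
                            seed, transform = c("log10_plus1", "ln"),
                            centroids = NULL, mantel_permutations = 99,
                            max_drop_frac = 0.1) {
  transform <- match.arg(transform)
  if (missing(seed)) stop("seed is required")
  d <- .join_cells(catch, pfe)          # a = catch, b = pfe
  n_zero <- sum(d$b <= 0)
  d <- d[d$b > 0, , drop = FALSE]
  if (transform == "ln") {
    if (any(d$a <= 0)) stop("ln transform requires strictly positive catch")
  }
  if (nrow(d) < draw_size)
    stop("draw_size (", draw_size, ") exceeds the ", nrow(d),
         " usable cells with pfe > 0")
  y_all <- if (transform == "log10_plus1") log10(d$a + 1) else log(d$a)

  if (!is.null(centroids)) {
    cpos <- centroids[match(d$cell_id, centroids$cell_id), c("x", "y")]
    if (anyNA(cpos)) stop("centroids missing for some fitted cells")
  }

  set.seed(seed)
  rows <- vector("list", n_draws)
  dropped <- 0L
  for (i in seq_len(n_draws)) {
    idx <- sample(nrow(d), draw_size)
    f <- .fit_catch_draw(d$b[idx], y_all[idx], transform)
    if (is.null(f)) { dropped <- dropped + 1L; next }
    mr <- mp <- NA_real_
    if (!is.null(centroids)) {
      mt <- mantel_test(f$resid, cpos[idx, ], n_perm = mantel_permutations)
      mr <- mt$r; mp <- mt$p
    }
    rows[[i]] <- data.frame(draw = i, K = f$K, b = f$b,
                            ci_K_lo = f$ci_K[1], ci_K_hi = f$ci_K[2],
                            ci_b_lo = f$ci_b[1], ci_b_hi = f$ci_b[2],
                            mantel_r = mr, mantel_p = mp)
  }
  if (dropped > max_drop_frac * n_draws)
    stop(dropped, " of ", n_draws, " draws failed to converge")
  per_draw <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])

  K <- mean(per_draw$K); b <- mean(per_draw$b)
  pred <- predict_catch(d$b, K, b)
  r2 <- 1 - sum((d$a - pred)^2) / sum((d$a - mean(d$a))^2)
  structure(list(
    K = K, b = b,
    ci_K = c(mean(per_draw$ci_K_lo), mean(per_draw$ci_K_hi)),
    ci_b = c(mean(per_draw$ci_b_lo), mean(per_draw$ci_b_hi)),
    r2 = r2, per_draw = per_draw,
    n_draws = n_draws, draw_size = draw_size,
    n_cells_used = nrow(d), n_zero_pfe = n_zero,
    n_dropped_draws = dropped, transform = transform, seed = seed),
    class = "pfe_catch_fit")
}

#' @export
print.pfe_catch_fit <- function(x, ...) {
  cat(sprintf("Catch-effort fit: catch = K * exp(-b/PFE) (%d draws of %d cells)\n",
              x$n_draws, x$draw_size))
  cat(sprintf("  K = %.1f t/cell/yr (95%% CI %.1f-%.1f)\n", x$K, x$ci_K[1], x$ci_K[2]))
  cat(sprintf("  b = %.2f (95%% CI %.2f-%.2f), arithmetic r2 = %.3f\n",
              x$b, x$ci_b[1], x$ci_b[2], x$r2))
  if (any(is.finite(x$per_draw$mantel_p)))
    cat(sprintf("  Mantel: %d / %d draws with p < 0.05\n",
                sum(x$per_draw$mantel_p < 0.05, na.rm = TRUE), nrow(x$per_draw)))
  if (x$n_zero_pfe > 0)
    cat("  excluded", x$n_zero_pfe, "cells with pfe = 0\n")
  invisible(x)
}

#' Mantel test for spatial autocorrelation of residuals
#'
#' Pearson correlation between the pairwise residual dissimilarities
#' |r_i - r_j| and the Euclidean distances between the corresponding
#' locations, with a one-sided permutation p-value for positive spatial
#' autocorrelation: p = (1 + #\{permuted r >= observed\}) / (n_perm + 1).
#' The permutation machinery is vegan's.
#'
#' @param residuals numeric residuals, one per location
#' @param locations data.frame or matrix of projected x, y (meters)
#' @param n_perm number of permutations (default 999), or a permutation
#'   matrix (rows = permutations) for exact enumeration
#' @param seed optional integer seed for the permutations
#' @return list: r (Mantel statistic), p (one-sided), n_perm
#' @export
mantel_test <- function(residuals, locations, n_perm = 999, seed = NULL) {
  locations <- as.matrix(locations)
  n <- length(residuals)
  if (n < 4) stop("need at least 4 points")
  if (nrow(locations) != n) stop("residuals and locations differ in length")
  if (stats::sd(residuals) == 0)
    stop("constant residuals: Mantel statistic undefined")
  if (!is.null(seed)) set.seed(seed)
  dres <- stats::dist(residuals)
  dgeo <- stats::dist(locations)
  mt <- vegan::mantel(dgeo, dres, method = "pearson", permutations = n_perm)
  list(r = unname(mt$statistic), p = mt$signif,
       n_perm = if (is.matrix(n_perm)) nrow(n_perm) else n_perm)
}

#' Fleet-capacity diagnostics from a catch-effort fit
#'
#' Turns the fitted curve into management quantities: the plateau-onset
#' effort b/2 per cell, the catch there (K * e^-2), and — extrapolated over
#' the whole area of influence — the largest fleet without diminishing
#' returns, `fleet_capacity = trunc(b/2 * n_cells)`, compared with the
#' observed fleet.
#'
#' @param fit a `pfe_catch_fit`, or a list/vector with elements K and b
#' @param n_cells number of grid cells in the area of influence (>= 1)
#' @param cell_area_km2 cell area (default 500)
#' @param observed_fleet observed number of boats operating at one moment
#' @return a `pfe_capacity` list: pfe_inflection, catch_at_inflection,
#'   n_cells, area_km2, fleet_capacity, observed_fleet, excess_boats,
#'   excess_percent (rounded to integer percent)
#' @export
#' @examples
#' capacity_report(list(K = 2204, b = 47), n_cells = 565,
#'                 observed_fleet = 17839)
capacity_report <- function(fit, n_cells, cell_area_km2 = 500, observed_fleet) {
  if (is.list(fit)) { K <- fit$K; b <- fit$b }
  else { K <- unname(fit["K"]); b <- unname(fit["b"]) }
  K <- as.numeric(K); b <- as.numeric(b)
  if (!is.finite(K) || !is.finite(b) || K <= 0 || b <= 0)
    stop("fit must provide positive K and b")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (observed_fleet < 0) stop("observed_fleet must be >= 0")
  pfe_inf <- inflection_point(b)
  capacity <- as.integer(trunc(pfe_inf * n_cells))
  if (capacity == 0) stop("fleet capacity is zero: excess percent undefined")
  excess <- observed_fleet - capacity
  structure(list(
    pfe_inflection = pfe_inf,
    catch_at_inflection = predict_catch(pfe_inf, K, b),  # K * e^-2
    n_cells = n_cells, area_km2 = n_cells * cell_area_km2,
    fleet_capacity = capacity, observed_fleet = observed_fleet,
    excess_boats = excess,
    excess_percent = round(100 * excess / capacity)),
    class = "pfe_capacity")
}

#' @export
print.pfe_capacity <- function(x, ...) {
  cat("Fleet-capacity report\n")
  cat(sprintf("  plateau onset: %.1f boats per cell (%.0f t/cell/yr)\n",
              x$pfe_inflection, x$catch_at_inflection))
  cat(sprintf("  area of influence: %d cells = %s km2\n",
              x$n_cells, format(x$area_km2, big.mark = ",")))
  cat(sprintf("  fleet capacity: %s boats; observed %s -> excess %s (%d%%)\n",
              format(x$fleet_capacity, big.mark = ","),
              format(x$observed_fleet, big.mark = ","),
              format(x$excess_boats, big.mark = ","), x$excess_percent))
  invisible(x)
}
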