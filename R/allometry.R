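# Allometric (power-law) scaling of boat numbers with coastal population:
# boats = k * population^m, fitted on log-log axes. The through-origin form
# (k = 1) is the one the effort statistic consumes.

.join_cells <- function(a, b) {
  ids <- intersect(a$cell_id, b$cell_id)
  data.frame(cell_id = ids,
             a = a$value[match(ids, a$cell_id)],
             b = b$value[match(ids, b$cell_id)])
}

#' Fit the boats-population power law
#'
#' Ordinary least squares of log(boats + offset) on log(population + offset).
#' With `through_origin = TRUE` the intercept is fixed at 0 (log k = 0, i.e.
#' k = 1) and the slope is the allometric exponent m; the +offset (default 1)
#' avoids the log-zero indetermination in empty cells. The exponent is
#' invariant to the log base.
#'
#' @param boats,population [cell_values()] on shared cell ids
#' @param through_origin fix the intercept at zero (default TRUE)
#' @param offset added to both variables inside the logs (default 1;
#'   use 0 for strictly positive data)
#' @param log_base base of the logarithm (default 10; cosmetic only)
#' @param variant tag recording the pipeline stage ("pre_kde" or "post_kde")
#' @return a `pfe_allometry` list: m, se_m, intercept (NA when forced
#'   through the origin), r2, F, df, p, n, offset, through_origin, variant
#' @export
fit_power_law <- function(boats, population, through_origin = TRUE,
                          offset = 1, log_base = 10,
                          variant = c("post_kde", "pre_kde")) {
  variant <- match.arg(variant)
  d <- .join_cells(boats, population)
  d <- d[d$a + offset > 0 & d$b + offset > 0, , drop = FALSE]
  if (nrow(d) < 2) stop("need at least 2 usable cells")
  if (all(d$b == 0)) stop("population is zero in every shared cell")
  y <- log(d$a + offset, base = log_base)
  x <- log(d$b + offset, base = log_base)
  fit <- if (through_origin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  s <- summary(fit)
  co <- s$coefficients
  slope_row <- if (through_origin) 1 else 2
  fstat <- s$fstatistic
  structure(list(
    m = unname(co[slope_row, 1]),
    se_m = unname(co[slope_row, 2]),
    intercept = if (through_origin) NA_real_ else unname(co[1, 1]),
    r2 = s$r.squared,
    F = unname(fstat[1]),
    df = unname(fstat[2:3]),
    p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = nrow(d), offset = offset, log_base = log_base,
    through_origin = through_origin, variant = variant,
    fit = fit), class = "pfe_allometry")
}

#' @export
print.pfe_allometry <- function(x, ...) {
  cat(sprintf("Allometric fit (%s%s): m = %.4f +/- %.4f\n", x$variant,
              if (x$through_origin) ", through origin" else "", x$m, x$se_m))
  cat(sprintf("  r2 = %.3f, F(%d,%d) = %.1f, p = %.3g, n = %d, offset = %g\n",
              x$r2, x$df[1], x$df[2], x$F, x$p, x$n, x$offset))
  invisible(x)
}

#' Population-predicted boat numbers
#'
#' The through-origin power law reduces to boats = population^m.
#'
#' @param population non-negative population value(s)
#' @param m allometric exponent (>= 0)
#' @return predicted boat numbers
#' @export
#' @examples
#' predict_boats(10000, 0.43) # 52.48
predict_boats <- function(population, m) {
  if (any(population < 0)) stop("population must be >= 0")
  if (m < 0) stop("m must be >= 0")
  population^m
}

#' Diagnose aliasing between counted and population-predicted boats
#'
#' The effort statistic assumes counted boats and population^m measure the
#' same signal; this checks that they are linearly related with slope 1
#' (through-origin OLS) and reports the Pearson correlation.
#'
#' @param boats,population [cell_values()] on shared cell ids
#' @param m allometric exponent
#' @param slope_tol flag departure from slope 1 beyond this tolerance
#' @return list: slope, r, n, aliased (TRUE when |slope - 1| <= slope_tol)
#' @export
diagnose_alias <- function(boats, population, m, slope_tol = 0.1) {
  d <- .join_cells(boats, population)
  if (nrow(d) < 2) stop("need at least 2 shared cells")
  x <- predict_boats(d$b, m); y <- d$a
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (constant) inputs")
  slope <- sum(x * y) / sum(x * x)
  r <- stats::cor(x, y)
  list(slope = slope, r = r, n = nrow(d),
       aliased = abs(slope - 1) <= slope_tol)
}
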