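# The Predicted Fishing Effort statistic.

#' Compute Predicted Fishing Effort per grid cell
#'
#' PFE combines the two aliased effort proxies — counted boats and the
#' population-predicted boat numbers — into one interaction term, their
#' geometric mean:
#'
#'   PFE = sqrt(boats * population^m)
#'
#' measured as boats per day per cell, adjusted by the local coastal
#' population. Zeros in either input propagate to PFE = 0 (no offset is
#' applied here; the +1 device belongs to the log-log fit only).
#'
#' @param boats [cell_values()] of boat counts (post-KDE cell totals in the
#'   standard pipeline; raw counts for diagnostics)
#' @param population [cell_values()] of coastal population
#' @param m allometric exponent (>= 0), typically from [fit_power_law()];
#'   0.43 is the fixed fallback used in the Gulf of California study
#' @return a `pfe_surface` ([cell_values()] subclass) over the shared cells,
#'   with the exponent and input units recorded in attributes
#' @export
#' @examples
#' b <- cell_values(1:2, c(100, 0), "boats")
#' p <- cell_values(1:2, c(10000, 500), "persons")
#' compute_pfe(b, p, m = 0.43)
compute_pfe <- function(boats, population, m) {
  if (!is.numeric(m) || length(m) != 1 || m < 0) stop("m must be a single number >= 0")
  if (any(boats$value < 0) || any(population$value < 0))
    stop("inputs must be >= 0")
  d <- .join_cells(boats, population)
  out <- cell_values(d$cell_id, sqrt(d$a * d$b^m), units = "PFE")
  attr(out, "m") <- m
  attr(out, "boats_units") <- attr(boats, "units")
  attr(out, "population_units") <- attr(population, "units")
  class(out) <- c("pfe_surface", class(out))
  out
}

#' @export
print.pfe_surface <- function(x, ...) {
  cat(sprintf(
    "PFE surface: %d cells, m = %.3f, range [%.3g, %.3g] boats/day/cell\n",
    nrow(x), attr(x, "m"), min(x$value), max(x$value)))
  invisible(x)
}
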