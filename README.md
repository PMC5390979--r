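# pfe — Predicted Fishing Effort for data-poor small-scale fisheries

Small-scale fishing fleets are, for practical purposes, untracked: no VMS,
no logbooks, often not even a reliable vessel count. Yet they land about as
much fish for human consumption as the industrial fleet, and managing them
spatially requires knowing *where* the effort is. This package estimates a
gridded fishing-effort surface from the two quantities that are obtainable
in even the poorest data settings — counts of boats and the size of coastal
human populations — and, where landings records exist, turns that surface
into fleet-capacity diagnostics. It is aimed at fisheries scientists and
spatial ecologists working on coastal artisanal fleets.

## The method in brief

1. **Area of influence.** Buffer the coastline by the mean distance fishers
   travel to their grounds (default 75 km) and grid it into square cells
   (default 500 km², one panga's working area). All geometry is projected
   (UTM, meters).
2. **Kernel density surfaces.** Spread community populations and boat
   counts over the area of influence with a quadratic (Epanechnikov) kernel
   of bandwidth *h* = 75 km at 1 km² resolution, and average per cell. The
   default normalization conserves totals: boats stay boats.
3. **Allometry.** Fit the power law *boats* = *population*^m^ on log–log
   axes through the origin (+1 inside the logs to dodge log 0).
4. **Effort statistic.** Combine the two aliased proxies as their geometric
   mean, per cell:

   PFE = √(*boats* × *population*^m^)

   — boats per day per cell, adjusted by the local coastal population.
5. **Catch and capacity.** Where landings exist, fit the saturating curve
   *catch* = *K*·e^(−b/PFE) by resampled nonlinear least squares on
   log₁₀(x+1)-transformed data (500 draws of 250 cells; Mantel checks for
   residual spatial autocorrelation). Diminishing returns set in at the
   inflection PFE = *b*/2; multiplied by the cell count this gives the
   largest fleet the region supports without diminishing returns, and the
   comparison with the observed fleet measures overcapacity.

A synthetic-region generator (`pfe_scenario()`, `generate_region()`,
`generate_catch()`, `generate_tracks()`) emulates all required inputs —
coastline, lognormal community populations, power-law boat counts,
saturating landings, GPS tracks with embedded low-speed fishing events — so
the whole pipeline runs and is tested without any external data.

## Worked example

A full run on a synthetic Gulf-of-California-scale region:

```r
library(pfe)

sc     <- pfe_scenario(seed = 7)          # ~1,000 km coast, 150 communities
region <- generate_region(sc)

aoi  <- buffer_seaward(region$coastline, distance_km = 75)
grid <- build_grid(aoi, cell_area_km2 = 500)
grid
#> Analysis grid: 507 cells of 500 km2 (side 22.36 km), 52 x 14 lattice

pop   <- aggregate_mean(density_surface(region$communities, aoi, h_km = 75),
                        grid, output = "cell_total")
boats <- aggregate_mean(density_surface(region$boats, aoi, h_km = 75),
                        grid, output = "cell_total")

allo <- fit_power_law(boats, pop)         # through-origin log-log slope
allo
#> Allometric fit (post_kde, through origin): m = 0.3174 +/- 0.0037
#>   r2 = 0.937, F(1,506) = 7485.0, p = 2.27e-305, n = 507, offset = 1

surf <- compute_pfe(boats, pop, m = allo$m)
surf
#> PFE surface: 507 cells, m = 0.317, range [0, 34.3] boats/day/cell

catch <- generate_catch(surf, K_true = 2204, b_true = 47, sigma_c = 0.3,
                        seed = 8)
fit <- fit_catch_model(surf, catch, n_draws = 500, draw_size = 250, seed = 9)
fit
#> Catch-effort fit: catch = K * exp(-b/PFE) (500 draws of 250 cells)
#>   K = 2230.5 t/cell/yr (95% CI 1992.0-2469.0)
#>   b = 47.34 (95% CI 45.94-48.74), arithmetic r2 = 0.868
#>   excluded 18 cells with pfe = 0

capacity_report(fit, n_cells = nrow(grid), observed_fleet = 17839)
#> Fleet-capacity report
#>   plateau onset: 23.7 boats per cell (302 t/cell/yr)
#>   area of influence: 507 cells = 253,500 km2
#>   fleet capacity: 12,000 boats; observed 17,839 -> excess 5,839 (49%)
```

Reading the output: the resampled fit recovers the generating parameters
(*K* = 2204, *b* = 47) from noisy landings; catch gains flatten beyond
≈ 23.7 boats per 500 km² cell, where a cell yields ≈ 302 t/yr; across the
507-cell area of influence that caps the economically sensible fleet at
12,000 boats, so a fleet of 17,839 would be 49% over capacity. With the
published Gulf of California parameters (*K* = 2204, *b* = 47.0, 565
cells), `capacity_report(list(K = 2204, b = 47), 565, observed_fleet =
17839)` reproduces the study chain: inflection 23.5, 298 t, 282,500 km²,
capacity 13,277 pangas, excess 4,562 (34%).

`run_pipeline()` wires all stages together (including GPS-track validation
of PFE against observed per-cell fishing frequency), and a thin CLI over
the same functions lives at `inst/cli/pfe.R`
(`Rscript inst/cli/pfe.R simulate|grid|kde|allometry|compute|fit-catch|capacity|validate|run ...`).

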