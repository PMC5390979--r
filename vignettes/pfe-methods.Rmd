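---
title: "Predicted Fishing Effort: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicted Fishing Effort: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfe)
```

## The problem

Small-scale fleets land roughly as much fish for human consumption as the
industrial fleet, yet once their boats leave port they are effectively
untraceable: no VMS, no logbooks, often no vessel registry. Where fishing
happens, and how intensely, is exactly the information spatial management
needs and data-poor fisheries lack. This package implements a method that
estimates a spatial effort surface from two quantities obtainable almost
anywhere — the number of fishing boats and the size of coastal human
populations — and then uses landed-catch records, where they exist, to turn
that surface into fleet-capacity diagnostics.

## The model

The pipeline has five stages.

**1. Area of influence and grid.** The coastline is buffered by the mean
distance fishers travel to their grounds (default 75 km, taken from
upper-Gulf-of-California trip data) to delimit the fishable area, and an
axis-aligned grid of square cells (default 500 km^2, a conservative
estimate of the area worked by one panga) is laid over it. Only cells
intersecting the area of influence are kept. All geometry is handled in a
UTM projection, in meters.

**2. Kernel density surfaces.** Community populations, boat counts and
(optionally) landings are point observations; each point of value $u_i$ is
spread over its surroundings with the quadratic (Epanechnikov) kernel
$K(u) = \tfrac{3}{4}(1 - u^2)$ up to the bandwidth $h$ (default 75 km, the
same travel range) on a 1 km^2 lattice, and pixel densities are averaged
per grid cell. Two normalizations are provided. The default,
*mass-conserving*, scales the kernel as $\frac{2}{\pi h^2}(1 - r^2/h^2)$ so
that each point's bump integrates to its value over the disc $r \le h$:
cell totals then add back to the input total (boats remain boats), which is
a testable conservation contract. The *literal-1d* mode instead applies
the one-dimensional textbook normalization $\frac{0.75}{h}(1 - r^2/h^2)$;
the two surfaces are exactly proportional on the kernel support, so every
scale-free statistic downstream (allometric exponent, correlations) is
identical between them. Because the inputs are totals rather than sample
points, no $1/n$ factor is applied — the kernel spreads amounts, not a
probability density. No edge correction is applied at the raster boundary;
the fraction of kernel mass lost there is reported as a diagnostic and is
zero for interior points.

**3. Allometry.** Boat numbers scale with the population that supports
them as a power law, $\mathrm{boats} = k \cdot \mathrm{population}^m$. On
log-log axes this is a straight line; the intercept is forced through the
origin (no people, no boats, hence $k = 1$) and the slope $m$ is estimated
by OLS, adding 1 to both variables inside the logarithms to avoid
$\log 0$ in empty cells. The exponent is invariant to the logarithm base.
In the Gulf of California case study this through-origin post-KDE slope is
0.432, and 0.43 is kept available as a fixed fallback exponent.

**4. The effort statistic.** Counted boats and population-predicted boats
$\mathrm{population}^m$ measure the same underlying demand (they are
aliased, linearly related with slope 1), so they enter as a single
interaction term — their geometric mean:

$$\mathrm{PFE} = \sqrt{\mathrm{boats} \times \mathrm{population}^m}$$

in units of boats per day per cell, adjusted by the local population. The
geometric mean damps extremes (fishing camps with many boats and few
people; cities with many people and few boats) without skewing the
surface. No +1 offset enters here — the offset is purely a log-fit device —
so a zero in either input gives PFE = 0.

**5. Catch and capacity.** Where landings exist, total annual catch per
cell saturates with effort as

$$\mathrm{catch} = K e^{-b/\mathrm{PFE}},$$

with $K$ the maximum total catch per cell and $b$ a slope parameter. The
curve rises from 0, accelerates up to the inflection at
$\mathrm{PFE} = b/2$, then flattens towards $K$: past $b/2$ extra boats
buy progressively less catch. Multiplying $b/2$ by the number of cells in
the area of influence gives the largest fleet the region supports without
diminishing returns; comparing it with the observed fleet measures
overcapacity. With the Gulf parameters ($K = 2204$ t per cell per yr,
$b = 47$, 565 cells) the inflection sits at 23.5 boats per 500 km^2,
$K e^{-2} \approx 298$ t, and capacity at
$\lfloor 23.5 \times 565 \rfloor = 13{,}277$ pangas.

## Fitting the catch model

The fit deliberately mirrors a data-poor, spatially autocorrelated
setting:

* Landings are compared with PFE per cell after a $\log_{10}(x+1)$
  transform, which approximates normality and homogenizes the strongly
  funnel-shaped variance (dispersion grows with effort).
* The model is fitted in *transform-both-sides* form: nonlinear least
  squares of $\log_{10}(\mathrm{catch}+1)$ on
  $\log_{10}(K e^{-b/\mathrm{PFE}} + 1)$ (Levenberg–Marquardt, started from
  the log-linear approximation in $1/\mathrm{PFE}$). This is the
  multiplicative-error fit, and on noiseless data it recovers $(K, b)$
  exactly — an identity the test suite asserts at $10^{-6}$. A natural-log,
  no-offset mode is also provided; it is exactly linear in
  $1/\mathrm{PFE}$.
* To keep neighboring cells from pretending to be independent
  observations, the fit is repeated on 500 random draws of 250 cells
  (without replacement within a draw); the reported $K$, $b$ and 95%
  limits are the means of the per-draw estimates and per-draw Wald
  intervals. Per-draw residuals can be screened for spatial
  autocorrelation with a one-sided Mantel permutation test
  ($|r_i - r_j|$ against Euclidean centroid distance,
  $p = (1 + \#\{r^\ast \ge r\})/(n_{\mathrm{perm}} + 1)$), delegated to
  vegan's permutation machinery.
* Cells with PFE = 0 are excluded (the curve is undefined there) and
  counted; draws whose optimizer fails are dropped and more than 10%
  failures aborts the fit.

The per-draw confidence-interval method is a Wald interval from the
nonlinear fit; profile intervals would be disproportionate at 500 draws
and differ negligibly at draw size 250.

## Validation against GPS tracks

Where volunteered GPS tracks exist, fishing events are detected as maximal
runs of at least `min_points` consecutive between-fix segments at or below
`speed_max` — gear deployment and retrieval happen at low speed. The
thresholds are heuristics, deliberately mandatory-visible in every call;
the defaults (1 m/s ≈ 2 knots, 3 segments) suit gillnetting, and a preset
for trawlers (2 m/s, 5 segments) is included. Each event is reduced to the
midpoint between the run's first and last fix, events are counted per
cell, and observed frequency is regressed on PFE (OLS with intercept plus
Pearson correlation) within the tracked region only — extrapolating a
local tracking campaign to the whole area of influence would dilute the
comparison with structurally untracked cells. Cells outside the 95%
prediction limits are flagged rather than dropped; in the original study
the two outliers turned out to be spots where fishers stop to clean fish,
mimicking a fishing stop.

## The synthetic-region generator

`pfe_scenario()` and its generators exist so that every stage is testable
without any deposited data. They emulate, at Gulf-of-California scale:

* a 1,000 km sinusoidal coastline whose 75 km area of influence holds
  roughly 500 cells of 500 km^2 (the study's 565);
* ~150 coastal communities in the 5 km strip with lognormal populations
  (meanlog 8, sdlog 1.5 on the natural-log scale — median ≈ 3,000, a
  camps-to-cities spread totalling ≈ 1.4 million people, the Gulf's
  coastal total);
* boat counts $\mathrm{round}(\mathrm{population}^{0.43} e^\varepsilon)$,
  $\varepsilon \sim N(0, 0.3^2)$;
* landings $K e^{-b/\mathrm{PFE}} e^\eta$ with $K = 2204$, $b = 47$,
  $\eta \sim N(0, 0.3^2)$;
* vessel tracks departing port communities sampled in proportion to boat
  counts (so fishing frequency genuinely tracks local effort), cruising at
  5 m/s with embedded 0.5 m/s fishing drifts of known location and count.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: boat counts here are exact (real counts come
from over-flights and satellite images with detection error), landings are
generated from the same PFE surface that is later fitted (real landings
are recorded at offices, not where fish are caught, and carry reporting
error), community placement is statistically uniform along the coast, and
there is no temporal structure, no species composition, no bathymetry and
no protected areas. The synthetic recovery results certify the estimator
chain, not the realism of any particular coastline.

## Numerical choices and degenerate inputs

* **Grid anchoring and ties.** The grid is anchored at the minimum corner
  of the area-of-influence bounding box, making cell ids deterministic.
  A point exactly on a shared cell edge belongs to the cell with the
  lower (row, col) index; the same rule places raster pixels and events.
* **Cell intersection.** A cell is kept when its exact
  rectangle-to-polyline distance is within the buffer distance (a
  vectorized centroid prefilter decides all but the boundary band). With
  a land mask, a 7x7 lattice of sample points per cell decides whether
  any seaward part remains.
* **Projection.** Transverse Mercator by the standard series (WGS84,
  $k_0 = 0.9996$), accurate well under 1 m within a zone; round-trip
  displacement is asserted below 1 m in the tests. Study areas spanning
  more than one zone are projected in the centroid's zone with a warning.
* **KDE discretization.** Pixel membership is by pixel center; mass
  conservation for interior points holds to well under 1% at the default
  1 km resolution with h = 75 km.
* **Buffer areas** are measured by counting lattice pixel centers
  (default 1 km), an O(resolution) approximation used for reporting, not
  for any fit.
* **Degenerate inputs** error early and loudly: empty coastlines,
  non-positive buffers or bandwidths, fewer than 2 usable allometry
  cells, all-zero populations, constant residuals in the Mantel test,
  constant PFE in validation, draw sizes exceeding the usable cells,
  fleet capacity of zero in the overcapacity percentage.
* **Truncation, not rounding,** converts per-cell capacity into a fleet
  size ($23.5 \times 565 = 13{,}277.5 \to 13{,}277$), matching how the
  extrapolation is used; the overcapacity percentage is rounded to an
  integer with capacity as denominator.

## Open design points resolved here

* The textbook Epanechnikov normalization $\frac{1}{nh}K(u)$ is
  one-dimensional while the effort surface is two-dimensional, and the GIS
  tools historically used for such maps apply their own quartic kernel.
  The package makes the mass-conserving 2-D Epanechnikov kernel the
  default — conservation of totals is the property the rest of the
  pipeline relies on — and keeps the literal 1-D scaling as an explicit
  mode. The quartic kernel is out of scope.
* The catch model is sometimes described as "logistic"; the fitted form
  $K e^{-b/\mathrm{PFE}}$ is exponential saturation (it has the sigmoid's
  inflection but a different algebra). The formula, not the label, is what
  is implemented.
* Whether the Gulf case study's exponent 0.432 was computed with or
  without the +1 offset is not recorded; both are available (`offset = 1` default,
  `offset = 0` for strictly positive data). The offset induces a small
  attenuation on data far from zero, which is why the parameter-recovery
  tests fit with `offset = 0` on strictly positive simulated data.
* How the three boat surveys were spatially reconciled before averaging
  is not recoverable; surveys are averaged per cell after assignment.

## Problem sizes used by the test-suite simulations

Simulation-backed tests run at deliberately chosen sizes: catch-model
recovery at 20 replicates of ~500 cells with 100 draws of 250; allometric
recovery at 200 replicates of n = 500; Mantel size checks at 200
replicates of 100 points with 99 permutations plus exact enumeration at
n = 4; full-pipeline recovery at 20 seeded synthetic regions. These sizes
give the comparisons stable tolerances (bias bands of 10%, coverage
thresholds of 95%) while keeping the whole suite under a minute of
simulation time.

## Known limitations

PFE is a snapshot: it has no temporal dimension and is fishery-type
independent (separating gear types needs per-type boat counts and ranges).
The kernel ignores the coastline as a barrier, so effort can bleed across
narrow peninsulas. The capacity extrapolation assumes all cells share the
same fishing history, which overstates capacity wherever stocks are
already depleted. And the catch model's parameters are only as good as the
landings records behind them — misreported or unreported catch propagates
directly into $K$.
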