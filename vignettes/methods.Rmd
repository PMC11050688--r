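---
title: "Methods: decay modelling and risk-map construction in rotadist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decay modelling and risk-map construction in rotadist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotadist)
```

## The model and its assumptions

`rotadist` supports crop-rotation planning against pests that overwinter at
(or very near) the sites of their previous-year host crop and disperse to
new host fields in spring. The model system is the pea moth on grain and
green peas, but every parameter is exposed so the workflow transfers to
other site-faithful, mono- or oligophagous pests.

Percent seed infestation is modelled as exponential decay in the minimum
crop rotation distance,

$$ y = a \, e^{-MD / b}, $$

with $a$ the infestation (percent) at $MD = 0$ and $b$ the e-folding
distance (meters). $MD$ is the **edge-to-edge** Euclidean distance from the
current field polygon to the nearest previous-year host polygon; only the
nearest site enters the regression. (Some sources describe $b$ as an
inflection point; a pure exponential has none, and throughout this package
$b$ is the e-folding scale: predicted infestation falls by the factor
$1/e$ every $b$ meters.)

Assumptions worth making explicit:

* **Site fidelity.** Overwintering happens at the previous-year site; the
  relevant covariate is distance to that site, not regional abundance.
* **Source anonymity.** Only the existence of a previous-year site counts;
  its observed infestation intensity is not weighted in (collecting it
  area-wide every year would defeat the purpose of the tool).
* **Isotropy.** Dispersal is direction-independent; landscape barriers
  (forests, towns) are not modelled.
* **Single-season memory.** Only year $t-1$ sites are sources.

## Fitting: estimator, statistics, conventions

`fit_decay()` estimates $(a, b)$ by nonlinear least squares
(Levenberg–Marquardt via `minpack.lm::nlsLM`) with box bounds
$a \in (0, 100]$ (percent scale) and $b \in (0, 10^6]$ m (geographic
plausibility). Start values default to $a_0 = \max y$ and
$b_0 = \max MD / 2$, which are robust for decay data; both are overridable.
The iteration cap is 200.

Reported statistics follow the usual regression conventions, stated here
because they are often printed without definition:

* $SE(a), SE(b)$ from the estimated parameter covariance;
* p-values from $t = \text{estimate}/SE$ with $n - 2$ degrees of freedom
  (significance codes `***` < 0.001, `**` < 0.01, `*` < 0.05);
* $\mathrm{RMSE} = \sqrt{SSE / (n - 2)}$ — the degrees-of-freedom form;
* $R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - 3)$ with $R^2$ against the
  mean-only model.

Degenerate inputs fail loudly: fewer than 3 observations, fewer than 2
distinct distances, or no positive infestation (the green-pea situation —
mean observed infestation 0.11 % — where no curve is identifiable and the
fixed 500 m safety buffer applies instead).

### The percent domain and simulation studies

Observed infestation must lie in $[0, 100]$ and `fit_decay()` enforces
this. For parameter-recovery simulations there is a subtlety: with additive
Gaussian noise at the realistic residual scale (SD ≈ 9.1 % against an
intercept of ≈ 9.8 %), truncating simulated draws at zero raises the mean
of the far tail by $E[\max(0, \varepsilon)] = \sigma/\sqrt{2\pi} \approx
3.6$ percentage points. The least-squares fit responds by flattening, i.e.
biasing $\hat b$ upward; in a 100-replicate study ($n = 200$,
$MD \sim U[0, 3000]$) the nominal $\pm 2\,SE$ interval for $b$ then covers
the truth in only about two thirds of replicates, versus ~92 % under the
untruncated Gaussian error model the estimator actually assumes. The
package therefore runs its recovery study on untruncated noise
(`fit_decay(..., check_domain = FALSE)`), keeps truncation in the
*landscape* generator where physical observations must be non-negative, and
flags the truncation bias here as a known property of percent-domain data
rather than hiding it. The same mechanism will bias fits to *real* data
whose residual scale is comparable to the intercept — one reason the
published fits have low $R^2$ yet significant parameters.

## From fit to buffer distances

`derive_buffers()` maps group fits to three concentric distances:

| buffer | definition | grain-pea value |
|---|---|---|
| inner  | $b$ of the all-sites fit | 1261 m |
| middle | $b + SE(b)$ of the all-sites fit | 1560 m |
| outer  | $b + SE(b)$ of the untreated-sites fit | 1825 m |

Rounding is half-away-from-zero to whole meters. The untreated group
defines the outer (worst) case because remote sensing cannot reveal whether
a previous site was insecticide-treated, and the treated-sites scale
(619 m) would understate risk. A violated ordering inner ≤ middle ≤ outer
is a warning, not an error: it is data-dependent, not a code defect.

## Risk schemes and escalation

A `risk_scheme()` pairs strictly increasing band distances with strictly
decreasing risk classes drawn from a *ladder* — the ordered set of
admissible class values, linear (1, 2, 3, 4) or exponential (1, 2, 4, 8) or
custom. Defaults: grain peas 1261/1560/1825 m classed 4/2/1 on the
exponential ladder; green peas a single 500 m band. Design choices made
where the procedure was genuinely open:

* **Escalation counts sources, not zones.** A region covered by rings of
  *two or more distinct* previous-year sites moves **one** ladder step up
  from the maximum covering class, saturating at the ladder cap. One step
  is the literal reading of "next highest class"; a `per-source-step` mode
  ($k$ sources → $k - 1$ steps) is available for users who prefer
  overlap-count sensitivity.
* **Mixed-class overlaps escalate from the maximum** covering class: risk
  is at least that of the worse source.
* **Rings of one source never escalate against each other** — they are
  disjoint by construction.
* **The source polygon belongs to the innermost zone**: an unrotated field
  is the maximal-risk case.
* **Green-pea band class.** The single green-pea band carries class 2 on
  the shared exponential ladder, so overlapping green-pea buffers can still
  escalate; the choice of 2 (rather than 1 or 4) is a package convention.

`flatten_with_escalation()` implements this as a priority overlay: zones
are grouped by (class, band), higher classes claim territory first (ties
broken toward the inner band), and coverage-depth unions ($U_{\geq k}$ =
region covered by at least $k$ source footprints, built incrementally)
split each claimed region into its non-escalated and escalated parts. The
output is *flat*: zone interiors are pairwise disjoint and their union
equals the union of all input buffers.

## Geometry engine and numerical choices

All geometry is planar, in meters — which is why layers must carry a
projected meter-unit CRS, a declared geographic (degree) CRS is rejected at
the door, and `reproject_lonlat_layer()` (azimuthal-equidistant about a
local origin, geodesic distance/bearing on WGS84) is the explicit escape
hatch for lon/lat input. Distortion of that projection is negligible at
the ~30 km scale of a growing region but grows quadratically with distance;
for continental-scale data use a proper projected CRS upstream.

* **Boolean operations** (union, intersection, difference) use the Vatti
  clipper in `polyclip` under the even-odd fill rule. Every call shares one
  fixed integer snapping grid (origin 0, resolution $10^{-9}$ m). A common
  grid makes boundaries shared between the results of *different*
  operations coincide exactly; residual "T-junction" slivers between
  flattened zones stay below $10^{-7}$ m², comfortably inside the package's
  own $10^{-6}$ m² flatness tolerance. Per-feature area conservation of the
  overlay is relative $10^{-6}$ or better.
* **Buffering** uses polygon offsetting with round joins. Arcs are
  approximated by chords whose vertices lie on the true circle, with
  `segments = 16` chords per quarter circle by default; the maximal radial
  deviation is $d\,(1 - \cos(\pi/64)) \approx 0.0012\,d$ — about 2.2 m on
  the 1825 m outer buffer. Because the chord polygon is inscribed, buffer
  areas slightly *understate* the true disc; tests compare against the
  closed-form chord-polygon area, not $\pi d^2$.
* **Band-edge ambiguity.** A point whose true Euclidean distance to a
  source is within the arc deviation of a band edge can land on either side
  of the polygonal band boundary. Oracle-equivalence tests therefore probe
  random points but exclude those within 5 m of any band edge (distance
  computed exactly, per source); this checks the banding and escalation
  logic, which is the substance, without testing the documented arc
  discretisation.
* **Point-in-polygon** is even-odd over rings with boundary points counted
  inside; class lookups resolve boundary ties toward the higher class —
  the conservative call for planning advice.
* **Invalid geometry policy.** Self-intersecting input rings are repaired
  by even-odd resolution (the zero-distance-buffer fix of GIS practice);
  features still empty or zero-area afterwards are rejected with their id.
  If the repair does not change the ring structure, the original
  coordinates are kept so round-trips are bit-faithful.
* **Shapefile dialect.** Polygon records (type 5) are written with the
  shapefile ring-orientation convention (exterior clockwise) and a fixed
  10-character field-name mapping (`infestation_pct` → `INFEST_PCT`, …);
  GeoJSON uses RFC 7946 orientation. Ring roles on input are recovered by
  containment parity, so either convention reads back correctly.

## Risk queries

`query_risk()` clips each map zone to a chord-polygon disc around the
queried coordinates (default radius: outermost band distance + 500 m, so
the window always shows the full local risk neighbourhood), reports the
class at the point, and lists every previous-year site whose outermost band
reaches the point, with its edge distance and the compass bearing from the
query point to the site centroid (degrees clockwise from north). Bearing to
the centroid, rather than to the nearest edge point, is a presentation
choice — it is stable for compact parcels and tells the planner which way
the risk lies.

## The synthetic landscape generator

No parcel data ship with the package; `generate_fields()` emulates the
relevant features of administrative parcel polygons so every module is
testable offline:

* a circular region 30 km across (the approximate diameter of a monitored
  growing region);
* per year, `n_fields` mutually non-overlapping convex quadrilateral-ish
  parcels (randomly rotated rectangles with perturbed corners, convex
  hulled, rescaled to an exact target area) with areas uniform in 1–50 ha;
* independent placement per year, so some current-year fields fall near
  previous-year fields by chance and all distance bands get exercised;
* rejection sampling with a documented retry cap (200 × `n_fields` draws)
  and an explicit "infeasible packing" error.

`generate_observations()` draws infestation as
$\max(0, \min(100, a\,e^{-MD/b} + \varepsilon))$, $\varepsilon \sim
N(0, 9.1)$ by default — the published residual scale — with decay defaults
$a = 9.79$, $b = 1260.7$. All randomness derives from the spec seed
(per-year sub-seeds; the global RNG state is preserved), so repeated calls
are bit-identical.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: true parcel shapes (concavities, slivers,
holes), road/field adjacency structure, crop-rotation agronomy, spatially
correlated infestation, dispersal barriers, and any border-truncation
effects of administrative data availability.

## Problem sizes used by the test suite

Unit tests run landscapes of 6–20 fields; the oracle-equivalence check uses
10 landscapes × 10 fields × 1000 probe points against a brute-force
pointwise oracle; the recovery study uses 100 replicates of $n = 200$
observations. These sizes give stable verdicts for every property tested
while keeping the default suite fast enough to run habitually.

## Known limitations

* Escalation beyond two sources is a modelling convention (one step, or
  $k-1$ steps in the alternative mode); no field data constrain it.
* The decay fit ignores year and region effects and any covariates; site
  size was examined in the underlying monitoring and found uninformative.
* Truncation bias (above) affects fits to data whose residual scale is
  comparable to the intercept.
* The azimuthal-equidistant helper is for region-scale data only.
* Risk maps treat national/state data borders as if no sources lay beyond
  them; near borders the mapped risk is a lower bound.
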