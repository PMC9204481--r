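---
title: "Methods: ruptured-plaque morphometry and idealized lesion physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ruptured-plaque morphometry and idealized lesion physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqrupt)
```

## What the package computes

Culprit lesions that rupture and cause myocardial infarction occur both in
native coronary vessels (PR-NV) and inside previously stented segments where
neoatherosclerosis has formed (PR-NA). `plaqrupt` quantifies such lesions
from frame-level intravascular OCT annotations and compares the two
phenotypes, then builds a representative idealized pre-rupture geometry per
group and evaluates two physiology surrogates on it: endothelial shear
stress (ESS, the frictional force of blood on the lumen, Pa) and plaque
structural stress (PSS, the wall stress under luminal pressure, kPa).

The pipeline is: annotated pullback → culprit-lesion delimitation →
geometric metrics (MLA, lesion length, area stenosis, radius gradients) →
tissue morphometry (cap thickness, phenotype, tissue indices, rupture and
thrombus metrics) → group comparison tables → mean lesion specification →
idealized geometry → flow and stress summaries. A seeded synthetic-cohort
generator stands in for the clinical data, which were never deposited.

## Data model and conventions

An annotated cross-section (`frame_annotation()`) carries the lumen (either
a ≥36-sample angular radius profile or an area), optional EEM / stent /
neointima measurements, tissue arcs, a fibrous-cap thickness profile over
lipid, the rupture state (including the reconstructed pre-rupture lumen
border), four thrombus quadrant flags, and microchannel / cholesterol
crystal findings. Conventions fixed by the package, since annotation
software conventions vary:

* **Angles**: degrees, counter-clockwise, 0° at 3 o'clock. Arc widths are
  modular, so spans crossing 0° are exact.
* **Axial order**: frames are stored proximal → distal; frame 0 is the most
  proximal analyzed cross-section and "upstream" means lower `z`.
* **Spacing**: a pullback-level constant, 0.4 mm (0.375 mm for the Lunawave
  system), enforced to 1 nm.
* **MLA ties** break to the distal frame; frames exactly 2.5 mm from the
  MLA belong to the MLA-site segment. Both are configurable.

JSON is the canonical serialization (schema shipped under
`inst/extdata/pullback-schema.json`); CSV is a flat one-row-per-frame
export. Unknown JSON fields survive a round trip in each frame's `meta`
map.

## Diagnostic thresholds

All thresholds live in one `threshold_config()` object: TCFA cap ≤ 65 μm
(inclusive), lipid pool arc > 45°, macrophage extent > 20°, microchannel
diameter ≤ 300 μm in ≥ 3 consecutive frames, thrombus dimension ≥ 250 μm,
plaque burden ≥ 40% (native border rule), mean neointima ≥ 0.5 mm (in-stent
border rule), MLA-site half-length 2.5 mm, 90° quadrants, high ESS > 7 Pa,
superficial depth ≤ 200 μm. Two analysis conventions travel with them: the
30° shoulder tolerance and the MLA tie rule.

## Morphometry definitions and open choices

* **Tissue index** = 100 × (mean arc × tissue length) / (lesion length ×
  360): the percent of the unrolled lesion surface covered by the tissue.
  Published lesion tables sometimes print this quantity on another,
  undocumented scale; the package emits the formula-scale index as primary
  and a raw arc × length variant (degree-mm) alongside, and does not guess
  any further normalization.
* **Per-frame arc** of a tissue is the sum of its arc-span widths in the
  frame; **tissue length** is the count of frames carrying it times the
  spacing. How multiple pools in one frame combine is not standardized;
  summation is the package's choice.
* **Cap statistics** pool angular samples across frames with equal weight
  (not per-frame means). With equal samples per frame the two conventions
  coincide; pooling is the documented default.
* **Phenotype**: fibroatheroma iff any frame has > 90° of lipid; TCFA iff
  additionally the lesion-minimum cap ≤ 65 μm (boundary inclusive).
  Frame-level TCFA/ThCFA predicates are the per-frame analogues.
* **Rupture metrics**: sites are contiguous rupture-frame runs; depth is
  the largest radial excess of the cavity border over the reconstructed
  pre-rupture border (an annotated per-frame depth takes precedence); the
  arc is the mean over rupture frames of the per-frame widest rupture span.
* **Shoulder vs center** of a rupture has no standard definition: the
  package classes a site "shoulder" when the rupture-arc midpoint of its
  peak frame lies within 30° of a lipid-pool edge, flags the convention in
  the thresholds object, and keeps it configurable.
* **Prevalences** always carry count and denominator, because per-variable
  missingness makes bare percentages ambiguous in small cohorts; printed
  percentages are reproduced with half-up rounding to one decimal.

## Group statistics

`build_comparison_table()` mirrors clinical lesion tables: continuous
variables pass a Shapiro–Wilk screen (α = 0.05, both groups) and use the t
test when normal (pooled Student by default, Welch available), otherwise
the Mann–Whitney U test (exact for small untied samples). Binary variables
use the Pearson chi-square on the 2×2 counts **without** Yates continuity
correction — the variant that reproduces printed medication p-values
(0.006, 0.010, 0.019) from printed counts; with the correction they do not
match. p-values print to three decimals, "<0.001" below. No multiplicity
adjustment is applied, matching the reporting style the tables come from.

## Idealized geometry

`build_lumen_profile()` uses a two-piece cosine taper through (0, proximal
reference radius), (MLA position, minimum radius), (L, distal reference
radius). The family is a package choice — only "mean characteristics" are
specified by the source material — and is pluggable; its virtues are C¹
continuity, an exactly placed and exactly valued MLA, and zero slope at the
ends. `build_wall()` adds:

* a cap-thickness field equal to `cap_mean` away from the lipid pool,
  dipping to exactly `cap_min` at the pool crown, placed a quarter
  pool-length proximal to the pool center (snapped to the station grid) —
  encoding the observation that the thinnest cap sits proximal to the MLA;
* a lipid pool occupying the specified axial range × circumferential arc
  (the eccentric plaque is represented arc-limited so a half-model symmetry
  plane exists);
* an EEM envelope interpolated in area between the reference-site EEM and
  a remodeled EEM at the MLA (remodeling index 1.20 by default, the
  literature value for ruptured plaques where the EEM is invisible).
  Reference EEM areas are rarely annotated; when absent they are estimated
  from the reference lumen assuming a 25% reference-site plaque burden —
  mild disease typical of "normal-looking" reference segments. Where a
  thick neointimal cap would pierce this envelope, the EEM is pushed out
  with a 0.1 mm adventitial margin;
* for stented specs, strut rings (circular cross-section, 90 μm thickness)
  every 1 mm from z = 0, at the stent radius. The PR-NA stent diameter is
  not part of the printed record; it defaults to the group's mean reference
  lumen diameter and is configurable.

STL export is ASCII (text, watertight, with end caps); the station CSV
re-imports losslessly.

## Hemodynamics

Boundary conditions: steady laminar inflow of 1 ml/s with a parabolic
profile, blood as a Newtonian fluid (μ = 0.0035 Pa s, ρ = 1050 kg/m³),
100 mmHg at the outlet, rigid no-slip wall. Two solvers share them:

* **Quasi-1D** (`quasi1d_flow()`): the local Poiseuille closure, τ(z) =
  4μQ/(πR³), dp/dz = −8μQ/(πR⁴) integrated upstream from the outlet. Exact
  for straight tubes, slightly low in the throat of a stenosis.
* **Axisymmetric Navier–Stokes** (`axisymmetric_ns_solve()`): steady
  stream-function / vorticity finite differences on a boundary-fitted grid
  (axial station × radius normalized by the local lumen radius). Numerical
  choices: red-black SOR on the stream-function Poisson equation
  (relaxation 1.5); first-order upwinding of vorticity convection with
  under-relaxation 0.5; second-order (Jensen) wall-vorticity closure —
  the first-order Thom formula loses ~8% of wall shear on practical grids;
  outlet by zero axial gradient; convergence when the combined relative
  change of both fields drops below 1e-6. Wall shear stress is μ times the
  wall vorticity. Pressure integrates the axial momentum equation along
  the centerline, with the axis second radial derivative taken from the
  vorticity field (differencing near-axis velocities cancels to the size
  of its own truncation error). Mass flux is checked per station by
  Simpson integration of the reconstructed velocities; 0.5% is the
  acceptance bar. Default grid 121 × 25 for lesion-scale geometries;
  `mesh_convergence()` re-runs at 61×13 / 91×19 / 137×29 and requires
  < 2% change in τ_max.

The high-ESS fraction (> 7 Pa) is computed over the lesion **wall area**
(with the slope-corrected area element); an axial-length denominator would
be a few points different and the published definition is ambiguous. The
reference 3D computations this surrogates were strut-resolved with
millions of elements: their absolute values (e.g. 19.1 vs 11.0 Pa maxima,
0.95 vs 2.03 mmHg drops, 28.5% vs 9.0% high-ESS fractions) are not
reproducible at desk scale and are asserted only as orderings and ratios —
the quasi-1D stented/native τ_max ratio, (2.93/2.00)^{3/2} ≈ 1.77, matches
the published CFD ratio 19.1/11.0 ≈ 1.74 closely because both are
dominated by the MLA difference.

## Structural stress

Over the lipid pool the soft lipid carries negligible load, so the
superficial cap stress follows the Laplace membrane limit σ = pR/h with
the local luminal pressure from the flow solution (static outlet pressure
plus the flow pressure profile — the "total vs static" combination is not
documented in the source; the surrogate uses the local static pressure).
Away from the pool the wall is a Lamé thick-walled cylinder from lumen to
EEM. Consequences that the tests assert: the superficial maximum sits at
the thinnest cap, proximal to the MLA; it decreases with cap thickness and
increases with pressure and radius.

In the stented variant the lattice carries part of the ring tension: wall
stresses are scaled by a caging factor < 1. The default derives from the
strut geometry — a stiff strut unloads the wall over an axial influence
zone of about six strut thicknesses, leaving 1 − 6·t/spacing ≈ 0.46 of the
length (hence of the mean ring tension) wall-borne; the steel/tissue
stiffness ratio is so extreme that the share inside the influence zone is
negligible. The factor is configurable, as is the contact concentration
factor (default 2.5) applied to the deep-layer stress at strut rings,
which places the stented model's overall stress maximum in the strut
vicinity — the published location. The 5-parameter Mooney–Rivlin
coefficients for plaque tissue were cited, not printed, in the source;
the defaults (c10 = 18.9, c01 = 2.75, c20 = 85.72 kPa, c11 = c02 = 0) are
values in common use for fibrous arterial tissue, and every stress result
records the coefficients used. Absolute published stresses (95.1 / 38.8 /
58.7 kPa) are not reproducible with closed-form surrogates and are
asserted only as orderings and locations.

## Synthetic cohorts

`simulate_cohort()` draws per-lesion metrics from truncated normals
(lower bound 0 or a physical floor; upper bound 360° for arcs, 100% for
scores) whose underlying parameters are re-targeted by moment matching so
the realized mean/SD equal the printed ones despite truncation. Binary
features are Bernoulli draws at the printed incidences; rupture-site
longitudinal and circumferential classes follow the printed location
distribution. Constraints are resolved by redrawing the counterpart
variable — references upward until they exceed the MLA, minimum cap until
it is below the mean cap — so the clinically primary marginals (MLA, mean
FCT) keep the printed moments exactly; the references acquire a small
upward bias (~0.6 mm² at the study sizes) as the price of that choice.
Correlations between metrics are not published and are not simulated:
margins are independent. One knock-on effect worth knowing: matching the
printed mean ± SD of lesion length (14.8 ± 11.1 mm, floored at 2 mm) in
the stented group forces a strongly skewed distribution, so rank-based
tests can detect a shape difference between groups even though the means
barely differ.

`synthesize_pullback()` inverts the morphometry pipeline for one cohort
row: cosine lumen through the row's areas sampled at 0.4 mm, margin frames
with sub-threshold burden (so delimitation recovers the generator extent),
arcs painted at the row's mean values, a cap profile whose pooled minimum
and mean equal the row's cap statistics exactly, a rupture cavity with the
row's depth painted into the radius profiles, and a quadrant pattern that
inverts the thrombus score. Lengths therefore come back within half a
frame (0.2 mm), arcs and cap statistics exactly, and indices exactly on
the frame-snapped lengths. What the generator does **not** emulate: image
noise and reader variability, intra-lesion axial correlation of tissue
arcs, per-variable missingness, and metric correlations — so passing
round-trip tests demonstrates pipeline correctness, not robustness to
real annotation noise.

Problem sizes used by the test suite: cohorts of 56 + 24 for recovery
checks (the study sizes), 40–50 replicates for calibration rates, 10⁴ rows
for law-of-large-numbers checks, and the 121 × 25 default grid with a
61×13–137×29 refinement ladder for the solver; these keep the full suite
under a minute while leaving every rate estimate's Monte-Carlo error well
inside the asserted margins.

## Known limitations

* The surrogates are axisymmetric and strut-smeared: no strut wakes,
  recirculation, pulsatility, non-Newtonian rheology, or 3D eccentric
  lumen mechanics. Orderings between the native and stented models are
  meaningful; absolute stress/shear values are not comparable to 3D
  finite-element results.
* The Laplace cap stress diverges as the cap thins; at sub-50 μm caps it
  overestimates relative to a finite-thickness shell solution.
* Independent-margin synthesis understates the covariance structure of
  real lesions; comparison-table power estimates inherit that.
* The delimitation rules need an annotated EEM (native) or neointima
  (stented); frames lacking both can only enter a lesion through lipid.
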