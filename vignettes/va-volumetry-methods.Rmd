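---
title: "Vestibular aqueduct volumetry: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vestibular aqueduct volumetry: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vamorph)
```

## The measurement problem

The vestibular aqueduct (VA) is a thin, curved bony canal running from the
vestibule of the inner ear to the posterior cranial fossa, where it opens at
the operculum. An enlarged VA (EVA) is the most common radiologic inner-ear
malformation in children with sensorineural hearing loss, but the accepted
definitions are 2D: a caliper width on an axial CT slice, taken either at
the midpoint of the course (Valvassori, > 1.5 mm) or at both the midpoint
and the operculum (Cincinnati, midpoint > 0.9 mm and/or operculum
> 1.9 mm). Because the duct's caliber can vary strongly along its course —
centrally dilated ducts narrow toward both ends, funnel-shaped ducts flare
open only at the operculum — a fixed-point caliper can misrepresent the
duct's size. This package implements the volumetric alternative: segment
the duct from CT by Hounsfield thresholding, reconstruct its surface, and
use the enclosed volume (cutoff > 15.4 mm³) as the diagnostic quantity,
alongside the 2D criteria and the statistical machinery needed to compare
them.

Because no clinical images are distributed with studies of this kind, the
package's first-class citizen is a synthetic temporal-bone phantom with
analytic ground truth. Every stage of the pipeline is validated against
quantities that are known exactly by construction.

## The phantom

A synthetic ear consists of:

* a **VA tube** whose centerline is a planar circular arc of length $L$
  (default 10 mm) and bend radius $R_b$ (default 15 mm), whose plane is
  tilted by a small angle (default 10°) from the axial plane. Any tangent
  of a curve in a plane tilted by $\tau$ stays within $\tau$ of the axial
  plane, so axial caliper widths stay close to true diameters, as in
  clinical practice where the VA runs roughly axially;
* a **radius profile** $r(s)$, $s \in [0,1]$, a monotone (Fritsch–Carlson)
  cubic through three control radii at the vestibule exit, midpoint, and
  operculum. Monotone interpolation guarantees $r(s)$ never overshoots the
  control radii, so the three published archetypes — uniform, funnel,
  central dilatation — are exactly representable and the true diameters at
  the two caliper landmarks are simply $2r(0.5)$ and $2r(1)$;
* an **ellipsoidal vestibule** (semi-axes 2.5 × 1.5 × 1.5 mm) attached at
  the exit so that the exit plane is tangent to it: the vestibule then lies
  entirely on its own side of the plane and never contaminates the VA
  volume. The cochlea is omitted by default (it plays no role in VA
  morphometry) and available behind a flag for visual realism.

The analytic truth volume is $\int_0^L \pi r(s/L)^2\,ds$ by adaptive
quadrature (relative tolerance $10^{-9}$). The curvature correction for a
bent tube is neglected; with $R_b$ forced above the maximal tube radius the
error is below 2%, and the self-consistency tests (digitized truth versus
quadrature at 0.2 mm spacing, within 5%) bound it empirically.

Voxel intensities are $\mathrm{HU} = \mathrm{bone} + (\mathrm{fluid} -
\mathrm{bone}) \cdot \mathrm{coverage}$, where coverage is the fraction of
the voxel inside the lumen, computed exactly for interior/exterior voxels
and by $3^3$ supersampling for boundary voxels; Gaussian blur (default
$\sigma$ = 0.3 mm) and seeded Gaussian noise (default 40 HU) follow.

**HU levels are a design choice, not clinical dogma.** The segmentation
protocol uses a fixed band of −1024 to 700 HU. For a phantom evaluated by a
*fixed* threshold, the threshold should sit at the fluid/bone half-maximum:
otherwise the segmented boundary is systematically offset by a fraction of
a voxel and the phantom measures its own HU choice rather than the
geometry (with fluid at 30 HU and bone at 1800 HU the offset is ~0.12
voxel, a −3% volume bias on a 1.5 mm-radius duct). The defaults are
therefore fluid 30 HU, bone 1370 HU, placing 700 HU exactly at
half-maximum — a plausible petrous-bone value, and config-exposed like
every other HU parameter. A second benefit is that Gaussian blur preserves
the half-maximum level set of a flat interface, so mild blur does not bias
the segmentation either.

## Cohort simulation

Group sizes default to the study composition this package emulates: 42
controls and 56 malformed ears (18 cochlear hypoplasia, 12 incomplete
partition type I, 11 type II, 15 EVAS). One published table reports 43
controls while the accompanying text says 42; the default uses 42.

Per group, the midpoint and operculum diameters are drawn from truncated
log-normal distributions: the support is the published per-group min–max
range (zero minima floored at 0.05 mm — a strictly zero-caliber duct is
not representable by a positive-radius tube), the log-scale comes from the
published interquartile ratio, and the log-location is solved numerically
so that the *truncated* median equals the published median exactly. The
three radii of one ear share a latent log-normal factor ($\rho = 0.7$): an
enlarged duct is enlarged along its whole course, which is both
anatomically sensible and what keeps the simulated volume distributions of
controls and EVAS ears apart, as observed clinically. Course length
(median 10 mm, range 8–13 mm) and exit diameter (median 0.5 mm — the
isthmus at the vestibule is uniformly narrow) are not published as tables;
their defaults are package choices. Calibration deliberately targets
diameters, not volumes: the source study reports two different control
median volumes (5.8 and 5.2 mm³) in different sections, so volumes are
left to emerge from the geometry.

Archetype tags on sampled ears describe the dominant drawn shape (central
dilatation when the midpoint radius exceeds both ends, funnel when the
operculum exceeds the exit, uniform otherwise); they are generator
metadata, never diagnostic logic.

## Segmentation

`isolate_va()` makes the semi-automatic clinical protocol explicit and
reproducible: threshold the HU band (inclusive at both ends — the most
literal reading of a stated range, and boundary-testable), label connected
components under 26-connectivity (thin anisotropically sampled ducts
fragment under 6-connectivity), keep the component containing the seed
click, and clip with two planes: the vestibule-exit plane and the
operculum end plane, both carried in the landmark sidecar with normals
pointing away from the VA. Published descriptions do not state how the VA
was truncated against the vestibule; the exit plane here is a declared
reconstruction of that manual step, not a claim about the original
procedure.

## Morphometry conventions

Several choices that 2D measurement papers leave implicit are pinned down
here:

* **Centerline.** A medialness-weighted geodesic: the chamfer distance
  transform of the mask defines a medialness field, and the centerline is
  the minimum-cost voxel path (cost per step $\propto$ step length /
  (boundary distance)²) between the foreground voxels nearest the two
  landmarks, smoothed by a 3-point moving average and arc-length
  parameterized. This is the standard robust alternative to topological
  thinning for tubular structures: it cannot produce spurs, and its
  endpoints are anchored at the anatomical landmarks.
* **Caliper direction.** Diameter is measured on the axial slice,
  perpendicular to the in-slice projection of the local course direction —
  the direction in which an oblique cylinder's section is exactly $2r$
  regardless of obliquity. Interior tangents come from a ±0.5 mm central
  difference along the centerline.
* **Width definition.** The distance between the outermost 0.5-crossings
  of the interpolated binary field along the measurement line (sampling
  step = min in-plane spacing / 4), so a centrally dilated duct with small
  lumen irregularities measures its full extent; a `first_crossing` mode
  is available.
* **The operculum is measured at the aperture.** At the terminal voxel the
  axial slice cuts only a partial cross-section of the obliquely ending
  duct, and interpolation against the emptiness beyond the end-cap erodes
  the boundary. The caliper line is therefore pulled 0.6 in-plane voxels
  inside the cap, and the field is *mirrored* across the operculum plane
  while sampling — the natural boundary treatment when measuring a
  structure at its own anatomical truncation. The operculum landmark plane
  supplies both the mirror and the measurement direction; a landmark-free
  fallback uses the principal axis of the trailing 1.5 mm of centerline.
  The 0.6-voxel constant was fixed against the analytic-truth phantom
  battery during method development.
* **Volume.** Both voxel-counting and surface-mesh volume are computed.
  The mesh comes from marching tetrahedra on the Freudenthal subdivision
  (watertight by construction, orientation fixed outward), and its
  enclosed volume is the headline "VA volume"; voxel and mesh volumes
  agreeing within 15% is also the package's internal resolution check —
  records violating it, or with a midpoint width under two in-plane
  voxels, carry flags instead of failing silently.

## Simulated raters

Two blinded raters are modeled as independent perturbations of the manual
interactions: every point landmark displaced uniformly within a 0.3 mm
sphere (the sphere jitter is applied to all point landmarks, not only the
seed, so that the clip planes — and hence the volume — acquire a small,
realistic inter-rater variance), the caliper line rotated by up to ±10°,
and the measurement slice offset by one slice index. A rater whose seed
click misses a narrow lumen re-clicks closer to the duct, then at the
aperture where the duct is widest; a duct that is nowhere identifiable at
the image resolution is recorded with zero widths and volume (clinical
tables report 0.0 mm minima for exactly this reason) and flagged.

## Statistics

The battery mirrors standard nonparametric practice for small clinical
groups: tie-corrected Kruskal–Wallis (with an exact permutation p-value
computed alongside whenever the pooled sample is at most 8), Dunn's
pairwise z tests with Bonferroni multiplication (the convention of common
biostatistics software; Holm and none available), Hodges–Lehmann location
differences with the Moses order-statistic CI (a reconstruction — the
emulated analysis does not state its "median difference" estimator),
Spearman correlation (exact permutation p for n ≤ 9, t-approximation
above), ROC with the Youden-maximal cutoff under a strict-greater positive
rule (matching the "> 15.4 mm³" phrasing of volumetric cutoffs; ties break
toward sensitivity, then the smaller threshold), and Clopper–Pearson
binomial intervals. ICC is fixed to ICC(2,1) — two-way random effects,
absolute agreement, single measures — the conservative standard for two
fixed-instruction raters rating all subjects; the published source names
only "ICC". Reported sensitivity/specificity CI bounds in the emulated
study are not exactly reproduced by any standard exact method at the
stated group sizes; no method is asserted as theirs.

Five-number summaries use `quantile(type = 7)` (inclusive linear
interpolation).

## Problem sizes and what the tests show

The validation suite runs phantoms at 0.2 mm isotropic spacing (the fine
end of the clinical in-plane range), the full synthetic study at the
published group sizes, cohort calibration checks at 200 ears per group
(truth values only — no rasterization), and the rater experiment at 20
replicate 15-ear cohorts. These sizes were chosen so the whole suite
completes in a few minutes on a laptop core while keeping every stochastic
check comfortably powered.

Passing tests demonstrate that the pipeline recovers *known synthetic*
geometry: digitization, partial volume, blur, noise, rater jitter, and
cohort-level statistics behave as designed. They do not demonstrate
clinical accuracy on real temporal-bone CT, which additionally involves
beam hardening, inhomogeneous bone, anatomical neighbors of the VA
(posterior semicircular canal, jugular bulb), oblique acquisitions, and
genuinely ambiguous duct boundaries. The phantom deliberately omits all of
these (axis-aligned geometry only; no artifact modeling), so package
results upper-bound, rather than estimate, clinical performance.

## Known limitations

* Ducts thinner than about two voxels in radius are at the partial-volume
  limit: volumes are underestimated and records are flagged; end-to-end
  volume recovery within 10% holds for ducts resolved at ≥ 2 voxels
  radius. This mirrors the clinical situation — sub-voxel VAs are
  radiologically invisible.
* The operculum caliper has a residual negative bias (a few percent) for
  ducts flaring steeply right at the aperture, because any axial
  measurement a finite distance inside the cap samples a slightly
  narrower section.
* Volumes carry a small negative bias (≲ 1% for well-resolved ducts) from
  measuring the 0.5-level of the digitized binary field.
* Indices are 1-based with voxel centers at `origin + (index-1)*spacing`,
  the R-native convention; rotated (oblique) volumes are rejected
  explicitly rather than resampled.
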