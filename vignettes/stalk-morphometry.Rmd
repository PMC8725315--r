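---
title: "Cross-section morphometry of plant stalks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-section morphometry of plant stalks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stalkmorph` turns a calibrated RGB image of a stained stalk cross-section
into the four phenotypes most strongly associated with stalk bending
strength — major diameter, minor diameter, mean rind thickness and vascular
bundle count — plus region areas and exportable boundary geometry. This
vignette explains the measurement model, the tunable parameters, the
synthetic phantoms used for validation, and the numerical and design
choices, so a maintainer can see not just *what* the code does but *why*.

## Measurement model and assumptions

The pipeline assumes one stained section per image, imaged roughly
perpendicular to the stem axis, with lignified tissue (rind, bundles)
substantially darker than pith and background after staining. The spatial
calibration is a single isotropic factor in px/mm, as produced by imaging a
scale rule at fixed magnification; anisotropic pixels are rejected rather
than silently averaged. Image coordinates are 0-based, x rightward,
y downward, at pixel centers; every module shares this convention and only
the world-coordinate export flips y.

**Binarization.** Two methods, dispatched on the declared plant type but
overridable:

* *Otsu* (hollow stems): the global threshold minimizing within-class
  intensity variance over the 8-bit histogram. Ties are broken toward the
  smaller threshold so the result is deterministic; the implementation
  maximizes between-class variance via cumulative sums, and the test suite
  checks it against an exhaustive search over all 256 thresholds. Hollow
  sections are cleanly bimodal (ring vs background), which is why the
  global method suffices.
* *Local adaptive* (pith-filled): a pixel is tissue when its value does not
  exceed `local_mean × (1 − 0.3 × sensitivity)`, with the local mean taken
  over a square window (summed-area table, reflective padding). Pith-filled
  sections have three intensity populations (rind/bundles, pith,
  background) whose local balance varies across the image, so a local
  threshold is more robust than a single global split.

The adaptive window defaults to **half of the image's short side**
(`window_fraction = 0.5`). This is deliberately large: a local-mean window
must be wider than the rind, because deep inside a region thicker than the
window the local mean equals the region's own intensity and the interior
stops being classified as tissue — for thick-rinded sections (rind up to a
third of the radius) a narrow window visibly hollows out or even
disconnects the rind ring. With a window of half the frame, every rind
pixel's neighborhood still samples pith and background, while enough
locality remains to absorb illumination gradients (the test suite checks
98% mask agreement under a ±10 gray-level gradient). `sensitivity = 0.5`
maps to the classic "threshold at 85% of the local mean" rule;
`sensitivity = 0` degenerates to the plain local mean and 1 to 70% of it.
The comparison is `≤` rather than `<` so that re-thresholding an
already-binarized (0/255) rendering is the identity even where the local
mean is 0.

**Segmentation.** The whole section is the largest 8-connected foreground
component with all enclosed holes filled; the pith (or lumen) is that
component's largest enclosed background hole, with its own enclosed islands
(the bundles) filled back in so the pith support is a single region.
Foreground uses 8-connectivity and holes 4-connectivity — the standard
complementary pairing that avoids topological paradoxes. A broken rind ring
(no enclosed hole) is an error pointing at the threshold settings, not a
silent repair.

**Smoothing.** Segmentation of real stained sections reveals small bright
clusters inside the rind and dark clusters in the pith. These are cleared
by *area-gated* operations: foreground components at or below
`speck_area_frac` of the whole-section area are removed, and enclosed holes
at or below `hole_area_frac` are filled (defaults 0.001 — large enough to
clear artifact clusters, two orders of magnitude below any real pith or
lumen). Both limits scale with the section, so settings transfer across
magnifications. Morphological opening is available (`opening_radius`, disc
element) but **off by default**: erosion-based smoothing shifts boundaries
inward and would bias every distance measurement, whereas area-gated
removal touches no retained boundary pixel. The pipeline computes the
area reference from the filled largest component of the raw mask, smooths
the binary image, and only then segments; this keeps the smoothing
thresholds well-defined before a clean segmentation exists, and the result
is idempotent (smoothing twice equals once, asserted in tests).

**Boundary tracing.** Outer and inner rind boundaries are traced with
Moore-neighbor tracing (Jacob's stopping criterion) at pixel centers,
closed, and canonically oriented (positive shoelace area in image
coordinates). Tracing at pixel centers places the polygon about half a
pixel inside the true continuous contour on each side; because the outer
boundary of the rind and the boundary of the pith shift the same way, the
rind-thickness errors largely cancel, and the residual diameter bias is
under a pixel (quantified below).

**Diameters.** Two conventions, selected by `diameter_convention`:

* `axis-endpoint`: chords through the section centroid along the image
  axes — rays at 0°, 90°, 180°, 270° intersected with the outer boundary,
  outermost crossing per ray; the larger chord is the major diameter. This
  matches measuring the section in the orientation it was imaged. The rays
  are anchored at the foreground centroid (not the bounding-box center),
  which is stable under boundary noise.
* `feret`: maximum Feret diameter and minimum Feret width via rotating
  calipers on the convex hull — the parallel-jaw caliper analogue, and
  rotation-invariant. Feret major ≥ axis-endpoint major always; the two
  coincide (within a pixel) for axis-aligned sections.

Major/minor are assigned by magnitude, not axis identity, since stalks are
imaged in arbitrary orientation.

**Rind thickness** is the directed mean: for every outer-boundary vertex,
the shortest Euclidean distance to the inner *polyline* (point-to-segment,
not vertex-to-vertex, so the result does not depend on vertex density), and
then the arithmetic mean over all outer vertices — every vertex, not a
subsample. The symmetric (bidirectional) mean was considered and rejected:
measuring from the outer boundary matches the field's "shortest segment
from the outside in" reading and keeps the statistic interpretable as a
per-outer-point thickness profile. Touching or crossing boundaries are an
error.

**Bundles.** Dark components inside the pith are accepted when their area
lies in `[min_area, max_area]` (defaults 25 px and 2% of the pith area) and
their circularity `4πA/P²` is at least `min_circularity` (default 0.3,
permissive since stained bundles are only roughly circular). Components
that are too large or too ragged are reported as *merged-cluster
candidates* rather than guessed at: the field practice is to resolve
merged bundles by hand, so the package replaces interactive clicking with a
plain-text edit list (`remove,<id>` / `add,<x>,<y>`) that is scriptable and
testable. Bundle counts after edits always equal
`auto − removals + additions`; the edit is intentionally not idempotent
(re-removing a gone id is an error, which catches stale edit files).
Detection is restricted to the pith; rind-embedded bundles of hollow
species are out of scope, and hollow sections carry manual point counts
only.

**Geometry export.** Boundaries (and traced bundle outlines) are converted
to world millimeters with the origin at the section centroid and y up — the
natural frame of an FE sketch plane, chosen so the sketch centers at the
origin. The emitted script follows the Abaqus/CAE scripting sequence
(model, per-sketch sheet size, closed `Spline` command with the full
coordinate list at fixed 6 decimals, rename). The sheet size is the
smallest power of 10 exceeding twice the bounding-box diagonal — any value
comfortably larger than the part works, and a power of 10 keeps scripts
tidy and deterministic. Splines destined for the FE script are simplified
with Douglas–Peucker at `decimation_tol` (default 0.01 mm, about a pixel at
typical calibrations) so command lists stay tractable; neutral formats
(CSV/GeoJSON/SVG) export at full resolution. The script is validated by a
companion parser (exact round trip at printed precision), not by executing
the commercial package.

## Synthetic phantoms: what they emulate, and what they do not

`make_phantom()` renders a stained section as hard-edged regions: a dark
elliptical rind annulus on a light background, enclosing either a lighter
pith with dark circular bundle disks (pith-filled) or a background-filled
lumen (hollow); light speck ellipses inside the rind and dark ones inside
the pith mimic the artifact clusters segmentation reveals in real images;
i.i.d. Gaussian noise (clipped) is added per pixel and channel.
Anti-aliasing is deliberately off so that pixel-level ground truth is
exact — soft edges would add a sub-pixel tolerance confounder to every
recovery test. Noise after drawing, rather than textured tissue, is the
simplest model that genuinely exercises thresholding. Class intensities
must be separated by at least `4 × noise_sd` so the thresholding problem is
well-posed by construction. Specks are kept one pixel clear of region
boundaries and bundles, so their removal restores the clean mask exactly.
Bundles are placed by rejection sampling with a 10,000-draw cap; placement
failure is an error, never a silently reduced count.

Ground truth is analytic: Feret diameters of an ellipse are `2a`/`2b`
regardless of rotation; axis-endpoint chords follow from the ellipse radius
along the image axes in closed form; areas are `πab`; rind thickness is the
mean shortest gap between the continuous outer and inner ellipses, computed
by dense arc-length sampling of the exact curves (vertex-to-vertex at 6,000
inner samples, a quadrature error orders of magnitude below a pixel) —
independent of the raster pipeline and of its C++ distance primitive.

What passing the phantom suite does **not** show: phantoms have uniform
tissue intensities, elliptical boundaries, circular bundles and no
sectioning damage. Real sections add texture, stain variability, oblique
cuts, torn rinds and out-of-round shapes; accuracy there is bounded by
staining contrast and should be spot-checked with the overlay images
(`write_overlay()`), which is exactly what the semi-automatic edit workflow
is for.

## Study conditions and problem sizes

The validation sweep (`phantom_sweep_specs()`, used by both the acceptance
tests and `scripts/acceptance.R`) draws 50 phantoms: outer diameters 2–20 mm
at 80 px/mm, aspect ratios 0.8–1 (stalks are near-round), rind thickness
10–35% of the semi-minor axis, random rotations, speck noise on, and — for
the 70% of phantoms that are pith-filled — bundle counts up to 40, capped by
a packing-density bound (half the random-sequential-adsorption limit) so
rejection placement at the required separation always succeeds. Bundle radii
scale with the section (4–5% of the semi-major axis, at least 4 px): this
keeps bundles above the detector's minimum area and above the speck-removal
limit at every size, with minimum separation `2·r_max + 5` px so planted
bundles are always resolvable as distinct components. The 80 px/mm working
resolution keeps the full sweep under two minutes while leaving the
smallest sections (160 px across) comfortably above the tracing floor.
The generator derives per-phantom seeds as `(31·seed + 7919·i) mod 2^31−1`,
so a batch is reproducible from one integer and each phantom is
individually reproducible.

Measured on this sweep (recomputed by `scripts/acceptance.R`): diameter
mean absolute relative errors are well under 1% in both conventions, rind
thickness within 5% and well under 1.5 px equivalent, bundle counts exact,
and measured-vs-true R² effectively 1 for every phenotype — the synthetic
analogue of the caliper-agreement correlations used to validate the method
on physical stalks.

## Numerical choices and degenerate inputs

* Otsu ties break to the smaller threshold; constant images are a
  descriptive error.
* The adaptive window is forced odd and must be at least 3 px.
* Contours with fewer than 8 boundary pixels, collinear convex hulls, rays
  that miss the boundary (non-star-shaped outlines), and intersecting
  rind boundaries are all errors, not NaNs.
* `fill_holes` never shrinks and `remove_specks` never grows the
  foreground (property-tested); opening is idempotent.
* Douglas–Peucker anchors at the two mutually farthest hull vertices of the
  closed polyline, so closure is preserved and the tolerance bound holds on
  both chains; tolerance 0 is the identity.
* All exports are deterministic functions of their inputs (byte-identical
  reruns); the measurement path itself uses no randomness — every random
  draw in the package lives in the phantom generator, under `withr`-scoped
  seeds that leave the caller's RNG untouched.
* Batch processing sorts files lexicographically and records per-image
  failures (with the failing stage) in the manifest instead of aborting.

## Known limitations

* One section per image; multi-stalk frames are out of scope.
* The calibration is isotropic; calibrate per magnification.
* Merged bundle clusters are flagged, not split — watershed separation is
  deliberately left to manual edits.
* The FE script is validated by round-trip parsing, not by execution in the
  commercial preprocessor.
* Phantom realism is geometric, not photometric (see above); treat phantom
  accuracy as an upper bound on real-image accuracy.
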