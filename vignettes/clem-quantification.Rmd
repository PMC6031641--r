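---
title: "Quantifying particle tags in electron micrographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying particle tags in electron micrographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clemquant)
```

## The analysis problem

Genetically encoded electron-dense tags (ferritin particles recruited to a
protein of interest by chemically induced dimerization) appear in
transmission EM sections as ~7 nm dots. Turning those dots into biology
requires a chain of quantitative steps: deciding which cellular compartment
each particle occupies, testing whether a compartment is labeled above
chance, characterizing how far a detected particle can sit from the protein
it marks (the labeling resolution), and mapping particles onto a common
reference structure such as a clathrin-coated pit (CCP). `clemquant`
implements that chain for annotation data — segmented membrane polylines and
particle centres — rather than raw pixels, because EM particle picking and
membrane segmentation in this workflow are manual.

All geometry is planar and per-section: each micrograph is a 2-D section of
known thickness (default 70 nm, the conventional ultrathin serial-section
thickness), and volumes are areas multiplied by that thickness.

## Compartment model

A membrane contour is an ordered polyline in nm. Its cytoplasmic side is a
per-contour convention (`"left"` of the traversal direction by default). A
point is:

* **extracellular** if its nearest membrane point lies on the non-cytoplasmic
  side;
* **membrane-proximal** if cytoplasmic-side and within the zone width of the
  membrane (50 nm by default, closed interval, so a particle at exactly
  50 nm is proximal);
* **coated** if, in addition, the *foot* of its closest approach (the
  nearest point on the polyline, expressed in arc length) falls inside a
  coat interval; otherwise **uncoated membrane-proximal**;
* **cytoplasm** otherwise.

Coat and pit marks are stored as arc-length intervals rather than vertex
flags so they survive resampling of the polyline. The foot-position rule is
the simplest rule consistent with "coated membrane-proximal region"; an
angular-sector rule would differ only for particles near coat edges.

Region *areas* are computed by midpoint-grid quadrature: the frame is tiled
at a `grid_nm` spacing (default 4 nm) and each cell centre is classified
with exactly the rule above. This makes areas and particle counts mutually
consistent by construction, conserves the frame area exactly, and handles
arbitrary contour shapes (including self-approaching buffers) without
polygon clipping. Against analytic oracles the quadrature is accurate to
well under 1% for a straight membrane band and under 2% for a curved
(half-annulus) coated band at the default spacing. Cost grows as
(frame/grid)^2; 4 nm is a good compromise for 1-2 um frames.

Densities divide pooled counts by pooled volumes (pooling over the images of
a condition or experiment first, then dividing), matching how labeling
tables report per-experiment totals. Per-image densities are only used for
group comparisons (one-way ANOVA with Tukey HSD), mirroring scatter-dot
presentations.

## Stereological labeling test

The relative labeling intensity (RLI) machinery follows the point-counting
approach of Mayhew and Lucocq for immuno-EM. An 8 x 6 line grid is overlaid
with its outer lines on the image perimeter, leaving 6 x 4 = 24 interior
intersections per image as test points; the grid is deterministic because
the perimeter registration fixes it. Each point is classified with the same
compartment rule as particles; fractions are pooled over an experiment's
images, renormalized over the intracellular compartments, and scaled to the
total observed particle count, so expected counts sum exactly to the
observed total. The test statistic is Pearson's chi-squared with Yates'
continuity correction on the 2 x 2 {observed, expected} x {cytoplasm,
coated} table, df = 1 — this construction reproduces published
labeling-table statistics from their printed counts to within the rounding
of 1-decimal expected values. Uncoated membrane-proximal counts are reported
but not tested.

A dedicated null simulator (`simulate_rli_null`) generates experiments in
which particles are placed uniformly over the pooled intracellular area of
randomly framed scenes, to measure the test's operating characteristics.
Its scenes are designed to be statistically faithful to how micrographs
frame a cell: thin cell profiles (lamellae) whose intracellular space lies
entirely within the span covered by the interior grid rows (the 24-point
grid never samples the outer half-spacing margins of the frame), membrane
depths uniform over whole grid periods, and pits drawn from an
x-stationary hard-core process over the full frame width so that — as in
real images — a pit can sit anywhere, including cut by the frame edge.
Without these properties, scene inhomogeneities beat against the
deterministic grid and masquerade as labeling bias; under them, pooled
observed/expected ratios are 1 within simulation error.
Two properties of the deterministic-grid design matter here and are worth
knowing when interpreting results on real data:

* with 24 points per image, *per-image* point fractions are coarse; the
  pipeline therefore always pools points over an experiment before scaling;
* because the expected row is derived from several-fold more grid points
  than there are particles, the contingency-table construction attributes
  more variance to the expected counts than they actually have. Together
  with the continuity correction this makes the test conservative at
  published count scales (observed type-I error below the nominal 5% in our
  null calibration). Enrichment calls from this test are therefore, if
  anything, understated — an acceptable property for a labeling claim.

## Labeling-resolution model

The tag is modelled as a membrane-anchored linker whose particle sits at a
conformational length L between 7 and 18 nm (continuous uniform by default;
a discrete number of length states can be configured), never beyond the
22 nm fully extended colinear arrangement. Orientation is drawn uniformly
in solid angle within a cone about the membrane normal ("membrane
exclusion": the tag cannot penetrate the membrane half-space), with a
45-degree half-angle by default as a steric compromise between linker
flexibility and the bulk of the 12 nm particle against the membrane;
hemisphere-uniform and strictly perpendicular laws are available. Each draw
places the particle in 3-D relative to an anchor at uniform depth in a
70 nm section and is accepted only if the particle centre falls inside the
section; the recorded quantity is the in-plane perpendicular distance to
the membrane trace, which for a membrane perpendicular to the section plane
is L cos(theta).

Within this family there is a genuine trade-off: narrower cones raise the
median detected distance but narrow the distribution, and no half-angle
reproduces both a ~9.5 nm median and a ~10 nm full width at half maximum
simultaneously. The default prioritizes the *width* — the quantity that
summarizes labeling resolution — landing the FWHM near 9-10 nm with a
median near 10.5 nm. The FWHM is computed on a Gaussian kernel-density
estimate (Silverman-type bandwidth, recorded in the output) between the
outermost half-height crossings, which avoids histogram bin-edge
sensitivity; for a plateau-topped density the outermost-crossing rule is
also robust to where the sample mode lands on the plateau.

Per-particle SNR is |mean(disc) - mean(annulus)| / SD(annulus) with a
3.5 nm signal disc (half the nominal 7 nm particle diameter) and a 7-14 nm
background annulus, converted to pixels by the image calibration. It is
reported as missing when the annulus SD is zero.

## Pit mapping

For a contour with pit marks, each cytoplasmic-side particle's foot is
classified pit (closed interval) or distal; pit particles get a normalized
arc fraction s = (foot - pit start) / pit length, distal particles a signed
arc offset to the nearest pit edge. Normalizing by each pit's own contour
length absorbs the variable closure of real pits. The idealized projection
places pit particles on a 100 nm diameter semicircular model pit at arc
fraction s, offset outward along the local normal by their measured
proximity (so the proximity to the assigned model component is preserved
exactly), distal particles on flat flanks at their arc offset, and
duplicates every point by mirror symmetry about the pit axis — n particles
always yield 2n plotted points. Per-image frequencies are emitted both raw
and normalized per unit arc length (pit arc vs analyzed distal arc), since
either convention is defensible; the normalizing lengths are recorded.

## Live-cell kinetics

Spots are detected per frame on the reference channel by Otsu thresholding
and connected-component labelling (components under 4 px discarded); spots
are *not* tracked across frames because the per-frame median ratio does not
need identity. Background per frame and channel is the mode (KDE peak) of
the non-spot pixel intensities — robust to the sparse bright spots. Each
spot contributes (mean tag - bg) / (mean reference - bg); the per-frame
value is the median over spots; each cell's trace is shifted so its
pre-stimulus median is exactly 0; cells are averaged as mean +/- SEM. The
control randomizes the tag channel pixel-wise within each frame (seeded,
reproducible) and reruns the identical analysis; for a genuine recruitment
signal this flattens the response. Frame-shuffling or spot-reassignment
controls would also be defensible; pixel permutation is the default because
it preserves each frame's intensity histogram exactly.

## What the synthetic generator does and does not emulate

`generate_scene` builds a membrane profile spanning the frame at a random
depth, with coated-pit invaginations modelled as semicircular crowns
(radius 50 nm) joined to the flat membrane by tangent-continuous 25 nm
shoulder fillets (an uncoated "neck"); the crown arcs carry the coat
intervals and the first pit's interval is recorded as the pit marks. The
depth range spans whole periods of the overlay grid and pits are placed by
uniform dart throwing, so membrane features sit at uniformly distributed
offsets relative to the deterministic stereology grid, as in real
micrographs where framing is arbitrary. The shoulder radius is kept at or
above the maximum tag length so that a tag displaced along the local normal
is always nearest its own anchor — without the fillets, anchors near a
semicircle's mouth would be displaced parallel to the adjacent flat
membrane and systematically mislabeled.

Volumetric particles are placed with Poisson counts (mean = density x
region volume, so counting statistics are realistic) uniformly in area
within each region, by rejection sampling against the classifier itself;
depth within the section is not modelled. Default densities are the
measured labeling regime for ferritin-tagged clathrin (cytoplasm 72.5,
coated zone 1308.6 particles per cubic micron); the uncoated-proximal
default (100) is a round value in the enriched-but-lower range those
experiments report qualitatively. Membrane-anchored tags are placed at
Poisson-rate anchor points along coated or uncoated arcs and displaced
toward the cytoplasm by a draw from a tag-geometry model; two length
regimes (18 nm extended at pits, 7.5 nm kinked distally, narrow 25-degree
cones) synthesize the conformational difference whose recovery the pit
mapping demonstrates — a 10 nm mean proximity offset.

The kinetics generator emulates recruitment, not creation, of signal: the
tag channel's spot gain after onset is drawn from its diffuse pool so total
frame intensity is conserved, and the default 256 px frame with 8 spots
keeps spot coverage near 1% of the frame as in real cell images. Both
choices matter for the randomized-channel control: with dense spots or
non-conserved totals, a pixel permutation acquires a small systematic step
at onset that real images do not show.

What the generator does **not** emulate: pixel-level EM texture (stages
consume annotations, not images), vesicular membrane profiles other than
the spanning plasma membrane, partial-particle section inclusion, variable
pit closure, photobleaching, or spatially varying backgrounds. Passing
tests on this synthetic material therefore validates the *computations* —
classification, areas, statistics, geometry, traces — not the upstream
segmentation or detection steps that a real study performs by hand.

## Numerical choices and degenerate inputs

* Proximity exactly at the zone width, and feet exactly at coat or pit
  edges, are **included** (closed intervals); boundary feet at a shared
  junction vertex resolve to the first segment attaining the minimum.
* Membrane polylines are chords of smooth shapes; on concave-side
  stretches a chord can cut inside the smooth curve by d(1 - cos(turn)),
  which the generator keeps below 0.04 nm.
* Zero observed particles give zero expected counts and zero densities
  (missing where a region has zero volume); the enrichment ratio is
  missing when the cytoplasmic density is zero; SNR is missing when the
  annulus SD is zero; a degenerate (all-identical) distance sample has
  FWHM 0 with a warning; a chi-squared table with a zero margin is an
  error naming the margin.
* All simulation entry points take an explicit integer seed and are
  bit-for-bit reproducible for a fixed seed.

## Study sizes used by the packaged checks

The packaged acceptance checks run at sizes chosen to balance statistical
resolution against a laptop-scale run: 1000 null experiments of 20
micrographs and ~80 particles for the RLI calibration (published
experiments range over 5-29 micrographs and 10-165 particles), 30 scenes
for density recovery, 100,000 draws for the resolution simulation, 50
seeds for pit-effect recovery, and 20 seeds for the kinetics control. The
ANOVA type-I check uses 1000 replicates of 3 x 8 observations.

## Known limitations

* The RLI chi-squared is conservative at small expected counts (see above);
  a likelihood-ratio or exact multinomial variant is out of scope here.
* Areas come from quadrature, so very thin or highly convoluted regions
  need a finer `grid_nm` than the default.
* The labeling-resolution simulation is a geometric stand-in for the full
  detection physics; its orientation law and length-state count are
  configuration, and conclusions about a specific tag should scan them.
* Pit mapping is per-section 2-D; no 3-D reconstruction across serial
  sections is attempted.
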