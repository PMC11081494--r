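---
title: "Quantifying epithelial morphogenesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epithelial morphogenesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `epimorph`, the choices made where
the design was genuinely open, and what the synthetic-data validation does
and does not establish about real data.

## Coordinate frame and conventions

All geometry lives in a right-handed embryonic frame: +x along the
antero-posterior (AP) axis toward the posterior, +y along the dorso-ventral
(DV) axis away from the ventral midline, units micrometres. Image rows index
DV and columns AP, with pixel centres at half-integer multiples of the pixel
size. Undirected angles (interface and cell orientations) are acute angles
from AP in [0, 90] degrees; axis-bearing directed quantities (bipolarity
phase, long-axis direction) live in [0, 180). All strain rates are
proportion per minute (pp/min); rates of change use a centred window of ±2
frames, i.e. ±1 minute at the 30-second frame interval, and undefined values
propagate as `NA` — never as zero — into every summary.

## Strain-rate decomposition

The local tissue strain rate of a cell is the symmetric part of the velocity
gradient **L** obtained by unweighted least squares of first-ring
neighbourhood centroid velocities (central differences across the rate
window) against centroid positions, `v ≈ c + Lx`. The domain is the focal
cell plus its first-ring neighbours — the smallest neighbourhood that still
constrains a linear field; cells with fewer than three usable neighbours are
flagged undefined. A rigid translation gives exactly zero; a rigid rotation
gives an antisymmetric gradient and hence zero symmetric part.

The cell-shape strain rate is derived from the best linear map `A` carrying
the cell's outline at `t − 2` frames onto the outline at `t + 2`:
`C = logm((AᵀA)^{1/2}) / Δt`, the matrix logarithm of the right stretch of
the map, discarding its rotation. Tracked meshes provide vertex
correspondence, so `A` is fitted by least squares over centred corresponding
vertices; this is exact for any affine deformation and exactly zero for
rigid rotation. Where no correspondence exists (e.g. geometry rebuilt
independently per frame from label images), the package falls back to
mapping the cell's area-normalised second-moment tensors `S₁ → S₂`,
projecting both on the compromise frame diagonalising `S₁ + S₂` and taking
per-axis log ratios; that fallback is exact for principal-axis-aligned
stretches and for rigid rotations, and approximate (few per cent) for
oblique deformations.

The intercalation strain rate is defined as the difference
`I = T − C`, so the decomposition `T = C + I` is an identity of the output
tables, not an estimate. Cell area strain rates are `d(ln area)/dt` by the
same central difference.

Cell shapes are summarised by the moment ellipse of the polygon (covariance
of the uniform distribution over its interior; semi-axes `a ≥ b`,
elongation `e = (a − b)/(a + b)`). The axial shape elongation is
`e · (−cos 2θ)` with θ the directed long-axis angle from AP. This functional
form was chosen because it meets all four anchor behaviours — +1 strongly
DV, −1 strongly AP, 0 isotropic, 0 at 45° — while being smooth and bounded;
its interior scaling between those anchors is a package choice, as only the
anchors are fixed by the definitions.

## T1 detection and productivity

Neighbour relations come from the per-frame interface table. A contact
change must persist at least 2 frames (1 minute) to count, suppressing
segmentation flickers at near-4-way vertices. An event is recorded when a
pair gains contact and the opposite pair of the same quartet (the two
common neighbours) lost contact within the preceding frames; the swap time
is the midpoint between the last old-contact frame and the first
new-contact frame, which also covers transient 4-way-vertex configurations.
Edge events with incomplete quartets are discarded.

The continuous productivity of an event is `−cos 2θ` of the gaining pair's
centroid–centroid angle from AP. Among the one-parameter families through
the three fixed anchors (+1 at 90°, 0 at 45°, −1 at 0°) the cosine form is
used by default because it equals the strain-projection factor, which is
what makes productivity-weighted exchange rates directly comparable to
AP-projected intercalation strain rates; a linear-in-angle alternative is
available via `method = "linear"`. Exchange rates divide by the bin-average
number of DV-oriented interfaces and by bin minutes; an interface at
exactly 45° counts as AP-oriented (the DV class is strictly "greater
than 45°").

## Myosin II quantification

Normalisation is literal two-step: pixels up to the frame's 5th percentile
are set to zero (threshold-zeroing, not subtraction), then every frame is
scaled by the single factor mapping the reference frame's 98.5th percentile
to grey 200, clipped at 255 — the 200–255 headroom is the tail left for
high-value pixels, with no separate nonlinear map. Zeroing precedes the
stretch; the stretch factor is computed on the zeroed reference frame. Using
one reference time point preserves genuine intensity trends over time. The
maximum-intensity z-projection of a ±2 µm window is a pre-step that applies
only to stack input; synthetic data are planar.

Junctional pools are the 1-pixel contour lines of each cell; a shared
interface's density is the mean of the two adjacent cells' lines, computed
symmetrically. Pixels within 2 px of a vertex point are excluded (vertices
are Myosin-enriched) and form the vertex pool; the non-junctional pool is
the remaining cell pixels.

Bipolarity fits the period-2 model `a₀ + p cos 2θ + q sin 2θ` to the
interface densities of each cell with at least three defined interfaces,
where θ is each interface's direction after *unstretching* — mapping
boundary points by `S^{-1/2}` (determinant-normalised shape tensor) about
the centroid, which equalises the angular extents that cell elongation
would otherwise bias. The fit is weighted by unstretched interface length
and solved by least squares rather than by resampling the profile to an
equal-angle grid and transforming: a piecewise-constant resample attenuates
the period-2 coefficient of a six-interface cell by sin(π/3)/(π/3) ≈ 0.83,
whereas the weighted fit is the deconvolved version of the same quantity
and recovers a painted cosine law on a regular hexagon exactly. Amplitude
is `√(p² + q²)`, phase `atan2(q, p)/2` mapped to [0, 180), and the AP
projection `A·cos 2(φ − 90°)` is positive when DV-oriented junctions are
enriched — the polarised configuration that drives AP-productive
intercalation.

Channel registration displaces interface/vertex sampling positions by
`offset_fraction` (channel time offset over frame interval) times their
predicted inter-frame flow, optionally composing the focal cell's shape
strain in the same fractional manner, and samples bilinearly.

## Synchronisation and genotype statistics

Stage 1 offsets each movie at the first threshold crossing (0.01 pp/min
AP-projected tissue strain rate, linearly interpolated) that is *sustained*
for at least 2 minutes — the persistence rule is the package's definition of
"sustained", guarding against onset fluctuations, which is also why the
threshold itself is nonzero. Stage 2 shifts each genotype as a block so its
average curve crosses 0 pp/min at t = 0; the zero anchor is found by
walking back from the average curve's own sustained threshold crossing to
its last non-positive point, which ignores isolated zero-crossings of
pre-onset noise. Note that a centred ±1-minute rate window makes a measured
ramp depart from zero about a minute before the scripted onset; this common
bias cancels between genotypes and in all relative comparisons.

The genotype comparison is a per-30-s-bin mixed-effects test of a genotype
fixed effect with embryo as the random unit. By default it is fit at the
embryo level: each embryo contributes its bin mean, whereupon the random
embryo intercept is absorbed into the residual and the Wald test on the
genotype coefficient is exactly calibrated even for cohorts of a few
embryos — the regime this package targets (four embryos per genotype, as in
the emulated study design). A cell-level random-intercept fit
(`lmerTest`, Satterthwaite degrees of freedom) is available with
`method = "cell"` and falls back to the embryo fit when degenerate. Whether
the original analyses fit at cell or embryo level is not derivable from
their description; the embryo-level default was chosen for small-cohort
calibration, which the test suite verifies against the nominal α = 0.01
over a thousand null bins. No multiple-testing correction is applied across
bins, matching the per-bin significance shading convention. The 3-bin
moving average is applied to display curves only; all tests use unsmoothed
values.

Because movies carry no AP landmarks, AP positions are never registered
across movies; cross-movie AP comparisons go through the 100-µm central
window, whose anterior bound is a configuration parameter (chosen in real
data to exclude cephalic-furrow-influenced cells).

## The synthetic-embryo generator

The default scene emulates the geometry of a ventral germband field of
view: ~180 cells of 12 µm mean diameter (~170 × 140 µm), frames every 30 s
from −15 to +30 minutes, midline at the field's ventral edge (y = 0).
Tessellations are jittered pointy-top hexagonal lattices (vertex jitter
0.15 of a cell diameter, capped to keep polygons simple); pointy-top so
that DV-oriented junctions exist, as in the germband. Flows:

- *DV pull* (mesoderm invagination): `∂v_y/∂y = r·exp(−y/λ)` with peak rate
  r = 0.02 pp/min and decay length λ = 50 µm, active −13 to +7 minutes with
  2-minute ramps — the invagination window of the emulated study;
- *AP pull* (endoderm invagination / extension): AP stretch increasing
  toward the posterior with a 120-µm exponential profile, peak 0.025 pp/min
  at the posterior edge, active 0–20 minutes with a 1-minute ramp.

The "wildtype" preset has both pulls; "twist" lacks the DV pull. Each
embryo draws an onset shift uniform in ±2 minutes (so synchronisation does
real work) and a flow-magnitude factor with 10 % coefficient of variation
(between-embryo variability). Vertices are advected by Euler substeps
(0.1 min); ground-truth tensors are the symmetric velocity gradient at each
cell's centroid, recorded from the clean (noise-free) state.

Scripted T1s select interior DV-oriented interfaces with pairwise-disjoint
quartets; the losing junction shrinks linearly over 5 minutes to a
near-4-way vertex at the scripted time and the new junction grows
perpendicular over 5 minutes to 5 µm. Swap times are drawn from +6 to +20
minutes after onset so that junction shrinkage, like polarised
intercalation, is a feature of extension proper. The default of 20 events
per movie is the largest count for which disjoint quartets can always be
scheduled on the default field.

Stored vertex positions carry Gaussian tracking jitter of 0.1 µm SD
(≈0.2 px), the package's stand-in for sub-pixel segmentation noise in
manually corrected tracking; it gives the genotype statistics an honest
noise floor. Exactness checks (the decomposition closure on a prescribed
affine flow) construct movies with this jitter set to zero, because they
verify algebraic identities of the estimators, not robustness.

The Myosin renderer paints each shared junction as a 3-px band (≈1.5 µm, a
junctional band in a maximum projection) with intensity
`base + A·cos 2(θ − φ)` averaged over the two adjacent cells' prescribed
parameters (base 100, A ~ U(20, 60), φ ~ N(90°, 15°) wrapped), plus
Gaussian pixel noise (SD 10) and quantisation. Because shared junctions
average the two adjacent cells' laws, the per-cell polarity actually present
in the rendered field differs from the raw sampling parameters; the
generator therefore also records the *effective* per-cell bipolarity of the
painted field (computed analytically before noise), and recovery is
validated against that self-consistent ground truth.

### What the synthetic validation does not show

The generator is kinematic, not mechanical: flows are prescribed, not
force-balanced, and T1s are scripted rather than emerging from junctional
tension. Cells are convex-ish polygons on a plane — no curved-surface
extraction, no cell divisions, no ingression, no photobleaching or depth
attenuation in the imaging model, and segmentation errors are reduced to
Gaussian vertex jitter plus contact flickers. Passing the closure tests
therefore establishes that the estimators are correct and calibrated on
data satisfying their assumptions; it does not establish robustness to
segmentation failure modes or 3D artefacts in real movies.

## Numerical choices and degenerate inputs

Polygon moments use exact shoelace-type formulas; pixel-derived shape
tensors add the within-pixel variance `px²/12`. Interfaces are straight
vertex-to-vertex segments; their pixels, where image-backed, are boundary
pixels assigned to the most frequent foreign neighbour label, with corners
where ≥3 regions meet detected on 2×2 blocks. Ties at exactly 45° are
AP-oriented. Isotropic cells have undefined orientation (flagged, `NA`).
Degenerate polygons, cells with fewer than three usable neighbours or
interfaces, and truncated rate windows all yield `NA`. The sustained-crossing
rules use linear interpolation between samples. Problem sizes in the test
suite are chosen at desk scale: lattices of 49–200 cells, movies of 11–91
frames, cohorts of 2–4 embryos per genotype, 1 000 null bins for the
type-I calibration; the end-to-end genotype comparison runs 4 embryos per
genotype at 120 cells over −15 to +25 minutes.
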