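---
title: "Models and methods behind toemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind toemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(toemorph)
```

`toemorph` implements a complete landmark-based analysis of anole toe and
toepad shape: tpsDig-dialect ingestion, template validation, generalized
Procrustes alignment with bending-energy sliding of semilandmarks,
permutation-based multivariate inference, and a battery of
landmark-derived linear measurements. This vignette explains the models,
the numerical choices, and what the synthetic-data generator does and
does not emulate.

## The digitization template

Every specimen is a scanned rear toe digitized with 19 fixed landmarks
and 13 curves. Landmarks 1–2 sit where the toe meets the palm, 3–4 where
the pad begins to widen, 5–6 at the widest points of the pad, 7–8 at the
distal end of the pad, 9 at the ventral base of the claw, and 10–19 on
the left/right edges of lamellae five through ten (distal to proximal).
Eight curves outline the toe through the consecutive outline landmarks
1-3-5-7-9-8-6-4-2; five trace the free edge of each landmarked lamella.
Each curve carries 10 digitized points whose first and last duplicate the
anchor landmarks; stripping those leaves 8 semilandmarks per curve and
19 + 13 × 8 = 123 points per toe.

The outline-curve anchoring (which landmark pair bounds each of the eight
outline curves) is the natural reading of the template figure; because it
is a convention rather than a mathematical necessity, it lives in a YAML
scheme file (`inst/extdata/toe_scheme.yaml`) that users can replace
without touching code.

Two I/O conventions are worth stating plainly. `SCALE=` is read as
**millimetres per pixel** (coordinates are multiplied by it); TPS dialects
disagree here, so data in the inverse convention must be converted first.
Coordinates are stored exactly as digitized (tpsDig uses a bottom-left
origin); no axis flip is applied, because every downstream quantity is
orientation-invariant. Records with neither a `SCALE=` field nor a
DPI-derived fallback are excluded rather than kept unitless, because the
linear measurements require millimetres.

## Alignment

`gpa_align()` is a standard partial-Procrustes GPA: every configuration
is centred, scaled to unit centroid size, and rotated (proper rotations
only — side is handled by explicit mirroring, never by a fitted
reflection) onto the evolving consensus; the consensus is re-estimated
and unit-scaled each round until its mean displacement falls below `tol`
(default 1e-6) or `max_iter` (100) is reached. The final orientation is
canonicalized (consensus major axis vertical, largest-|y| point up), so
results do not depend on specimen order or on arbitrary similarity
transforms of the inputs.

Semilandmark sliding then minimizes thin-plate-spline bending energy
against the consensus. The bending energy matrix is built from the kernel
U(r) = r² log r² as the upper-left block of the inverted bordered TPS
system; it is symmetric, positive semi-definite, and annihilates affine
deformations. Each semilandmark may move only along its tangent — the
chord between its two curve neighbours, anchors included at curve ends —
and the optimal joint displacement is a single linear solve restricted to
those directions. Degenerate tangents (coincident neighbours) freeze the
point for that pass. Because the solve is an exact minimizer over a
subspace containing the zero displacement, energy cannot increase within
a pass; across passes the consensus (and therefore the energy surface)
moves, so sliding simply stops the moment a pass fails to reduce total
energy, guaranteeing a non-increasing energy log. Up to 5 sliding passes
follow initial convergence — stable and cheap at the study's scale
(n ≈ 250, 123 points). The sliding target is the evolving consensus (the
common toolkit default), not a designated reference specimen. Tangent
projection of the aligned shapes is available (`tangent_project`) but off
by default.

## Multivariate inference

**Procrustes ANOVA.** Shape is the 246-vector of flattened aligned
coordinates. `procrustes_anova()` partitions its variance under a linear
model (default `~ habitat * municipality`) with type-II sums of squares:
every term is adjusted for all terms that do not contain it, via residual
sum-of-squares differences of nested fits. A note on an accounting
subtlety: type-II term sums of squares are additive (terms + residual =
total) only on balanced/orthogonal designs; on unbalanced field samples
they need not be, which is inherent to type-II adjustment and not an
implementation artifact. Significance uses residual randomization
(RRPP): for each term the reduced-model residuals are permuted, the term
F recomputed, and p = (#{F\* ≥ F_obs}, observed included)/(n_perm + 1).
The default is 999 permutations plus the observed arrangement, giving a
minimum attainable p of 0.001; the seed is always recorded. The effect
size Z is the observed F standardized against the permutation
distribution.

**Disparity.** `morphological_disparity()` computes each group's
Procrustes variance (mean squared distance to the group mean) on the
residuals of a nuisance model (default: municipality), and tests pairwise
absolute differences by permuting group labels. The estimator — Procrustes
variance of nuisance-model residuals — is one of several reasonable
readings of "disparity with a covariate"; it is the package's choice and
is stated here so it can be compared against alternatives.

**Ordination.** `shape_pca()` is the eigendecomposition of the
coordinate covariance (via `prcomp`), with extreme-shape reconstructions
at the *observed* minimum and maximum scores (not ±k·sd) — the convention
chosen for all axis visualizations. `between_group_pca()` is a PCA of the
group mean shapes (≤ g − 1 axes) with all specimens projected in.

**CVA.** Canonical variates are computed in a reduced space: principal
component scores retaining min(dimensions explaining ≥ 95% of variance,
n − g − 1). The 95%/ceiling rule is the package's own (toolkits reduce
internally but rarely document the rule), and it is exposed as the
`retain` parameter. In that space the CV axes solve the between- versus
pooled-within-group eigenproblem, normalized so pooled within-group
variance along each axis is 1 — separations are therefore in canonical
variate (Mahalanobis-style) units and grow with the retained
dimensionality; they should only be compared against a null computed the
same way. "Percent of variation captured" by a CV axis is defined as the
variance of the data projected on the axis's unit-norm shape-space
direction, as a share of total shape variance. Because CVA separates even
random groupings of high-dimensional data, `cva_randomization_null()`
re-runs the full CVA on `n_rand` (default 100) group-size-preserving
label permutations and flags whether the observed separation exceeds the
null maximum — the deliberately conservative criterion used for the
habitat contrast.

**Allometry.** `allometry_test()` regresses shape on log size (centroid
size, digitized pad area, or SVL) with the same RRPP machinery and
reports correlations of PC1–PC3 scores with log size.

## Linear measurements

All distances are taken on *unaligned* millimetre coordinates: pad width
(landmarks 5–6), pad length (midpoint 3/4 to midpoint 7/8), proximal toe
segment (midpoint 1/2 to midpoint 3/4), total toe length (their sum,
exact by construction), and lamella height as the mean of the eight
adjacent edge-landmark distances (10-12, 12-14, 14-16, 16-18; 11-13,
13-15, 15-17, 17-19) — the proximal–distal spacing of lamellae, not their
vertical relief. The landmark-polygon area is the shoelace area of the
outline distal of the LM3–LM4 chord; this deliberately differs from a
digitized pad area bounded at the nearest phalangeal joint, and the two
are kept in separate columns. Self-intersecting outlines yield a warning
and the absolute shoelace value.

Group comparisons use Welch's unequal-variance t-test throughout (the
fractional degrees of freedom in the reported analyses indicate Welch),
on natural-log transformed lengths, areas and ratios and square-root
transformed lamella counts. Lamella traits are deliberately *not*
standardized by body size. Confidence intervals are computed on the
transformed scale and back-transformed by inverting the transform on the
bounds (the package's choice; other CI constructions exist).
Repeatability of replicated measurements uses the one-way random-effects
decomposition with the standard unbalanced-design coefficient:
ICC = σ²_among/(σ²_among + σ²_within).

## The synthetic generator

`sample_population()` draws toe configurations with known ground truth,
emulating the study design: two habitats × five municipalities with
13–20 specimens per cell by default (a fixed total, e.g. 246, can be
spread evenly instead). Trait means are the reported group means (pad
width 1.86/1.69 mm, pad length 3.61/3.20 mm, proximal segment
7.01/6.63 mm, lamella spacing 0.17/0.15 mm, lamella count 22.44/21.87);
lengths are drawn lognormally, moment-matched to the reported raw-scale
standard deviations. A key structural choice: a shared per-specimen
**size factor** (lognormal, cv 0.12) multiplies all length traits, with
small trait-specific residual cvs making up the remainder of each
printed sd. Individuals genuinely vary in overall size, so length traits
are strongly positively correlated; without this, ratios such as
width/length would be far noisier than any real dataset, and the
reported sds could not coexist with the reported ratio tests.

Quantities the study does not print are set once to field-plausible
values and exposed in the spec: distal (pad-to-claw) segment 2.1/2.0 mm;
SVL Normal(58, 5)/Normal(55, 5) mm; within-group cvs for proximal
length, distal length, and lamella spacing reuse the pad-length cv;
municipality offsets are ±3% multiplicative on all lengths with a fixed
sign pattern (structure without claiming per-site values); lamella-count
sds (1.3/1.5) are back-computed from the reported confidence intervals.
Digitized pad area is generated as 0.605 × width × (pad length +
0.35 × proximal) with 5% lognormal error — calibrated so group means land
near 6.87/5.57 mm² — and replicated three times for 150 specimens with
additive variance 0.010, reproducing a repeatability ICC near 0.997.

The dominant imaging nuisance — how straight the toe lay on the scanner —
is modelled by `apply_bend()`: a constant-curvature arc map rotating each
point by curvature × height about the instantaneous bending centre,
which preserves midline arc length exactly (a rigid rotation about the
toe base would stretch chords measurably at realistic deflections).
Curvatures are Normal(0, `bend_sd` = 0.015 rad/mm), truncated at 2.5 sd
because the field protocol re-imaged or replaced badly bent toes.
Digitization noise (Gaussian, 0.02 mm per coordinate) is added after
bending, to every digitized point, with curve endpoints sharing their
anchor's click as a real digitizer does. Half of all specimens are
emitted as right-side toes (pre-reflected) so ingestion's mirroring is
exercised; the mirror exactly undoes the reflection, so aligned shapes
carry the original signed curvature.

What the generator does *not* emulate: correlated (non-isotropic)
digitization error, curve-specific landmarking difficulty, within-toe
deformities or damage, pressure-dependent pad flattening, and any
phylogeographic structure beyond the fixed municipality offsets. Passing
tests therefore demonstrate that the pipeline recovers effects of the
calibrated kind from data of this structure — not that real digitized
toes satisfy these assumptions.

## Calibration and power checks

The test suite includes simulation checks run at sizes chosen to keep the
whole suite fast while retaining statistical resolution: type-I-error
calibration uses 200 replicate null populations of n = 150 with
199-permutation tests (GPA without sliding there, since sliding is a
deterministic smoothing common to all permutations and cannot affect
exchangeability under the null); effect recovery uses 200 replicate
calibrated populations at the study size n = 246 on the
measurement pipeline; the curvature artifact check uses one population of
n = 150 with `bend_sd` = 0.025, where the first principal component is
essentially the bend axis. Oracle checks pin the numerical cores to
independent implementations: a 0.001-radian rotation grid for the
two-shape Procrustes distance, a 10⁶-sample Monte-Carlo rasterization for
the shoelace area, a direct TPS interpolation fit for the bending-energy
quadratic form, hand-evaluated Welch and ICC formulas, `car::Anova` for
the univariate type-II table, `vegan::procrustes` for the two-shape fit,
and `MASS::lda` for the CVA direction.

## Numerical details and degenerate inputs

Anchor-coincidence tolerance for stripping is 0.02 mm by default
(digitizers rarely snap exactly; synthetic data are exact to machine
precision); farther endpoints warn but are stripped. Zero-size
configurations, duplicate TPS reference points, collinear references,
singular within-group covariances (CVA), rank-deficient GLM designs, and
groups smaller than 3 (disparity) are all hard errors with named
specimens or terms. Ties in the permutation tallies count in favour of
the null (p-values can only be conservative); the observed arrangement
always counts as one permutation, so p ∈ (0, 1]. Landmark indexing is
1-based everywhere a user sees it. Mirroring never renumbers landmarks:
they are defined anatomically, so indices keep their meaning after
reflection.

## Known limitations

2-D landmarks only; no missing-landmark estimation; no
minimized-Procrustes-distance sliding variant (bending energy is the
implemented criterion); no phylogenetic comparative machinery; no
mixed-effects municipality models (fixed effects only, as in the
analyses this pipeline supports); and the CVA separation scale depends on
the retained dimensionality, so cross-study comparisons of separations
require identical retention rules.
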