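---
title: "Methods: viewer-corrected pattern metrics and background matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viewer-corrected pattern metrics and background matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camomatch)
```

This vignette documents the models, parameter choices and numerical
conventions behind `camomatch`, and what the synthetic-data tests do and
do not establish about real field data.

## The observer model

All pattern metrics are computed "through the eyes" of a violet-sensitive
(VS) avian predator described by `viewer_model()`:

| parameter | default | units | role |
|---|---|---|---|
| `lambda_max` | 610, 545, 475, 415, 560 | nm | peak sensitivities of LW, MW, SW, VS single cones and the double cone |
| `acuity` | 41 | cycles/degree | spatial resolving power |
| `viewing_distance` | 5000 | mm | distance at which patterns are judged |
| `weber_chromatic`, `weber_luminance` | 0.05 | — | receptor noise of the noisiest single cone / the double cone |
| `abundances` | equal | — | relative single-cone abundances; channel noise is `w/sqrt(a_i/max a)` |
| `floor_value` | 0.001 | catch | replacement for non-positive catches |

The package takes cone-catch images as input; constructing spectral
sensitivity curves from the λmax values and camera calibration are out of
scope, and the synthetic scene generator produces catches directly.
Equal cone abundances are the default because only the Weber fraction is
specified for this observer; the abundance weighting is exposed for users
with better estimates.

### Acuity correction

The minimum resolvable angle is `1/acuity` degrees, which at the object
plane subtends `s = viewing_distance × (π/180)/acuity` ≈ 2.13 mm at the
defaults. `apply_acuity_filter()` blurs each channel with an isotropic
Gaussian whose FWHM equals `s` (σ = FWHM/2.355), using separable
convolution with half-sample symmetric (edge-repeating mirror) padding.
With a symmetric unit-mass kernel this boundary rule makes the smoothing
operator symmetric and doubly stochastic, so constant images, channel
means and total image mass are preserved exactly — a property the test
suite checks. Kernels below one pixel trigger a warning and the identity.

### RNL distances

Chromatic distances between cone-catch vectors use the log-linear
receptor-noise-limited form for any number of channels (four single cones
by default); luminance distances use the double cone only,
`|ln(Q_a/Q_b)|/w`. Both require strictly positive catches, which is why
flooring precedes everything; both are symmetric, zero only for equal
log-contrasts, and invariant to common scaling of the two stimuli.

## Segmentation and pattern statistics

`segment_rnl()` merges image regions agglomeratively while both the
chromatic and the luminance distance between region means fall below
thresholds `theta_color` and `theta_lum`. The thresholds default to 3.0
JND each: discrimination-threshold clustering is conventionally run a few
JND above 1 to absorb measurement noise, and the value is configurable
because no canonical setting exists. Two details are fixed purely for
determinism and are documented rather than principled:

* merge order is lowest combined distance `dc/θc + dl/θl` first, ties by
  lowest label;
* merging runs in two phases — spatially adjacent regions first, then a
  global phase without the adjacency constraint — so that disjoint
  patches of indistinguishable colour end up in the same cluster, which
  is what the "counts within clusters" metric presumes.

Patch counting uses 4-connectivity by default (8 available). The area of
the largest cluster is reported in mm² via the image scale; the scale is
carried on every image so the choice is recoverable.

`local_edge_intensity()` evaluates contrast in four directions
(horizontal, vertical, two diagonals) on the filtered, unsegmented image;
each neighbour pair credits both of its pixels, which makes the metric
invariant to image rotation (the test suite rotates a step edge 90° and
requires identical output). The per-pixel value is the maximum over
directions; the metric is the mean over ROI pixels with at least one
in-ROI neighbour.

The twelve secondary statistics (`secondary_stats()`) are a documented
default set spanning the colour-adjacency, visual-contrast and
boundary-strength families — Shannon diversity and evenness of cluster
areas, transition diversity and a horizontal:vertical transition ratio,
and area- and boundary-weighted means and CVs of pairwise chromatic and
luminance contrasts. The exact statistic set used on any given real
dataset varies between studies, so the set here is a stand-in that is
deliberately configurable downstream: the PCA stage accepts any n × 12
matrix. The transition ratio is Laplace-smoothed, `(h+1)/(v+1)`, so it is
finite for patterns with no horizontal transitions and equals 1 for
uniform images.

## Component spaces

The visual-model space is PC1–3 of the twelve secondary statistics,
centred and scaled. Component support is assessed by permuting each
column independently (`n_perm` = 999 by default) and comparing observed
eigenvalues to the null 95th percentiles; the first three components are
retained regardless, because the downstream geometry needs a fixed
dimensionality, and the support flags are reported alongside. Null draws
resample each column's *sorted* values, making the permutation stream
invariant to input row order.

The PCA is fitted on all ROI rows jointly — lizards and backgrounds —
because lizard-to-background distances require one shared space. Each
space is then z-scored over all rows jointly (default) before distances
and hulls: the cluster variables mix counts and mm² areas of
incommensurate magnitude, and unstandardized Euclidean distance would be
dominated by area. `standardize = "raw"` is provided for sensitivity
analysis, and hulls are computed on the same coordinates as distances for
unit coherence.

## Matching, GLMs and diversity

The optimal background is the argmin of Euclidean distance within the
microhabitat; ties (measure-zero for continuous data) break to the lowest
background id and are flagged. Lizards on their optimal background are
excluded from the perch-to-optimal analysis, whose response is the
distance between the perch and the optimal option.

The GLM stage fits `response ~ sex + habitat + clade + svl + sex:habitat
+ sex:clade` (Gaussian family). Interactions are screened by sequential
Type I deviance chi-squares at α = 0.05; if any is significant the
non-significant interactions are dropped and main effects are tested by
Type III chi-squares under sum-to-zero contrasts (required for
interpretable Type III tests); otherwise interactions are dropped and
Type II is used. Estimated marginal means average over the other factors
with SVL at its mean; pairwise contrasts use Holm adjustment by default —
a conservative, assumption-free choice for small families of contrasts.
Empty factor cells are flagged on the fit rather than silently dropped.

Background diversity is the convex-hull volume (3D spaces) or area (2D)
of a microhabitat's background vectors. The 2D hull uses the standard
planar hull with the shoelace formula. The 3D volume enumerates hull
facets by brute force over point triples on deterministically jittered
coordinates (relative scale 1e-9, to resolve coplanar ties) and sums the
tetrahedra each facet spans with the centroid; for the ≤ 6-point sets
this pipeline produces the O(m⁴) cost is negligible and the jitter bounds
the relative error near 1e-8, which the tests verify against the simplex
closed form and Monte-Carlo membership sampling. Hulls with fewer than
d + 1 points or affinely dependent points are degenerate with measure 0
and are excluded from the log10 GLMs (their count is reported), since
log 0 is undefined.

## Range-wide stage

Every lizard is compared with every usable background (52 × 309 = 16,068
distances per space under the default design; a lizard's own backgrounds
are included, as the full crossing implies). Per-lizard, per-location
means (± SE over that location's backgrounds; 364 points) form a 3D point
per lizard × location whose coordinates are the cluster, edge and visual
mean distances. Groups (clade, habitat, location) are compared with
pairwise Hotelling's T² tests; the large-sample chi-square form (df = p)
is the primary report and the exact-F version is carried alongside.
Bonferroni adjustment is the default for the pairwise families. The SE of
each location mean is descriptive and enters no test. Groups smaller than
p + 2 are flagged untestable rather than tested unstably.

## The synthetic generator

`generate_study()` emulates the field design: 52 lizards across 7 named
locations mapped to 4 clades (16/6/25/5 lizards) and 2 habitat classes,
6 backgrounds per lizard of which one is the perch, and 3 non-perch
background images removed as corrupted (perches are never removed —
every microhabitat's perch was analysable in the emulated design — and
each microhabitat keeps at least one alternative). SVL is uniform on
60–120 mm, a realistic adult range for a mid-sized agamid; sexes are
drawn evenly.

Metric rows are multivariate normal around group means and floored into
their natural ranges (counts rounded and ≥ 1, areas positive, CVs
non-negative); no field-calibrated generative model exists, so normals
are the simplest structure that supports the recovery tests, and the
default means/SDs are placeholders chosen to sit far from the floors, not
estimates of real metric distributions. The twelve secondary statistics
share three latent factors (one per statistic family) so the visual-space
PCA has genuinely supported components. Backgrounds are
`lizard + s·offset₀ + v·scatterⱼ`: the common offset (mismatch scale `s`)
sets how far the microhabitat sits from the lizard, the per-option
scatter (scale `v`) sets background diversity and perch-to-optimal
distances. Group multipliers on `s`/`v`, a log-linear SVL trend on `v`,
and a whole-location background shift plant effects that are
multiplicative in distance, hence linear after the log10 transforms the
GLM stage applies — this is what makes sign-and-significance recovery
tests well-posed. With `perch_rule = "optimal"` the perch duplicates the
lizard's own metric row, the one construction that is simultaneously the
argmin in all three component spaces, including after PCA projection.

What passing tests show — and what they do not: the suite demonstrates
that the pipeline's arithmetic is correct (oracle equivalences), that its
tests are calibrated under the null, and that planted effects of the
kinds reported in comparable field studies are recovered with the right
sign at realistic sample sizes. It does not show that real lizard
patterns follow the generator's distributions: real metric tables carry
skew, integer granularity, spatial autocorrelation between nearby
backgrounds and photographic noise that the generator deliberately omits.

## Problem sizes and determinism

The shipped tests run the default 52-lizard design for design-arithmetic
checks, 200-row null datasets over 50 replicates for GLM calibration,
20–25 replicates of n = 200, p = 12 noise PCAs at 199 permutations, and
497-lizard surveys for effect recovery — sizes chosen so the whole suite
completes in about a minute and a half on one CPU while keeping the
calibration estimates' Monte-Carlo error a few percentage points. Every
stochastic stage takes an explicit seed; `run_pipeline()` derives all
stage seeds from the master seed in `run_config()` and records them in
the run manifest, so identical configurations reproduce identical output
files byte for byte.

## Known limitations

* The secondary-statistic set is a configurable stand-in, not a canonical
  list; conclusions about individual statistics should not be read off
  the defaults.
* Segmentation thresholds (3 JND) and the merge-order convention are
  fixed by fiat; cluster counts can change near threshold boundaries.
* The chi-square form of Hotelling's T² is anticonservative for small
  groups; the exact-F values are provided and preferred when group sizes
  are near p + 2.
* The proportion test is the standard k-sample Pearson chi-square;
  expected counts below 5 (common with rare on-optimal events) make the
  asymptotic p-values approximate.
* Convex hulls are supported in 2 and 3 dimensions only, matching the
  component spaces.
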