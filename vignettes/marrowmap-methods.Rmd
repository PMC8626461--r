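---
title: "Methods: quantitative 3D analysis of the marrow vascular niche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative 3D analysis of the marrow vascular niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(marrowmap)
```

## The analysis problem

Multi-channel 3D fluorescence volumes of bone marrow show nuclei (DAPI), the
pan-endothelial marker CD31, the sinusoidal marker Endomucin (EMCN), and a
tumour reporter labelling disseminated tumour cells (DTCs). Three questions
drive the pipeline:

1. *Where is each vessel subtype?* Arterial vessels are CD31-high and
   EMCN-negative; type H capillaries are double-high; type L sinusoids are
   double-low-positive.
2. *Where do DTCs sit relative to those structures?* Measured as the 3D
   Euclidean distance from each spot centre to the nearest voxel of each
   structure, and summarised as the fraction of spots within 10 µm.
3. *Is that localisation more than chance?* Judged against simulated random
   spots of DTC size placed uniformly over the admissible marrow, with
   two-sided Kolmogorov–Smirnov tests on distance distributions and
   unpaired t tests on per-volume means.

All voxel grids use (x, y, z) array order with physical spacing in µm;
voxel `(i, j, k)` (0-based) is centred at `(i*sx, j*sy, k*sz)`. Distances,
areas and lengths are in µm-based units throughout.

## Vessel gating

The published gate placement was manual; `derive_gates()` replaces it with a
reproducible default: three-class Otsu thresholding of the CD31 histogram
over all voxels yields the vessel-presence and CD31-low/high thresholds, and
three-class Otsu of EMCN over the vessel-presence voxels yields the
EMCN-negative/low and low/high thresholds. Manual thresholds pass through
unchanged (`strategy = "manual"`).

Voxels falling between the three canonical gate quadrants (for instance
CD31-high with intermediate EMCN) are assigned to the nearest class centroid
in threshold-normalised gate space; centroids are estimated from the
unambiguous voxels. Whether faint CD31-low/EMCN-negative voxels belong to
sinusoids or background is not defined by the gating scheme itself; here
they fall to the same nearest-centroid rule.

Connected components use 26-connectivity. Components below 500 µm³ are
noise specks at the default spacing and are removed, unless they touch a
larger component of another subtype, in which case they are merged into it —
this repairs small boundary islets where noise flips a few voxels of a
contiguous vessel to the wrong subtype.

## Distances and the null model

`distance_field()` is an exact separable squared-distance transform with
per-axis physical weights, so anisotropic spacing is honoured exactly (the
test suite checks exact agreement with all-pairs brute force). Spot
distances interpolate the field trilinearly at the spot centroid; distances
are centre-to-structure by default. A `subtract_radius` flag provides
surface-referenced distances instead; both conventions are supported because
distance-measurement tools differ on this point, and the centre convention
is the default.

Random spots (10 µm diameter) are placed uniformly over the *admissible*
region — marrow excluding vessels, vessel lumens and bone — and only on
volumes that contain arterioles, type H vessels, type L sinusoids and bone;
volumes missing a subtype would otherwise bias chance proximity. The default
count is `max(10 x nDTC, 1000)`; `null_convergence_check()` reports the
across-seed standard deviation of the proximity fraction at several counts
and the smallest count below a tolerance (0.5 percentage points by
default), which is the package's empirical "how many random spots are
enough" validator. As the count grows, the null proximity fraction
converges to the admissible-volume fraction of the structure's 10-µm shell,
which is computable directly from the masks (`shell_volume_fraction()`) and
serves as the geometric oracle in the tests.

Distance histograms use right-open 10-µm bins with an overflow bin at
30 µm. KS tests are two-sided with asymptotic p values; t tests default to
Student's pooled-variance form on per-volume (per-mouse) means, with Welch
available by flag; no multiple-testing correction is applied (per-comparison
p values are reported, and the output metadata says so). Degenerate
zero-variance t inputs are resolved by convention (p = 1 for equal means,
p = 0 otherwise) and flagged.

## Spot detection

`detect_spots()` runs single-scale difference-of-Gaussian blob detection
with per-axis sigmas `d / (2 sqrt(3)) / spacing`, matched to the expected
10 µm DTC diameter; anisotropy is handled by the per-axis sigmas. The
intensity threshold defaults to median + 8 MAD of the smoothed channel:
robust statistics ignore the spots themselves (which can occupy percents of
the volume and would inflate a plain standard deviation), while the 8x
margin sits above the maxima of smoothed background noise, whose spatial
correlation pushes extremes well past the few-sd range of independent
samples; true spots exceed the threshold by an order of magnitude. Centroids get a per-axis parabolic
sub-voxel refinement. Overlapping cells merge into a single detection and
are flagged `is_cluster` when the fitted radius exceeds 1.5x the expected
radius, mirroring how clustered cells are counted as one spot. Curation
(`curate_spots()`) is the scripted surrogate for manual review: spots inside
bone or a vessel lumen, outside the marrow, or below a quality cutoff are
removed with logged reasons; every rule is configuration-exposed.

## Morphometry

Vessel length is the longest geodesic through the skeleton graph produced
by 3D topological thinning (sequential simple-point removal ordered by
interior depth, preserving endpoints; the (26, 6) simple-point criterion).
The main path is computed over skeleton nodes of vessel calibre — nodes at
least 2 µm in local radius and at least half the median calibre — so thin
sprouts and end-cap remnants register as side branches rather than
deflecting the centreline; arc length is measured on a lightly smoothed
polyline because the voxel-level staircase of the thinned axis otherwise
inflates lengths by several percent. Surface area is the triangulated
0.5-level isosurface (marching tetrahedra) of the mask after Gaussian
smoothing with sigma 0.75 voxels; smoothing tames the staircase
overestimation of binary surfaces, and a voxelized 10-µm-radius cylinder
lands within 10% of the analytic 2*pi*r per unit length. Objects at or below
one voxel are under mesh resolution and their area is underestimated; this
is documented behaviour, not a target of the estimator.

A sprout is a terminal skeleton branch whose extravascular portion is thin
(mean local radius below 2 µm) and at least 2 µm long; both thresholds are
configuration-exposed because "thin" has no published numeric definition.
Sprout length is the straight-line distance from the branch tip to the
parent centreline minus the parent radius, which is robust to the staircase
wiggle of the thinned connector path. Sprout density is reported per 100 µm
of main-path length. Counting is fully 3D; analyses that count sprouts on
transversal sections only will differ from these values.

Lumen areas are measured on planes perpendicular to the local centreline
tangent at up to 10 equidistant main-path nodes (excluding nodes within
5 µm of branch attachments and path ends), rasterised at 0.5 µm; the lumen
region is the in-plane component connected to the centreline point, taken
from a supplied lumen mask or, for wall-only inputs, from an in-plane hole
fill. Collapsed planes record area 0 and are flagged.

## The synthetic generator

The generator is the package's ground-truth instrument, emulating the study
conditions: ~100–300 µm-deep multi-channel stacks containing a hierarchical
vessel network, bone surfaces, endothelial sprouts and DTCs.

* **Geometry.** Vessels are capsule unions (spheres swept along polyline
  centrelines) — the simplest model that supports radius, lumen fraction,
  continuity and analytic oracles. Arterioles (radius ~8 µm) enter opposite
  the cortical plate, branch into type H capillaries (~5 µm) that run
  toward the bone, each feeding type L sinusoids (~12 µm) that wander back
  into the central marrow; the subtype order along any root-to-leaf path is
  always arterial → type H → type L. Defaults (3 arterioles, branch factor
  2, segment lengths 90/150/80 µm in a 256 × 256 × 128 µm volume) give a
  vessel volume fraction of ~4% and a 10-µm vascular shell of ~12% of the
  admissible marrow — a deliberately realistic density that also leaves
  room for several hundred non-overlapping DTCs in each shell. Bone is a
  cortical plate plus trabecular plates in a metaphyseal band.
* **Anisotropy.** The default spacing (1, 1, 2) µm emulates confocal
  z-undersampling and forces every analysis stage to honour physical
  spacing.
* **Intensities.** Per-subtype mean CD31/EMCN levels (arterial 200/8,
  type H 200/200, type L 80/80 over background 10/8), Gaussian noise
  (sd 12) and an optional blur (sigma 0.5 µm). The published "hi"/"lo"
  classes have no absolute intensity values — instrument scales are
  arbitrary — so these are synthetic conventions chosen so that per-channel
  three-class thresholds separate the classes cleanly at the default noise.
* **Sprouts.** Poisson anchors along type H/type L centrelines (arterioles
  are spared by default), perpendicular directions, Gaussian lengths
  truncated at 1 µm, radius 1.5 µm. Anchors keep a minimum 8 µm arc
  spacing — tip cells suppress their neighbours in sprouting angiogenesis,
  and spaced anchors are also what keeps individual sprouts resolvable at
  the default grid. Because sprout calibre sits at the voxel scale, each
  sprout is rasterised as its thin capsule body plus a minimal 26-connected
  voxel chain along its axis (starting inside the parent wall); the chain
  guarantees the sprout is connected to the vessel and survives topological
  thinning, which would otherwise erode two-voxel-wide filaments tip-first.
* **DTCs.** 500 spots of 5 µm radius by default. Each spot draws a
  placement class from the configured mix (perivascular, near-bone,
  near-type-H, remainder uniform); "near-X" spots are uniform over
  admissible voxels within the 10 µm shell of X, with sub-voxel jitter
  constrained to stay inside the shell. Centres respect a hard-core minimum
  separation of 11 µm: DTCs model whole ~10 µm cells that cannot
  interpenetrate, and touching cells are counted as single clustered spots
  by the detection convention. The generator records each spot's true class
  and true distances, so placement fractions are testable against the
  multinomial and geometric expectations.
* **Calibration.** Uniformly placed spots still fall inside a structure's
  shell at the geometric chance rate p, so a target total proximity
  fraction F is reached by setting the preferred fraction
  f = (F − p) / (1 − p) (`calibrate_placement_mix()`), with p measured on
  the generated masks. For null-model studies the type H content is
  calibrated in two phases until the type-H shell occupies a target fraction
  of the admissible marrow (`calibrate_type_h_shell()`): a coarse rescaling
  of the type H segment length (each length change regrows a different
  random tree, so this response is jagged and only ballpark), then bisection
  on the type H mean radius, which leaves the centrelines untouched and
  makes the shell fraction a smooth, monotone function of the knob.

What the generator does *not* emulate: light propagation and a realistic
PSF, spectral bleed-through, tissue autofluorescence, vessel taper and
haemodynamics, marrow cellularity texture beyond a flat nuclear background,
and growth-plate anatomy beyond a labelled metaphyseal band. Passing the
recovery tests therefore demonstrates that the measurement chain is
unbiased under known geometry and noise — not that it is robust to every
artefact of real microscopy; on real data the manual-override paths
(manual gates, explicit thresholds, curation rules) exist precisely because
those artefacts occur.

## Numerical choices and edge cases

* Distance transform: exact separable algorithm; infinite distances only
  for empty masks, which are rejected with the structure named.
* Trilinear sampling clamps to the half-voxel rim around the grid: voxel
  centres plus sub-voxel jitter remain valid sample points.
* Volume storage: multi-page 32-bit TIFF, channel-major, with a JSON
  sidecar carrying spacing, channel names and per-channel scales. The
  codec quantises samples within [0, 1], so channels are stored at half
  scale and binary channels are flagged and snapped back to exact 0/1 on
  read; continuous intensities round-trip at ~1e-9 relative error.
* Seeds: every stochastic stage derives its own stream from the master
  seed, so a run manifest plus seed reproduces all outputs bit-identically.
* Classification ties, zero-variance t tests and collapsed lumen planes are
  resolved by the documented conventions above and flagged rather than
  silently dropped.

## Validation scale

The test suite validates each stage against independent oracles
(brute-force distance transforms and flood fills on random small grids,
ECDF suprema, closed-form t statistics, analytic cylinders and annuli,
multinomial/binomial placement checks) and the full pipeline by parameter
recovery: 20-seed studies at the study scale (256 × 256 × 64 voxels,
~500 DTCs) recover calibrated proximity fractions for vessels, bone and
gated type H capillaries within binomial confidence bands, a 400-seed
uniform-placement study calibrates the KS type-I error, and 50,000-spot
null-model draws match the geometric shell fraction to within half a
percentage point. These sizes keep the full validation run within tens of
minutes on one CPU while leaving Monte-Carlo error well below the
tolerances tested.
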