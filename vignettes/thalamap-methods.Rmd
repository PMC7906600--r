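---
title: "Methods: spatial statistics for classed 3D cell maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial statistics for classed 3D cell maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalamap)
```

# The problem

Serial-section fluorescence imaging of a whole brain yields, after
segmentation, a cloud of detected soma positions, each carrying a molecular
class label (here: two GABAergic interneuron classes, one enriched caudally
in sensory thalamic nuclei, one rostro-medially in associative nuclei).
Three questions recur with such data:

1. **How many cells are there, and where?** Per-slice detection
   over-counts, because a soma ~10 µm across is detected on several optical
   planes spaced ~10 µm apart; counts must be corrected before any
   per-nucleus tally.
2. **Are the two classes spatially segregated?** Quantified by
   nearest-neighbour distances (NND) within and between classes, and by
   unsupervised spatial clustering with a silhouette-selected number of
   clusters.
3. **Where are migrating cells heading?** Quantified from the soma-to-tip
   vector of each cell's leading process, in spherical coordinates in the
   brain's axes.

thalamap implements these analyses, the group-comparison statistics that
accompany them, and a seeded synthetic-brain generator so the whole chain is
testable with planted ground truth.

# Coordinate conventions

All coordinates are micrometres: `+x` medial→lateral, `+y` ventral→dorsal,
`+z` caudal→rostral. Spherical coordinates take the rostro-caudal axis as
zenith: `theta = arccos(v_z / |v|)` (0 = pure rostral), `phi = atan2(v_y,
v_x)` in `[-pi, pi)` (0 = pure lateral). The zenith choice is a package
decision: the rostro-caudal axis is the dominant migration axis in the
system this models, so concentration around it is easiest to read off
`theta`.

Anatomical regions are axis-aligned boxes (`region_atlas()`), a deliberate
stylisation of a full reference atlas. Containment is half-open
`[min, max)` per axis so boxes sharing a face never double-count, and
overlap is resolved by list order (first box wins) — deterministic, and a
catch-all region can simply be listed last, as `demo_atlas()` does with
`other_TC`.

# Axial-oversampling correction

`correct_axial_oversampling()` groups detection events by the transitive
closure of "3D Euclidean distance ≤ radius" (single linkage; default radius
10 µm) and keeps one cell per group. Closure rather than clique grouping
makes the result independent of event order; distance is full 3D because a
detection radius, not a z-window, defines colocalisation.

Two collapse rules are provided because the source descriptions of this
step genuinely differ:

* **`mode = "median"`** (default): keep the member whose z is the group
  median — "the centrally positioned cell in the axial axis". For an
  even-sized group no member sits at the median; the member nearest it is
  taken, ties towards lower z then lexicographic (x, y). A canonical rule,
  never arrival order.
* **`mode = "mean"`**: average the group's positions.

The two differ in attainable z accuracy. With plane spacing Δz and radius
equal to Δz, a cell lying strictly between two planes produces exactly two
events; no single member can be guaranteed within Δz/2 of the truth (the
information is symmetric between the two planes), while the group mean
always is. So: median mode recovers counts exactly and z to within Δz;
mean mode recovers counts exactly and z to within Δz/2. Both bounds are
asserted in the acceptance suite.

`detect_blobs()` is the deliberately simple front end standing in for a
trained segmentation network: threshold, 8-connected components,
intensity-weighted centroids, minimum area. Its contract — intensity map
in, centroids in µm out — is what matters; anything producing such maps can
replace `render_synthetic_slice()`.

# NND statistics

`nnd_within()` gives each cell its distance to the nearest *other* cell of
the same set; `nnd_between()` is bidirectional and pooled (every A-cell to
nearest B and vice versa), which makes the pooled distribution invariant to
which class is called A. Each set is normalised to its own maximum
(`nnd_set()`), per brain, so cumulative distributions from brains of
different physical size share a [0, 1] axis; `pooled_cdf()` evaluates each
brain's ECDF on a common uniform grid (default 256 points — the resolution
is a package choice, configurable) and averages with SEM.

`ks_two_sample()` computes `D = sup |F_a - F_b|` exactly from the merged
order statistics and an asymptotic p-value via the Kolmogorov distribution
at `sqrt(n_e) D`, `n_e = n_a n_b/(n_a + n_b)`. No exact small-sample
enumeration is provided: the intended sample sizes are thousands of cells.
The headline contrast is run on per-brain-normalised values pooled across
brains; per-brain tests are also returned, since which variant the original
analysis used is not determinable.

One subtlety the test suite documents: with per-set max normalisation, the
*empirical* between-class CDF can exceed a within-class CDF by a single
step (1/n) in the extreme upper tail, because each set's largest value is
pinned to exactly 1. Dominance assertions therefore allow one ECDF step;
over the bulk of the range (grid ≤ 0.9) dominance is asserted strictly.

# Spatial clustering

`kmeans_fit()` is a seeded k-means: k-means++ initialisation, Lloyd
iterations until assignments stabilise (cap 300), best of `n_init`
restarts (default 10) by inertia; within-run inertia is asserted
non-increasing at every iteration. Distances are Euclidean on raw
micrometre coordinates — all axes already share physical units, so
standardisation would only distort anatomy. Emptied clusters are re-seeded
with the point farthest from its centroid.

`silhouette_score()` implements the standard per-sample silhouette
`s = (b - a)/max(a, b)` with singleton clusters contributing 0; the prose
description of the metric in the source ("average ratio of distances") is
too loose to implement directly, and the standard definition is what the
cited software computes. `select_k()` fits every k in `k_range` (default
2–10) and takes the silhouette argmax, ties towards smaller k;
`select_k_brains()` clusters each brain separately and averages silhouettes
across brains per k, reporting both SD and SEM of the per-brain scores
since the source's "±" form is ambiguous between the two.

`cluster_composition()` cross-tabulates clusters against true class labels;
the per-class *capture* is the fraction of that class in its majority
cluster, averaged across brains by `capture_summary()`.

# Orientation analysis

`process_vectors()` turns soma/tip pairs into vectors with `(theta, phi,
length)`; the transform round-trips to 1e-9 relative error.
`angular_histogram()` bins `(theta, phi)` on equal-width, right-open bins
(last bin closed), default 18 × 36 (10° resolution; the source states no
bin widths). `dominant_axis_fractions()` reports, per axis, the fraction of
vectors with positive/negative/zero component, named anatomically
(+z caudo-rostral, −y dorso-ventral, …). This sign-fraction reading of
"integrating the histogram along each axis" is exact when bin edges align
with the hemisphere boundaries, which the defaults do, and the equality is
verified as a two-route test. `polar_histogram()` projects onto a stated
anatomical plane, excluding (and counting) vectors whose projection is
below 1e-6 of their norm. `traceable_fraction()` summarises, per
developmental stage, how many cells had an identifiable leading process.

# Group statistics

* `chi2_homogeneity()`: Pearson chi-squared on the groups × regions count
  table, no continuity correction. Counts are the default because they
  preserve the sampling theory; a flag rescales rows to "average relative
  cell numbers" for fidelity comparisons with analyses done on
  proportions.
* `ttest_two_sample()`: unpaired two-tailed t, pooled variance by default
  (the source states nothing beyond "unpaired two-sample two-tailed");
  Welch's form behind `var_equal = FALSE`.
* `percent_change()`: reduction of each test brain relative to the
  reference-group mean, summarised as mean ± SEM — defined per test brain
  because the groups are unpaired; a ratio-of-means variant with
  delta-method SEM is the alternative reading.
* `grubbs_outliers()`: iterative two-sided Grubbs with the t-based critical
  value, default α = 0.05. The cited software's exact outlier routine is
  ambiguous; Grubbs is implemented and said so. The critical value is a
  union bound, so the per-dataset false-flag rate runs slightly above the
  nominal α at small n (measured ≈ 0.054 at α = 0.05, n = 12), which the
  calibration test's band anticipates.
* `roi_fraction_summary()`: ROI counts are pooled within (brain, nucleus)
  *before* dividing — pool-then-divide, matching "their content … added
  together" — then averaged across brains.

# The synthetic world

The generators state the world the tests assume; their defaults are fixed
and are not tuned against test outcomes.

* `synthetic_brain_config()`: two classes of 1000 cells per brain, 3
  brains. Class A is a two-component Gaussian mixture in the caudal
  sensory territory (LGd/VP boxes of `demo_atlas()`), class B a single
  component rostro-medially (MD box); within-class SD 200 µm, centroid
  separation ≈ 1400–1700 µm. These choices emulate the published caudal
  vs rostro-medial enrichment at a realistic nucleus scale (hundreds of
  µm), with cell counts of the order recovered per brain in such studies.
* `serial_imaging_config()`: optical planes every 10 µm anchored at z = 0,
  soma radius 10 µm, so a cell is detected on every plane within its
  radius; event z is the plane z, which is what per-slice segmentation
  yields. The fixed grid makes the dedup round-trip property exact.
* `migration_config()`: leading-process directions are von Mises–Fisher
  around a planted per-region mean. The source reports only binned
  orientation frequencies, so no distribution is asserted as "the" truth —
  vMF is the canonical spherical analogue of a Gaussian and exposes its
  concentration κ explicitly (default mean `(0, −1, 1)/√2`, κ = 20, the
  ventro-rostral dominant orientation; lengths Gaussian, 30 ± 8 µm,
  truncated at 1 µm).
* `render_synthetic_slice()`: Gaussian blobs on a constant background with
  optional Poisson sampling. It emulates soma-localised fluorescence only —
  no PSF anisotropy, depth attenuation, autofluorescence, or neurites — so
  a green detection test establishes the detector's contract, not
  performance on real tissue.

All generators draw from an explicitly seeded RNG scope that restores the
caller's state; identical (config, seed) gives byte-identical output.

# What a green suite does and does not establish

The original study's headline numbers (a silhouette of 0.472 ± 0.012 at
k = 2, captures of 94.9 ± 1.4% and 81.0 ± 0.3%, an LGd count of 1234 ± 82,
a 90.5 ± 1.5% knockout reduction) are functions of specimen coordinates
that were never deposited. They are therefore *not* reproduction targets;
the test suite instead verifies, against brute-force oracles and planted
ground truth, that every algorithm is implemented exactly and recovers
known structure: dedup inverts the sectioning model exactly under its
stated conditions; NND, silhouette, KS, chi-squared match O(n²)/closed-form
oracles to 1e-10; k-means attains the exhaustive 1D optimum; two planted
classes yield chosen k = 2 with ≥ 0.9 capture in ≥ 95/100 seeds; planted
vMF directions are recovered within 5°; t-test p-values are uniform under
the null and Grubbs flags an 8-SD outlier in > 99% of seeds.

# Known limitations

Box atlases cannot express curved nucleus boundaries; region assignment
accuracy on real data is limited accordingly. The dedup is O(n²) per
z-neighbourhood and intended for 10³–10⁵ events, not raw voxel streams.
The KS p-value is asymptotic and anti-conservative below a few dozen
points per sample. The blob detector is not a segmentation model and will
merge touching somata (documented, tested behaviour). No multiple-testing
correction is applied across nuclei, matching the analysis this package
mirrors.
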