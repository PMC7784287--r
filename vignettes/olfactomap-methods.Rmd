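---
title: "Angle-resolved analysis of olfactory-bulb odor maps and amyloid pathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angle-resolved analysis of olfactory-bulb odor maps and amyloid pathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfactomap)
```

## The problem this package addresses

Odor identity is encoded spatially in the olfactory bulb: each olfactory
sensory neuron (OSN) expresses one odorant receptor, and its axon targets a
stereotyped glomerulus, so an odorant evokes a reproducible pattern of
glomerular activity. This topography has a dorsoventral logic — OSNs of the
epithelial endoturbinate project to dorsal glomeruli, those of the
ectoturbinate to ventral glomeruli. In amyloid-driven neurodegeneration the
damage is not uniform along this axis, and neither is the behavioral
deficit: some odorants stop being detected while others remain detectable.

Relating a *physiological* map (widefield calcium imaging of the bulb), a
*histological* map (DAB immunostaining of amyloid-beta oligomers, A11) and
*behavioral* readouts requires putting all of them on a common spatial
coordinate. The package's central device is an **angular coordinate** on
the glomerular layer: the top (dorsal extreme) of the layer is 0°, the
ventral extreme is 180° in sagittal views, and coronal sections run 0–360°
about the section center. Any measurement — calcium response, stain
density, cell count — indexed by this angle becomes an *angular profile*
that can be compared across planes and modalities.

`olfactomap` implements this analysis end to end and couples it to a
seeded synthetic-data generator that emulates every raw input with known
("planted") ground truth, so each stage is validated by parameter
recovery rather than by eyeballing.

## Angular registration

Two constructions are used, chosen because the underlying geometry differs
by plane:

* **Sagittal (lateral) views** expose an open dorsal-to-ventral arc of the
  glomerular layer. A region of interest (ROI) is projected to its nearest
  point on the traced contour and receives
  `180 * (arc length from the zero landmark) / (total arc length)`.
  Normalized arc length is the only construction that guarantees the full
  0–180° range on an open curve regardless of its curvature.
* **Coronal sections** close the layer into a ring; here the angle is the
  polar angle about the section center (default: the contour centroid),
  measured from the ray through the zero landmark — the point on the upper
  rostral migratory stream track — and increasing in the direction the
  contour is ordered, in [0°, 360°).

Coordinates are image pixel coordinates (origin top-left, y increasing
downward, dorsal at smaller y). ROIs farther than an acceptance distance
(default 300 µm) from the contour are excluded and counted. Binning is 1°
by default, which yields the 180 dorsoventral sections of the analysis
grid. "Dorsal" means within 80° (circular distance) of 0°, "ventral"
within 80° of 180°; the band between is unassigned.

Each anterior-posterior frame carries its own zero landmark and the
per-frame profiles are merged by bin; users who prefer a single shared
landmark can pass one contour.

## Calcium imaging model

The acquisition emulated is single-wavelength fura-2 imaging at 380 nm
excitation, where calcium influx *decreases* fluorescence. A trial is 20 s
at 25 Hz (any rate in 25–125 Hz is accepted) with a 2-s odor stimulus at
t = 5 s, repeated 10 times per odorant.

* **Baseline** `F0`: per-pixel mean over the 3 s before stimulus onset,
  pooled over all retained trials (750 frames at 25 Hz).
* **dF/F0**: `(F - F0) / F0` per pixel and frame. No sign flip is applied
  by default; a `sign_flag` records whether values are `raw` (activation
  negative) or `activation-positive`.
* **Trial averaging**: mean across retained trials, then mean within each
  1-s bin (20 bins). Artifact trials are removed by an explicit exclusion
  list; there is no automatic artifact detector, because trial rejection
  is an inspection decision, not an algorithmic one.
* **Stimulus-window summary**: mean over the bins covering
  [onset, onset + 2 s]. A `sum` ("cumulated signal") reduction is
  available as a configuration switch; the mean is the default because it
  is invariant to the number of bins, and the choice is recorded in the
  output metadata.
* **ROI detection**: the reference plugin's internals are unpublished, so
  the detector is a documented stand-in — local maxima of the response
  magnitude above `median + 3 * MAD`, greedily thinned to a minimum
  separation of 200 µm, each outlined by a 200-µm-radius disk.
* **Analysis grid**: the bulb-mask bounding box split into 10 equal
  anterior-posterior columns × 180 equal dorsoventral rows; cells without
  mask pixels are missing-coded and excluded from all downstream means and
  correlations.

### Sign convention in the cross-modal correlation

Activity-map grids and odor-map clustering use magnitudes, |dF/F0|. The
angle-matched correlation against histology, however, uses the **signed**
profile in the raw 380-nm convention. This is deliberate: with signed
values, an odorant whose activity focus sits where A11 staining is high
contributes strongly *negative* calcium values at high-A11 angles, giving
a negative Spearman rho, while a dorsally-responding odorant yields a
positive rho against ventrally enriched staining. That is exactly the
group-level sign pattern the analysis is designed to expose; taking
magnitudes first would fold both cases onto the same sign and hide it.
The flag travels with every profile so either convention can be selected
explicitly.

## Histology model

Stain separation uses classical color deconvolution: optical density
`OD = -log10(I / 255)` per RGB channel (intensities floored at 1e-3 so
blank pixels stay finite), unmixed with the inverse of the stain matrix.
The default vectors are the standard published H-DAB set (hematoxylin
[0.650, 0.704, 0.286], DAB [0.269, 0.568, 0.778], residual = their
normalized cross product); they are configurable because deconvolution is
only as good as its vectors. Negative densities are clipped to zero. The
package also contains the exact forward model, so synthesized mixtures
round-trip through the deconvolution to numerical precision — this is the
backbone of the histology tests.

Derived quantities:

* **Percent stained area**: share of region pixels above a DAB OD
  threshold (default 0.15 — a conventional positivity cut; no threshold
  is prescribed by the measure itself, so it is a parameter).
* **Reciprocal intensity**: `(255 - mean intensity) / area in mm²`. The
  term is conventional but not standardized; the definition used is
  recorded in the result.
* **Angular immunoreactivity**: deconvolved DAB OD of pixels within the
  contour acceptance band, binned by angle — the histology-side angular
  profile. Mean OD per bin is the default; a binarized-area variant can be
  built from `percent_stain_area` per bin if preferred.
* **Region ratios**: dorsal and ventral means of a wild-type and a
  transgenic profile, all normalized by the WT dorsal mean so WT dorsal
  reads 1.00.

Cell-count operations consume already-counted tables (counts are made
manually by blinded investigators in the emulated workflow); the package
summarizes them (mean ± SD/SEM per marker × region × genotype) and tests
them (two-way genotype × region ANOVA with interaction, Bonferroni-adjusted
per-region Student contrasts).

## Behavior model

* **Zone occupancy**: the test cage is divided into three equal
  compartments along its long axis; occupancy is the fraction of valid
  frames whose tracked point lies in each third. The nose point is the
  default (the question is where the animal sniffs); the 4-point centroid
  is selectable. Missing frames are dropped and counted, never
  interpolated.
* **Performance index**: `PI = pct_exp - pct_ctrl` in percentage points,
  where each percentage is odorant-compartment occupancy relative to
  valid session time (the alternative — time relative to any-compartment
  time — is the same quantity here because every valid frame is in some
  compartment). PI = 100 means unambiguous detection, PI near 0 means the
  odorant is not distinguished from mineral oil.
* **Food-seeking latency**: normalized by the mean wild-type latency;
  observations at the 10-min recording cutoff are flagged censored rather
  than treated as exact.
* **Y-maze alternation**: `100 * (# of length-3 entry windows containing
  all three arms) / (N - 2)`; undefined (NA) below three entries.

## The synthetic study

The generator is first-class, tested code; its defaults *are* the study
conditions:

| Parameter | Default | Meaning |
|---|---|---|
| trials | 10 × 20 s, stim 2 s at t = 5 s | acquisition protocol |
| frame rate | 25 Hz | within the instrument's 25–125 Hz |
| field | 48 px at 25 µm/px (1.2 mm) | desk-scale bulb window |
| focus shape | isotropic Gaussian, σ = 100 µm | glomerular-scale blob |
| focus kinetics | constant during stimulus, exp. decay τ = 1 s | simplest testable model |
| group A / B centers | 40° / 150° | dorsal vs ventral odor groups |
| angle jitter | σ = 10° | glomerular position variability between animals |
| planted dips | 0.20 (primary), 0.12 (secondary focus) | relative fluorescence decrease |
| noise | 2% of baseline per pixel-frame | widefield shot-noise scale |
| ventral suppression | 0.7 | 5xFAD group-B amplitude × 0.3 |
| A11 ventral gain | 2.0 | 5xFAD ventral staining enrichment |
| A11 bin noise | SD 0.08 (baseline 1) | section-to-section variability |
| detection occupancy | 0.6 (detecting), 1/3 (chance) | bout-level zone preference |
| counts | printed group means/SDs (OMP); reported ratios/fold changes (TH, Ki67, TUNEL) | per-animal normal draws |

Where the emulated study prints a value (trial structure, frame-rate
range, OMP percentages, normalized TH ratios, the twofold Ki67/TUNEL
changes, 30-fps tracking, the 10-min cutoff), the generator uses it; where
it does not (per-animal imaging amplitude variability, kinetics, absolute
Ki67/TUNEL base rates), a single realistic choice was made once and is
listed above. Foci are snapped to the nearest pixel center so that a
noise-free planted dip is realized exactly by one pixel, which gives the
recovery tests a sharp target.

What the generator deliberately does **not** emulate: optics (PSF,
photobleaching, vignetting), hemodynamic or movement artifacts, realistic
nuclei or tissue texture in histology (sections are rendered only through
the exact H-DAB forward model), and pose-estimation errors beyond missing
frames. Passing tests therefore demonstrate that the analysis recovers
what it claims from data with the *statistical* structure of the study —
not robustness to every nuisance of real microscopy.

## Statistical machinery

* **Spearman correlation**: average ranks under ties; two-tailed p from
  the Gaussian approximation `z = rho * sqrt(n - 1)` (the approximation
  the emulated analysis reports); 95% CI by Fisher z with variance
  `1/(n - 3)`. An exact permutation p (full enumeration) is available for
  n ≤ 8 — the bound is 8 rather than 10 because enumeration beyond 8! is
  not worth its runtime in R for a secondary option.
* **Angle-matched correlation**: profiles paired bin-by-bin on identical
  edges (180 pairs at the default 1° sagittal binning), pairwise-complete
  deletion with the pair count reported, plus an OLS fit of calcium on
  histology with a pointwise 95% confidence band. Both the rho CI and the
  slope CI are emitted, labeled, since either may be the interval a reader
  wants.
* **Group comparisons**: Student's (not Welch's) unpaired two-tailed t —
  the equal-variance test matches the emulated study's reported df of
  n1 + n2 − 2 — and balanced two-way ANOVA with interaction followed by
  Bonferroni-adjusted within-region genotype contrasts.
* **Odor-map clustering**: pairwise Spearman across matched angular bins,
  average-linkage hierarchical clustering on `1 - rho`, cut at k = 2. The
  linkage is fixed for reproducibility (no algorithm is prescribed by the
  emulated analysis); the test suite checks it against an
  exhaustive-partition oracle at n = 7, where enumeration is cheap.

## Numerical choices and degenerate inputs

* Missing values propagate as NA and are excluded by pairwise deletion;
  counts of exclusions (masked pixels, dropped frames, excluded ROIs,
  empty bins) are always reported alongside.
* A baseline pixel ≤ 0 masks that pixel's dF/F0 rather than producing
  infinities; an empty region mask, an all-excluded trial list, or fewer
  than three Y-maze entries are errors or NA, never silent zeros.
* Angles exactly on a bin edge go to the right-open bin; the closing
  domain angle (180° or 360°) joins the last bin.
* Determinism: every stochastic step runs under a restorable
  Mersenne-Twister state derived from the configuration seed, so a config
  reproduces its dataset—and the pipeline its report—bit for bit.

## Problem sizes

The shipped analyses and tests run at desk scale by choice: a 48-px field
at 25 Hz (20.5 M samples per odorant trial set), 180-bin profiles, 6
animals per genotype in count tables, 20-seed replication for the
sign-pattern and clustering checks, and 1000 replicates for the t-test
calibration. All sizes are configuration parameters, and nothing in the
implementation depends on them.

## Known limitations

* Contours are inputs (hand-traced or synthetic); there is no automatic
  glomerular-layer segmentation.
* The ROI detector is a parameterized stand-in for an unpublished plugin;
  its outputs should be treated as one reasonable operationalization.
* No motion correction and no ratiometric (340/380) fura-2 computation —
  only the 380-nm channel is modeled.
* The behavioral generator's bout model is a caricature of mouse
  exploration; it reproduces occupancy statistics, not trajectories worth
  analyzing kinematically.
* No mixed-effects modeling; animals are treated as exchangeable within
  genotype, as in the emulated analyses.
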