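---
title: "Methods: ETDRS sectorization, grouped SVM cross-validation, and OCT-A encodings"
author: "fliopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ETDRS sectorization, grouped SVM cross-validation, and OCT-A encodings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind the
package: the measurement model, the grid geometry, the classification
protocol, the OCT-A encodings, and what the synthetic cohort generator does
and does not emulate. It states design rationale only; every number quoted
here is computed by the test suite, the analysis scripts or
`scripts/acceptance.R`.

## The measurement model

FLIO measures the fluorescence decay of intrinsic retinal fluorophores over
a 30° macular field. After the vendor's biexponential decay fit (upstream of
this package and out of its scope), each eye is summarised by four 256×256
matrices: the amplitude-weighted mean lifetime τ~m~ in picoseconds and the
photon-count intensity, for the short (SSC, 498–560 nm) and long (LSC,
560–720 nm) spectral channels. Typical healthy τ~m~ values fall in roughly
190–350 ps. Pixels can be invalid at low photon counts; the exported
matrices do not document how such pixels were handled, so the package adopts
an explicit convention: invalid cells are `NA` in memory (written as `NaN`
on disk) and every downstream mean is missing-aware. A sector with no valid
pixel yields `NA` rather than a fabricated value.

## ETDRS grid geometry

The grid has ring diameters of 1, 3 and 6 mm around the fovea, which is
taken as the image centre (the fixation target sits there during
acquisition; no fovea detection is attempted). The field is specified in
degrees but the grid in millimetres, so a conversion is required; the
package uses the standard emmetropic approximation of 0.3 mm per degree,
giving a 9.0 mm extent and a pixel pitch of 9/256 ≈ 0.035 mm for FLIO. Both
the scale and the ring diameters are `grid_geometry()` fields, so a
different schematic eye model is a configuration change, not a code change.

Ring membership uses the Euclidean radius in mm: central disc r ≤ 0.5,
inner ring 0.5 < r ≤ 1.5, outer ring 1.5 < r ≤ 3.0. Quadrants split on the
±45° diagonals — superior above, inferior below, nasal and temporal
left/right resolved by laterality. Two conventions deserve explanation:

* **Diagonal tie-break.** Pixels exactly on a ±45° diagonal exist for a
  256-grid (the centre falls between pixels, so offsets are half-integers
  and `|dx| == |dy|` has solutions). The package assigns them to the
  horizontal (nasal/temporal) quadrants on both diagonals. This is the
  unique deterministic rule under which two exact symmetries hold
  simultaneously: the OD and OS grids differ by a pure N↔T mask swap, and
  extracting features from an OS eye equals extracting from its
  horizontally mirrored image with OD geometry. An orientation-dependent
  rule (e.g. always clockwise) breaks both, because it makes the superior
  mask asymmetric. The tests assert both symmetries exactly.
* **Nasal/temporal orientation.** Export tools do not agree on whether the
  temporal retina appears on the image left or right. The package defaults
  to the fundus-photograph convention (OD temporal = image left) and
  records the choice in the geometry object; a misconfigured orientation
  relabels N↔T features rather than silently corrupting them.

The nine sector means of the four matrices, in a fixed canonical order
(τ~m~ before intensity, SSC before LSC, C, N1, S1, T1, I1, N2, S2, T2, I2),
form the 36-feature vector. Sectorization is validated against an
independent per-pixel brute-force implementation to 10⁻¹² relative error,
and the masks are asserted to partition the 6 mm disc exactly.

## Feature subsets and t-test selection

The classification experiments run over ten named subsets (all 36;
intensity 18; τ~m~ 18; per-channel 9; per-ring 8, centre excluded; the two
cross ring/channel combinations of 8; and the top-3 τ~m~ features by
t-test). Selection by test statistic on the full dataset leaks label
information into the evaluation, so `run_cv()` re-ranks the features inside
each training fold by default; the single global selection is available as
`paper_mode_selection = TRUE` because it is the protocol the reference
tables were produced with. Both modes are labelled in the result's
configuration echo. Whether the two eyes of a subject should count as
independent samples in the global t-test is debatable; the package follows
the reference protocol (eyes as samples) and exposes the ranking function
so a subject-mean analysis is a one-liner.

## SVM and cross-validation protocol

The classifier is a soft-margin SVM with RBF kernel (libsvm via e1071).
Lifetimes in ps and intensities in counts live on incomparable scales, so
features are z-scored with training-fold statistics; missing values are
imputed with training-fold feature means. The reference protocol does not
state C, γ or scaling, so the package uses the de-facto defaults — C = 1
and the "scale" rule γ = 1/(d·Var(X)) computed on the standardized training
matrix — and echoes all three into every output.

Cross-validation is grouped and stratified: subjects (never eyes) are
shuffled within each smoking stratum with a per-repeat seed and dealt
round-robin into k = 5 folds, so stratum counts differ by at most one
across folds and both eyes of a subject always share a fold. With 26/14/14
subjects this yields fold sizes {12, 11, 11, 11, 9}. Each repeat predicts
every sample exactly once; TP/FN/FP/TN are integer sums over the five
folds, the twenty repeats are averaged cell-wise, and rates are computed
from the averaged cells — the aggregation order that makes TP + FN and
FP + TN exact class counts while the means stay fractional. The ± columns
are SDs over the twenty per-repeat percentages; that interpretation is
recorded here because the reference tables do not define theirs. Class
imbalance in the heavy-smoker task (52 vs 28 eyes) is left unweighted,
matching the apparent reference protocol; `e1071`'s class weights remain
reachable through the configuration if a user wants them.

## OCT-A encodings

Slabs are 8-bit 512×512 en-face images from up to 15 canonical
segmentations. Histograms are kept as raw counts (all slabs share a pixel
count, so normalisation cannot change any comparison; a normalised option
exists). The circular 9-sector grid reuses the ETDRS machinery with a 20°
field: at 0.3 mm/degree the extent is 6.0 mm, so the 6 mm outer ring
exactly inscribes the image (outer radius 256 px). "Fit to the region of
measurement" could also mean rescaling the ring ratios; inscribing was
chosen because it preserves the standard 1:3:6 proportions, and it is
configurable.

The local fractal dimension map binarizes the slab with Otsu's global
threshold, then fits, for the window around every pixel, the least-squares
slope of log N(s) against log(1/s), where N(s) counts boxes of side s
(anchored at the window's top-left corner, edge boxes truncated) containing
vessel pixels. The source method delegates its parameters to common
practice, so the package fixes concrete, config-exposed defaults: window
25 px, box sides {2, 3, 4, 6, 8, 12}, symmetric reflection padding at
borders, FD = 0 for windows without foreground, and values clamped to the
theoretical [0, 2] range (finite-size least-squares fits can overshoot
marginally). Filled and line windows reproduce the closed-form slopes 2 and
1 exactly when the box sides divide the window. The implementation
evaluates all 512² windows with per-box-grid summed-area tables rather than
a per-pixel loop, and is tested against the naive per-window computation.

For embeddings, encodings are PCA-reduced to their 15 most variable
dimensions (component signs fixed by making each component's largest
loading positive, so results are reproducible across BLAS builds) and
embedded with an exact t-SNE. No t-SNE implementation is part of the
package's dependency stack, and cohort sizes here (~100 samples) make the
O(n²) exact algorithm cheap, so the package implements it directly:
perplexity calibrated by bisection (default 30, auto-reduced below
(n−1)/3), early exaggeration ×12, momentum gradient descent with adaptive
gains, and a PCA initialisation scaled to SD 10⁻⁴ — which makes runs fully
deterministic, a property the tests assert bit-for-bit. Group separation in
an embedding is judged by a permutation test on the distance between group
mean points, permuting labels at the **subject** level: the two eyes of a
subject are one exchangeable unit, exactly as in the grouped CV. Eye-level
permutation is anti-conservative whenever eyes of a subject are correlated,
and was measurably anti-conservative even on this generator's data at small
n. The pretrained-CNN image encoding used alongside histograms and
sectorization in the reference analysis requires downloaded weights and is
deliberately out of scope; `encode_cohort()` accepts any
`image → vector` function, so such an encoder plugs in without package
changes.

## The synthetic cohort generator

The generator exists so the pipeline's behaviour can be tested against a
known ground truth. It emulates the *statistical design* of the clinical
cohort, not retinal optics:

* 26 non-smokers, 14 light and 14 heavy smokers, two eyes each (108 FLIO
  samples); light smokers' cumulative consumption uniform in (500, 2500]
  packs, heavy in (2500, 8000], heavy = strictly over 2500.
* Each τ~m~ field is baseline (240 ps SSC, 280 ps LSC — placing typical
  pixels in the 190–350 ps display range) + a per-subject channel offset
  (SD 12 ps, shared by both eyes, which is what makes eyes "similar but
  not identical") + a smooth spatial field (white noise blurred at 8 px,
  rescaled to SD 10 ps) + a per-eye scalar (SD 4 ps) + the dose effect.
* The dose effect is linear with saturation: d = min(packs/5000, 1),
  adding d·(+15 ps) inside the inner-ring annulus of the SSC and
  d·(−15 ps) inside the outer-ring annulus of the LSC. The clinical
  literature asserts dose dependence but not a functional form; linear-
  with-saturation is the simplest monotone choice. The effect sizes in ps
  are stand-ins (none are published); +15/−15 ps against the 12 ps
  between-subject SD targets a sector-level standardized difference of
  about 1.2 for a fully dosed heavy smoker. Effects are injected from the
  annulus definition in retinal mm — an independent code path from the
  extractor's masks — so a mask bug cannot cancel out of the tests.
* Intensity fields share the structure (total SD 60 counts split
  0.6/0.75/0.28 between subject, spatial and eye components in quadrature,
  mean 300) but carry **no** dose term; OCT-A slabs are stochastic
  branching vessel trees rasterized to a target density of 0.12 with **no**
  group effect by default. These are the pipeline's negative controls.
* Determinism: every subject/eye/slab stream derives its seed from the
  cohort seed by folding the identifiers through a multiply-add hash, and
  all draws go through R's Mersenne-Twister, so identical configurations
  give bit-identical cohorts on any platform. A foveal lifetime dip is off
  by default (hook provided) — it is irrelevant to class separation and
  would only complicate the null.

What the generator does **not** emulate: photon-count decay statistics,
macular pigment, media opacity, fixation error, vessel shadows, or any
correlation between intensity and lifetime. Passing tests therefore show
that the pipeline recovers the *kind* of signal the clinical analysis
reports, where it was injected and at chance where none exists — they do
not certify clinical accuracy on real data, whose reference values ship
with the package only as worked examples for the metric arithmetic.

One behaviour of the generator is worth flagging: because the per-subject
channel offset is a strong shared nuisance, subsets that include
uninformative sectors of the same channel can outperform the minimal
informative subset — the extra sectors act as within-subject references
that cancel the offset. Real retinas have their own nuisance structure, so
the relative ordering of subsets on synthetic data should only be read
through the properties the tests actually assert: lifetime subsets beat
intensity, and the correctly combined rings beat the swapped combination.

## Problem sizes and numerical conventions

The test suite runs the full 108-sample design for the protocol and
signal-recovery checks (10 cohort seeds for the qualitative ordering, 5
zero-effect seeds for null calibration, 100 repeats for the fold
invariants) and scales the OCT-A property checks to 8-subject cohorts with
one slab per eye, where the permutation test is still well calibrated.
Matrix exports round-trip bit-identically (17 significant digits); feature
CSVs round-trip to better than 10⁻¹² relative (15 digits). Percentages in
report tables are rounded half away from zero to 2 decimals, matching the
printed-table convention (base R's `round()` rounds half to even).
Degenerate inputs have defined behaviour throughout: empty manifests load
to empty cohorts, all-`NA` sectors propagate `NA`, rank-deficient PCA pads
zero components with a warning, identical points embed at finite
coordinates, and zero-variance t-tests return t = 0, p = 1.

## Known limitations

* The fovea is assumed at the image centre; real fixation error displaces
  the grid.
* The mm-per-degree scale ignores individual axial length; ring areas are
  therefore approximate in a way that is uniform across a cohort.
* The SVM hyperparameters are fixed defaults, not tuned; the package
  deliberately contains no hyperparameter search.
* Single-decay-component features (τ₁, τ₂, α₁, α₂) are not modelled; the
  data model stops at τ~m~ and intensity.
* The exact t-SNE is O(n²) and intended for cohort-scale inputs, not
  thousands of samples.
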