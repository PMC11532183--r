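---
title: "Methods: collagen quantification, entropy, and treatment-response calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collagen quantification, entropy, and treatment-response calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroquant)
```

This vignette documents the models and procedures in `fibroquant`, the
assumptions behind them, every numerical choice that a reviewer might want
to audit, and what validation on synthetic slides does and does not
establish about real whole-slide images.

## Segmentation model

A Sirius-Red (SR) section has three optical classes: unstained near-white
scanner background, counterstained pale-yellow parenchyma, and SR-positive
red collagen. The pipeline assumes transmitted-light RGB at a known pixel
size (default 0.25 µm/px, the usual 40× scan resolution) and works in
optical-density space, where stain concentration is approximately linear:
`OD_c = -log10(max(I_c, 1) / 255)` per channel `c` (the `max(·, 1)` caps
saturated black pixels at a finite OD; pure white maps to exactly 0).

* **Tissue detection.** A pixel is background iff it is both bright
  (`max(R,G,B) > 220`) and unsaturated (HSV saturation `< 0.08`); everything
  else is tissue. The mask is then closed with a disc of radius 2 px and
  components under `min_object_px = 10` px are dropped. The two thresholds
  describe scanner background and are deliberately permissive: dark or
  colored pixels are never background.
* **Collagen.** The per-channel OD vector is projected onto a unit SR stain
  vector. The default vector is fitted to the package's reference collagen
  color; for real scanners the measured stain vectors should be supplied via
  `segmentation_params(stain_vectors = ...)`. Collagen = tissue pixels whose
  projected OD exceeds a threshold: Otsu's method over the *tissue-pixel* OD
  distribution by default (parameter-free, adapts to staining intensity), or
  an explicit value for exact reproducibility. Components under
  `min_object_px` are removed.

Degenerate inputs are defined, not errors: an all-background image yields an
empty tissue mask with a warning, and segmentation of it an empty collagen
mask. Raising the explicit OD threshold can only shrink the collagen mask
(monotonicity), and the whole chain commutes with image flips — both are
enforced by tests.

## ECA and EnC

**ECA** (Estimated Collagen Area) is purely a counting statistic:
`100 · |collagen| / |tissue|` percent. It is undefined (an error) when the
tissue mask is empty.

**EnC** (Entropy of Collagen) measures the spatial randomness of the SR
optical density. The main-text definition of the source analysis is verbal,
so the package fixes a fully documented operationalization:

1. Quantize the SR-OD map into `entropy_bins = 8` equal-width bins spanning
   the slide's tissue OD range (out-of-range values clamp to the edge bins;
   a constant field maps to one bin).
2. For every pixel, take the bin histogram over its
   `entropy_window_px = 9` × 9 neighborhood, clipped at the image border and
   restricted to tissue pixels (background never contributes).
3. The pixel's local entropy is the Shannon entropy of that histogram
   (natural log by default, base 2 available).
4. EnC is the mean local entropy over the support pixels — tissue by
   default; `entropy_support = "collagen"` averages over collagen pixels
   instead.

With these defaults EnC lies in `[0, ln 8 ≈ 2.08]`, which brackets the
0.6–2.1 range typical of fibrotic biopsies; a perfectly uniform OD field has
EnC exactly 0. All four knobs (window, bins, base, support) are parameters
of `feature_params()`. The implementation uses summed-area tables per bin
(O(N·bins)); the test suite pins it to a naive O(N·w²) sliding-window oracle
at 1e-9 on a 128×128 field.

## The ROI scale and the extended battery

Features are extracted at two scales: single pixel (the OD and entropy maps)
and 32×32-px ROIs (`roi_px`, ~8 µm at 0.25 µm/px). Tiling is exact — edge
ROIs may be smaller so the tiles partition the image — which gives an exact
conservation law used as a test: the tissue-weighted mean of per-ROI
collagen fractions equals ECA/100 to 1e-9. ROIs with tissue fraction below
`roi_min_tissue_fraction = 0.5` are flagged excluded (biopsy fragments have
ragged borders) and skipped by slide-level summaries; if every ROI is
excluded the error names the threshold.

Per ROI the battery computes: collagen fraction; OD mean/sd/skewness/
kurtosis (type-2 moment estimators; defined as 0 for degenerate samples);
local-entropy mean/sd; gray-level co-occurrence contrast, energy,
homogeneity and correlation; and collagen morphology (component count,
boundary pixels per tissue pixel, orientation anisotropy
`1 − sqrt(λ₂/λ₁)` of the coordinate covariance). Co-occurrence uses 8 gray
levels over the slide's tissue OD range, offsets (0,1) and (1,0) averaged,
symmetric pairs, both pixels tissue; a constant ROI has energy exactly 1 and,
by convention, correlation 1 (the zero-variance limit). Slide-level extended
features are tissue-weighted ROI means plus a global block (OD and entropy
quantiles, component statistics in µm²/mm² using the pixel size) — 31
features total, listed by `feature_registry()`. Only ECA and EnC carry
contractual semantics; the battery is a named, versioned registry standing
in for the fuller proprietary feature lists of commercial pipelines.

Heatmaps (`render_heatmap()`) upsample a per-ROI grid nearest-neighbor,
color it with viridis over the grid's finite range, and alpha-blend it over
the slide; excluded ROIs stay transparent.

## The synthetic-slide generator

`generate_slide()` draws the three optical classes with exact ground truth:
an elliptical section whose border is perturbed by low-frequency harmonics;
portal-tract disks; and septa as random-walk polylines between portal
tracts, stamped as discs of disorder-dependent radius. The
`target_collagen_fraction` is hit by stamping until the target pixel count
is reached (the overshoot is at most one stamp, tens of pixels), giving the
invariant `|achieved − target| ≤ 0.1·target + 0.002`. The `disorder` control
(0–1) simultaneously thins the strokes, raises the walk's jitter, and
fragments the stamping, so component count and EnC rise with it — both
asserted over 5 seeds. All randomness derives from one integer seed;
identical specs give bit-identical slides and the caller's RNG stream is
untouched.

Default cohort conditions mirror a fibrosis spectrum: stage-profile
fractions 0.026/0.057/0.109 (typical F2/F3/F4 collagen areas), per-slide
fractions drawn Normal(profile, 0.15·profile) truncated to [0,1], disorder
0.3, additive RGB noise sd 2 grey levels.

What the generator does **not** emulate: staining variability between
batches and scanners, steatosis vacuoles, inflammation, tissue folds,
out-of-focus regions, and the sheer size of clinical WSIs. Passing the
ground-truth recovery tests therefore shows the *algorithmic* chain is
correct (segmentation recovers a known mask; features equal their oracles);
it does not certify accuracy on real slides, which depends on supplying
stain vectors and thresholds appropriate to the scanner.

## Statistical layer

* **Fleiss' κ** is authored in-package: `κ = (P̄ − P̄ₑ)/(1 − P̄ₑ)` with the
  standard per-item pair-agreement and squared-marginal terms, over the
  six fine stages by default or the coarse four (F1a/b/c collapsed) via
  `coarse_stage()`. When every rating falls in one category, chance
  agreement is 1 but agreement is necessarily perfect, so κ = 1 is returned
  rather than 0/0. The test oracle is an independent brute-force
  pair-counting implementation (1e-12 over 100 random matrices).
* **Agreement bands**: κ is rounded half-up to 2 decimals and matched
  against the conventional inclusive ranges (slight 0.01–0.20, fair
  0.21–0.40, moderate 0.41–0.60, substantial 0.61–0.80). The printed
  convention leaves 0.81 unassigned ("almost perfect > 0.81"), so the
  package takes almost-perfect as rounded κ ≥ 0.81 to make banding total;
  κ ≤ 0 is "poor/none".
* **Paired t-test, ANOVA, Tukey HSD, quantiles** are delegated to base R
  (`t.test`, `aov`, `TukeyHSD`, type-7 `quantile`) behind validating
  wrappers: zero-variance differences and groups of size < 2 are typed
  errors, significance is flagged at p < 0.05, and stars follow the
  `**`/`***`/`****` convention. Because published figures sometimes mix sd
  and SEM in dispersion statements, `summarize_by_stage()` always reports
  both, plus the linear-interpolation IQR (the quartile method must be
  stated; it is type 7).

## Treatment-response calls

For a pre/post pair, histopathology is the sign of the ordinal stage delta
under F1a < F1b < F1c < F2 < F3 < F4. The F1 sub-stage ordering matters only
for cross-boundary moves (e.g. F1a→F2, an increase); no packaged case moves
within F1, so results are insensitive to it. The quantitative (AI) call is
strict: responder iff ECA *and* EnC both strictly decreased, non-responder
iff both strictly increased, else not conclusive — an exactly-zero delta
breaks congruity (no packaged case has one at printed precision), and
feature values are compared at recorded precision, never re-rounded.
Swapping pre and post provably mirrors responder ↔ non-responder and stage
decrease ↔ increase (a property test).

Cohort percentages are `100·count/n` rounded half-up to integers; with
n = 17, 4/17 rounds to 24 (not the truncated 23 sometimes seen in prose).
Two distinct "change by AI" notions coexist and both are reported:
*any-change* (nonzero deltas of both features — 100% in each packaged
cohort) and *congruous-change* (responder or non-responder — 76% pooled).
The weight-loss outcome is strict: more than 10% loss
(`weight_change_percent < −10`; −10 exactly is FALSE); the fixture encodes
only the published facts about which patients crossed it, with synthetic
filler values elsewhere, and the loader's documentation says so.

## Problem sizes and runtime choices

The test suite validates at sizes chosen to keep the full run around a
minute while leaving no algorithmic path untested: ground-truth recovery on
256–384 px slides, the EnC oracle on 128×128, Fleiss oracles on 100 small
matrices, Tukey family-wise error on 2000 null simulations (4 groups of 10,
observed FWER asserted ≤ 0.07 at nominal 0.05), and end-to-end determinism
on a 10-slide 512×512 cohort compared byte-for-byte across two runs. The
pipeline itself is scale-free; whole-slide inputs are limited only by
memory, since pyramidal streaming is out of scope.

## Known limitations

* Stain vectors and background thresholds are scanner-dependent; defaults
  are fitted to the synthetic palette and must be recalibrated for real
  WSIs (no cross-scanner stain normalization is included).
* EnC's window/bin/base/support are a documented choice, not a community
  standard; comparisons across studies require matching them.
* The extended battery is a stand-in registry: its members are standard
  texture/morphology measures, not a reproduction of any proprietary
  feature list.
* Published per-stage cohort means and inter-rater κ values cannot be
  recomputed without the underlying slides and rating matrices; the package
  validates those code paths on synthetic data and oracles instead.
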