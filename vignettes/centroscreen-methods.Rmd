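---
title: "Methods: spatial statistics for centromere-distribution screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial statistics for centromere-distribution screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centroscreen)
```

This vignette documents the statistical model behind `centroscreen`, the
estimators it implements, the main numerical choices, and the scale of
problems it is designed for.

## 1. The measurement problem

Centromeres appear as diffraction-limited fluorescent spots (CENP-C
marker) inside a nucleus whose outline is both irregular and variable
between cells. We want a single per-cell number that answers: *are these
spots more clustered, or more dispersed, than uniform random placement
in this particular nucleus?* The number must be comparable across cells
that differ in nuclear size, shape and spot count, because downstream we
aggregate it per well and compare thousands of gene knockouts.

## 2. Ripley's K in an arbitrary mask

For spots $x_1,\dots,x_n$ in a mask of area $A$, we use the standard
estimator

$$\hat K(r) = \frac{A}{n(n-1)} \sum_{i \ne j} \mathbf{1}[\,d_{ij} \le r\,].$$

No analytic edge correction is applied. Classical corrections
(Ripley's isotropic, translation) assume rectangular or convex windows;
nuclear masks are neither, and a miscorrected edge term biases exactly
the quantity we care about. Instead the window geometry is absorbed into
the null model (next section). `ripley_k()` is exact — the test suite
checks it against a brute-force pairwise enumeration on irregular masks.

## 3. The CSR-standardized clustering score

Under complete spatial randomness (CSR) in the same mask, $\hat K(r)$
has some mask-dependent mean $\mu(r, n)$ and SD $\sigma(r, n)$. We
estimate both by Monte Carlo: `n_mc = 100` resamples of $n$ uniform
points inside the mask (uniform pixel choice plus sub-pixel jitter).
The per-cell score is

$$S = \frac{1}{m} \sum_{j=1}^m
      \frac{\hat K(r_j) - \hat\mu(r_j, n)}{\hat\sigma(r_j, n)},$$

with the radius grid $r_j$ set to 5–50 % of the nucleus' equivalent
radius $R_{eq} = \sqrt{A/\pi}$ (10 points). Properties that follow by
construction, and that the test suite verifies empirically:

- **Calibration**: $E[S] \approx 0$ under CSR, for any mask shape and
  any $n \ge 3$ (verified over 2000 cells, spot counts 10–92: overall
  mean 0.02, per-count means within 0.1 of each other).
- **Size invariance**: jointly rescaling mask and spots leaves $S$
  unchanged up to Monte-Carlo noise, because the radius grid scales
  with $R_{eq}$ and the standardization cancels the area factor.
- **Ordering**: tight Thomas clusters score highest, CSR ≈ 0, hard-core
  (mutually inhibited) patterns score negative, monotonically in the
  cluster scale.

The per-cell sampling SD of $S$ is roughly 0.8 (the $m$ grid values are
strongly correlated, so averaging the grid does not shrink it by
$\sqrt m$). Per-cell values are therefore noisy by design; the screen
works with well means of ~100 cells, whose SE is ~0.08.

Monte-Carlo baselines are cached per (mask, $n$, grid) key, so scoring
many cells that share a segmentation mask costs one baseline. Scores
are undefined (NA with a reason attribute) below `min_spots = 3`;
$\hat\sigma$ has a floor of $10^{-9} A$ to avoid division blow-ups on
degenerate masks.

## 4. Normalized radial distance

Clustering is local; we also want a global position readout. For each
spot, the distance from the nucleus centroid is divided by the distance
from the centroid **through the spot** to the boundary (found by ray
marching at quarter-pixel steps, taking the farthest in-mask step plus a
half-step, clamped to [0, 1]). The per-cell mean of this ratio is 2/3
for uniform spots in a disk (verified to ±0.01); values above it
indicate peripheral bias, below it central bias. The ray normalization,
unlike dividing by $R_{eq}$, is exact for any star-shaped mask.

## 5. Spot detection

`detect_spots_log()` uses a scale-normalized Laplacian of Gaussian at
$\sigma$ = 0.25 µm (≈ the PSF), local maxima with greedy non-maximum
suppression, and intensity-weighted centroids in the raw channel.
Two numerical choices deserve a note:

- **Threshold: median + k·MAD, not mean + k·SD.** On a spot-dense
  nucleus, the spot signal itself dominates the response SD: on a
  noiseless 23-spot fixture the mean+5·SD threshold lands at 16.79
  against a maximum response of 16.81 — essentially every real spot is
  cut. Median and MAD see the (majority) background pixels, keep the
  threshold near the noise floor and leave recall at 1.0. An absolute
  floor of $10^{-6}$ of the image dynamic range rejects numerical
  ripple on synthetic noiseless images.
- **Replicate boundary padding.** Zero padding (or FFT circular
  convolution) creates a step edge at the image border — background
  0.02 against padding 0 — whose LoG response mimics a blob and yields
  spurious border detections. Replicate padding removes the edge.

On noiseless well-separated renders, recall and precision are ≥ 0.98
with ~0.1–0.2 px localization error. At SNR 3 recall degrades to
~0.8–0.85 and spots closer than ~2 PSF σ merge into a single detection
(the renderer records a `merged_spots` truth flag for exactly this
case).

## 6. Cell-cycle gating

DAPI integrated intensity is proportional to DNA content, so G2/M cells
sit one log2 unit above G1. `fit_gates()` first thresholds log2 EdU at
the density valley between its negative and positive modes (S phase),
then fits a two-component unequal-variance Gaussian mixture
(`mclust::meV`, deterministically initialized from an Otsu split) to the
log2 DAPI of EdU-negative cells. The fitted 2N–4N separation is
constrained to 1 ± 0.2 log2 units; a separation below 0.5 is reported
as a unimodal distribution (an error, not a silent guess). Phase
windows are ±3 fitted SDs; cells below the G1 window (subG1 debris) or
above the G2/M window (>4N) are excluded. On planted mixtures of
(0.5, 0.25, 0.25) with 8 % CV, fractions are recovered within 1–2
percentage points and the assigned-G2M/assigned-G1 true spot-count
ratio is 2.0.

## 7. Screen statistics

Per-cell features pass a strict morphology QC (solidity < 0.85 or area
< 30 µm² excluded), are averaged per well, and enter plate
normalization:

- **B-score**: two-way median polish of the row × column matrix,
  computed on library wells only (control wells are masked to NA and
  receive residuals without driving the fit), scaled by 1.4826 × MAD of
  the library residuals. If that MAD is zero — or indistinguishable
  from floating-point residue ($\le 10^{-10}$ of the largest residual)
  — the SD is used and flagged. Row/column gradients are removed
  exactly; single-well effects survive with correlation 1 against
  truth (both verified against a hand-written polish oracle).
- **Robust Z**: B-scores are standardized by the median and MAD of the
  library wells of the same replicate.
- **Merging and calling**: replicate Z-scores are averaged;
  |mean Z| ≥ 2.5 calls a hit, except when the gene is cytotoxic (cell
  count Z < −2.5) or the replicates disagree (|mean Z| below the
  replicate SD). Hits are categorized by the joint sign pattern of the
  clustering and spot-count effects.

On simulated 1040-gene, 2-replicate screens with 5 % planted ±4-MAD
effects, sensitivity is ~0.94–1.0 with a false-positive rate of
~0.3–0.6 %; a null screen calls < 1 %.

## 8. Generators: realism and limits

The simulators are designed to exercise the estimators, not to be
photorealistic:

- Nuclear masks are star-shaped (radial function of angle: ellipse +
  low-order harmonic roughness + evenly spaced notches). Real nuclei
  can be non-star-shaped (e.g. deeply folded); the spatial statistics
  do not assume star shape (only the radial-distance ray normalization
  does), but the generator cannot produce such shapes.
- Images use a single Gaussian PSF, uniform background and Poisson
  noise parameterized by SNR; no chromatic offsets, illumination
  gradients or camera artifacts. Plate-level artifacts are instead
  injected at the well-statistics level (`artifact_row_sd`,
  `artifact_col_sd`), which is where B-scores act.
- The screen simulator draws well-level and cell-level Gaussian
  effects; planted effect sizes are specified in library-MAD units and
  converted through the implied well-mean SD, so "a 4-MAD gene" means
  4 MADs after aggregation, independent of cells per well.

## 9. Problem sizes and cost

Targets on one CPU core: a full 1040-gene, 3-plate, 2-replicate,
100-cells/well simulation (~220 k cells) in well under a second;
scoring it (QC → wells → B-scores → Z → hits) in ~1 s; one clustering
score in milliseconds given a cached baseline (one baseline: ~100 × an
$O(n^2)$ K evaluation). The full test suite, including the end-to-end
property checks, runs in about half a minute. Memory stays below
~200 MB throughout.

## 10. Reproducibility

Every stochastic function takes an explicit seed (or params object
carrying one) and restores the caller's RNG state. The pipeline writes
schema-versioned CSV artifacts with 17-significant-digit numerics plus
a YAML config and manifest; identical inputs give byte-identical
output trees, which the test suite asserts with checksums.
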