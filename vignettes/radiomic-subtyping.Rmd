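---
title: "Radiomic texture analysis and subtype classification with radtex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic texture analysis and subtype classification with radtex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtex)
```

## The problem

Breast cancers are stratified into molecular subtypes — luminal A, luminal B,
HER2-enriched, and triple negative — via immunohistochemical surrogates of
estrogen receptor (ER), progesterone receptor (PR), and HER2 status. The
subtype drives therapy, but it is assessed from invasive tissue sampling of a
potentially heterogeneous tumor. Radiomics asks whether quantitative texture
and shape features of the lesion on contrast-enhanced MRI carry enough signal
to predict receptor status and subtype non-invasively.

`radtex` implements that analysis chain for single-slice lesion images with
binary regions of interest (ROI): gray-level normalization, a 352-feature
extractor in the style of the MaZda texture-analysis package, three filter
feature-selection criteria, a linear-discriminant projection onto
most-discriminating features (MDFs), and k-nearest-neighbor classification
under leave-one-out cross-validation (LOOCV). Because patient MRI cohorts of
this kind are not publicly deposited, the package ships a seeded synthetic
lesion generator so every stage is testable end to end.

## ROI normalization and quantization

Each ROI's gray levels are first limited to the window $\mu \pm 3\sigma$,
where $\mu$ and $\sigma$ are the mean and *population* standard deviation of
the masked intensities, then binned linearly into `n_levels` equal-width bins
mapped to integer levels $1..n_\text{levels}$ (default 64, the common 6-bit
setting for co-occurrence analysis). This removes per-scan brightness and
contrast offsets: any positive affine transform of the intensities leaves the
quantized ROI unchanged, which is asserted as a property test.

Two conventions are deliberate and documented rather than inherited:

* **Out-of-window pixels are clipped, not excluded.** Clipping keeps the ROI
  pixel set intact, so geometry and texture see the same support. (Excluding
  them is a defensible alternative; it changes the pixel set per lesion.)
* **A zero-variance ROI maps to the middle level** $\lceil n/2 \rceil$, so
  degenerate lesions still produce a full, finite feature vector.

All texture families — including the histogram family — operate on the same
quantized levels, so a single `quantized_roi` object is the sole substrate of
extraction.

## The 352-feature registry

The extractor emits exactly 352 named features: HIS 9, COM 220, RLM 20,
GRA 5, ARM 5, WAV 20, GEO 73. Names follow the MaZda conventions
(`S(dx,dy)Stat` for co-occurrence, `45dgr_LngREmph` for run length, `Teta1`,
`GeoW7`, `GeoE12`, ...), so selected-feature reports read like the tables of
the radiomics literature that uses that software.

* **HIS** — mean, population variance, skewness, excess kurtosis, and the
  1/10/50/90/99th percentiles (order statistics) of the quantized levels.
  Skewness and kurtosis of a constant ROI are defined as 0.
* **COM** — gray-level co-occurrence matrices at the 20 offsets
  $(0,d), (d,0), (d,d), (d,-d)$ for inter-pixel distances $d = 1..5$
  (the y axis points down, so $(d,-d)$ is the 45° diagonal), symmetrized and
  normalized; 11 Haralick statistics each. The count $11 \times 20 = 220$
  fixes this offset set. All entropies use the natural logarithm with
  $0\log 0 = 0$; degenerate matrices yield zeros, never `NaN`.
* **RLM** — maximal constant-level runs along masked collinear segments in
  four directions; short/long-run emphasis, gray-level and run-length
  non-uniformity, and the fraction of pixels starting a run. The conservation
  law $\sum_{g,l} l\, r(g,l) =$ (traversed masked pixels) is fuzz-tested.
* **GRA** — central-difference gradient magnitudes at interior pixels
  (all four neighbors masked), with moment statistics and the nonzero
  fraction.
* **ARM** — the causal 2-D autoregressive model
  $I(s) = \theta_1 I(W) + \theta_2 I(NW) + \theta_3 I(N) + \theta_4 I(NE) + e(s)$
  fit by least squares over eligible pixels. The model has no intercept, so
  levels are centered by the ROI mean before fitting (the usual zero-mean
  convention; without it a white-noise ROI would show spurious
  $\theta \approx 1/4$). The minimum-norm solution (SVD pseudoinverse)
  resolves singular designs; `Sigma` is the RMS residual.
* **WAV** — an orthonormal 2-D Haar decomposition of the ROI bounding box,
  padded with the ROI mean (not zero, to avoid fabricated edge energy) to the
  next power of two, over up to five scales. A subband's energy at a scale is
  the mean squared coefficient over positions whose spatial support square
  overlaps the mask; scales beyond the box size are emitted as 0. `HL`
  denotes high-pass along x.
* **GEO** — 73 descriptors of the binary mask: size and perimeter measures,
  Feret diameters, principal-axis elongation and eccentricity, convexity,
  radial-length statistics, symmetry overlaps, scale-normalized central
  moments with Hu-type invariants (`GeoW1..GeoW9`), and the first 12
  DC-normalized Fourier amplitudes of the boundary radius function
  (`GeoE1..GeoE12`). The family's published description names only the count
  and the W/E naming, not the 73 definitions; this registry is therefore a
  documented, deterministic reconstruction, and no claim is made that
  individual `GeoW`/`GeoE` slots coincide numerically with the original
  software's binaries.

Two geometry conventions deserve a note. `GeoPerimeter` is the city-block
boundary (count of exposed pixel edges). That estimator systematically
overestimates smooth perimeters (a digital disk has $P_{cb} \approx 8r$), so
circularity-type features are instead computed from the length of the
boundary polygon obtained by sampling the centroid radius function at 360
equal angles and smoothing it with a circular moving average spanning about
±1 pixel of arc at the mean radius — enough to remove single-pixel staircase
jitter at any lesion size while leaving spiculation lobes (angular orders
5–12, wavelength ≥ 30°) intact. With that estimator a digital disk scores
circularity ≈ 0.98 across radii 8–30, and spiculated masks score strictly
lower (≈ 0.59 for a five-lobed disk with 25% radial modulation).

## Feature selection

Selection is filter-based, once per pairwise comparison, on all samples of
the pair, *outside* cross-validation. This mirrors the clinical-radiomics
protocol the package reimplements and is optimistically biased: the held-out
fold has already influenced which features enter the classifier. The bias is
a property of the protocol, not a defect of the implementation; the
permutation-null tests quantify it (selection on 352 noise features with
n = 16 yields above-chance LOOCV accuracy even for identical recipes).

* **Subset size**: one feature per ten samples, read as nearest-integer with
  halves up: $k = \lfloor n/10 + 0.5 \rceil$. This is the only reading
  consistent with all printed per-comparison counts (57+11 samples → 7
  features; 91 → 9; 19 → 2), whereas flooring is not.
* **Fisher** — class-size-weighted between-class variance of the class means
  over pooled within-class variance. Zero within-variance with distinct
  means gets an `Inf` sentinel and ranks first.
* **POE + ACC** — greedy: the first feature minimizes the probability of
  classification error (the optimal single-threshold error in 1-D, found by
  exhaustive sweep; nearest-class-mean for more than two classes); each
  subsequent feature minimizes POE plus the mean absolute Pearson
  correlation with the already-selected set, with 1:1 weighting. Correlation
  with a constant feature is defined as 0. Ties break by registry order.
* **Mutual information** — the feature is discretized into 10 equal-width
  bins over its observed range; MI with the class label is reported in bits.
  The bin count is fixed and shared with the test oracle.

All three criteria are invariant to increasing affine rescaling of a feature
(exactly for Fisher and POE; for MI because the bin edges rescale with the
range), which is asserted as a property test.

## Classification

For each comparison the selected features are z-scored, and the generalized
eigenproblem of between-class versus within-class scatter is solved by
symmetric whitening; the eigenvectors are the MDFs. The within-scatter is
ridge-regularized by $10^{-6} \cdot \mathrm{tr}(S_w)/p$ when near-singular
(small groups can have fewer samples than features). The number of retained
MDFs is the number of eigenvalues individually exceeding 97% of the
eigenvalue sum, floored at 1 — for a two-class problem the between-scatter
has rank 1, so pairwise comparisons always retain a single MDF, which the
tests assert.

LOOCV is leakage-free by construction: the z-scoring parameters, scatter
matrices, and MDF axes are refit on every fold's n−1 training samples, and
the held-out sample is only projected and voted on. A dedicated test injects
an extreme outlier as the held-out sample and asserts the fold's training
projections are unchanged. The k-NN vote (k = 1 by default; the classifier
of the reimplemented protocol does not state k, and 1 is the common default
of its software) uses Euclidean distance in MDF space, with vote ties broken
by the nearest neighbor and distance ties by the lower sample index, for
full determinism.

Accuracy is the raw fraction correct, unbalanced — deliberately, because the
protocol under study reports raw accuracies and discusses the resulting
class-imbalance artifacts. `comparison_matrix()` reproduces the table layout
(`accuracy% (criterion; k)` cells plus a per-group misclassification table),
and `frozen_evaluate()` replays a stored feature set on a second cohort
without re-selection, as in external validation.

## The synthetic cohort generator

The generator stands in for patient data; its defaults define the study
conditions of the test suite.

Each lesion is a star-shaped region whose boundary radius is
$r(\varphi) = R\,(1 + a\, g(\varphi))$, with $g$ a unit-bounded sum of
sinusoids of angular orders 5–12 with seeded random phases and amplitudes
(low orders keep the mask simply connected), scaled anisotropically so the
major/minor axis ratio equals the `elongation` parameter at approximately
constant area. The interior is
`background + contrast_amplitude * field + noise`, where the field is white
noise convolved with an isotropic Gaussian kernel of SD
`correlation_length` and standardized to unit variance over the lesion — the
simplest random field with a controllable correlation length. Images are
written as 16-bit TIFF with background level 400 and positive lesion
contrast, emulating an enhancing lesion on post-contrast T1; masks as 8-bit
PNG. Per-sample seeds are derived deterministically from the master seed and
the class/sample indices, so cohorts are extensible without reshuffling
earlier samples.

The four default recipes (`default_recipes()`) give the canonical subtypes
distinct but overlapping texture and shape: luminal A smooth and regular,
luminal B spiculated and elongated, HER2-enriched fine-grained and
heterogeneous, TN round and circumscribed. The literature provides no
quantitative texture description per subtype, so these are calibration knobs
of the phantom — chosen once for plausible separability — and not claims
about real tumors. What passing tests show is that the pipeline recovers
class structure *that the generator put in*; they cannot show that real
subtypes are separable, that MR acquisition effects (coil bias, motion,
partial volume) are handled, or that the synthetic textures match tumor
biology.

## Numerical choices and degenerate inputs

* Entropies: natural log, $0\log 0 = 0$ (COM); base-2 for mutual
  information (reported in bits).
* Degenerate family outputs (no valid pixel pair, no interior pixel, < 20
  AR-eligible pixels) are zeros with a warning, never `NaN`, so selection
  and classification stay total.
* Masks are strictly binary pixel sets; multi-component masks fall back to
  the largest 4-connected component with a warning.
* The lesion reader enforces a 16-pixel mask floor, mirroring the ≥ 1 cm
  lesion inclusion rule that limits partial-volume effects.
* A reported protocol detail — a single two-class comparison retaining two
  MDFs — is not reproducible under the standard two-scatter formulation,
  whose between-class rank is 1; the package asserts the $\le C-1$ bound
  instead of emulating it.

## Problem sizes used by the test suite

The test and acceptance suites run entirely on synthetic data at desk scale,
chosen as the package's own trade-off between statistical resolution and
turnaround: oracle equivalence on 50 random 8×8 ROIs; planted-feature
recovery on 40 samples × 352 features over 20 seeds; permutation nulls with
100 label shuffles; and the separation sweep on 2 × 8 lesions of 64×64
pixels over 5 settings × 10 seeds. A full 256×256 lesion extracts in well
under a second, so realistic cohort sizes remain practical.

## Known limitations

* 2-D single-slice only; no 3-D texture, no DICOM, no bias-field correction.
* The GEO registry is a documented reconstruction, not a numerical clone of
  the original software's geometry module; the same caveat applies to the
  WAV ROI-overlap rule and the AR estimator.
* Selection outside CV is faithful to the reimplemented protocol but
  optimistic; use `select_features()` per fold manually if an unbiased
  estimate is needed.
* Raw-accuracy reporting inherits class-imbalance artifacts.
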