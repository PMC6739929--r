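# radtex

Radiomic texture and shape analysis of single-slice lesion MRI, with
discriminant-based classification of breast-cancer molecular subtypes and
receptor status.

## What it does

Molecular subtypes of breast cancer (luminal A, luminal B, HER2-enriched,
triple negative) are defined through immunohistochemical surrogates of
ER/PR/HER2 status and drive therapy decisions. `radtex` implements the
radiomic analysis chain used to ask whether lesion texture and shape on
contrast-enhanced MRI predict these labels non-invasively:

1. **ROI preparation** — gray levels of each lesion ROI are limited to
   μ ± 3σ (ROI mean ± 3 × population SD) and quantized to 64 levels, removing
   per-scan brightness/contrast variation.
2. **Feature extraction** — exactly 352 named features per lesion across
   seven families: first-order histogram (HIS, 9), gray-level co-occurrence
   matrices at 20 offsets × 11 Haralick statistics (COM, 220), run-length
   matrices in 4 directions (RLM, 20), absolute gradient (GRA, 5), a causal
   2-D autoregressive model (ARM, 5), Haar wavelet subband energies
   (WAV, 20), and mask geometry (GEO, 73), with MaZda-style names such as
   `S(5,-5)DifEntrp`, `45dgr_LngREmph`, `Teta4`, `GeoW7`.
3. **Feature selection** — per pairwise comparison, the top
   k = ⌊n/10 + 0.5⌋ features (one per ten samples) by one of three filter
   criteria: Fisher ratio (between-/within-class variance), greedy
   POE + ACC (probability of single-threshold classification error plus
   average absolute correlation with the already-selected set), or mutual
   information (10-bin, in bits).
4. **Classification** — the selected features are projected onto the most
   discriminating features (MDFs) of the between- vs within-class scatter
   eigenproblem (eigenvalues exceeding 97% of their sum are retained, floor
   1), and a held-out sample is classified by Euclidean 1-NN in MDF space
   under leave-one-out cross-validation, all fold parameters refit per fold.
5. **Cohort tooling** — manifests, frozen feature sets for external
   validation, pairwise comparison matrices formatted like the clinical
   tables (`accuracy% (criterion; k)`), per-pixel sliding-window feature
   maps, and a seeded synthetic lesion generator (Gaussian-correlated
   interior texture, sinusoidally spiculated and elongated outlines) that
   stands in for non-public patient data.

## Worked example

```r
library(radtex)

dir <- tempfile("cohort")
spec <- cohort_spec(
  list(class_recipe("LuminalA", correlation_length = 3, contrast_amplitude = 90,
                    noise_sd = 20, elongation = 1.2, spiculation_amplitude = 0.08,
                    mean_radius = 14),
       class_recipe("TN", correlation_length = 4, contrast_amplitude = 110,
                    noise_sd = 15, elongation = 1.05, spiculation_amplitude = 0.04,
                    mean_radius = 14)),
  n_per_class = 10, image_size = 72, seed = 42)
man <- generate_cohort(spec, dir)          # 20 TIFF/PNG pairs + manifest.csv
tab <- extract_cohort(man)                 # 20 x (1 + 352) feature table

sel <- select_features(tab, man$subtype, "fisher", c("LuminalA", "TN"))
print(sel)
#> Feature selection (fisher) for LuminalA vs TN: k = 2
#>      feature score
#>  GeoBBHeight   Inf
#>   GeoFeret90   Inf

rep <- knn_loocv(tab[sel$ranked$feature], man$subtype)
print(rep)
#> LOOCV 1-NN on 20 samples: accuracy 100.0% (MDFs retained: 1)
#>   LuminalA: 0/10 misclassified
#>   TN: 0/10 misclassified
```

With 20 samples the subset-size rule retains k = 2 features. Here the Fisher
criterion found two integer-valued geometry features whose within-class
variance happens to be zero with distinct class means — the `Inf` sentinel
that ranks such perfectly separating features first — and the two recipes
(round vs mildly elongated lesions) are separated perfectly under LOOCV; a
single MDF is retained, as always for a two-class comparison. Per-lesion
feature vectors are also available directly:

```r
les <- read_lesion(man$image[1], man$mask[1])
round(extract_all(les$image, les$mask)[
  c("S(1,0)Contrast", "GeoCircularity", "GeoElongation")], 3)
#> S(1,0)Contrast GeoCircularity  GeoElongation
#>         21.346          0.975          1.193
```

A thin CLI wraps the same stages
(`inst/cli/radtex simulate|extract|select|classify|matrix|map|registry|run`),
and `run_pipeline()` drives simulate → extract → select → classify from one
YAML config into a reproducible run directory.

## Scope

2-D single-slice lesions only; masks are inputs (no segmentation); no DICOM,
no MR acquisition modeling. The GEO family is a documented 73-feature
reconstruction that preserves the `GeoW*`/`GeoE*` naming; it is not claimed
to be numerically identical to the MaZda geometry binaries. See the methods
vignette (`vignettes/radiomic-subtyping.Rmd`) for the model, conventions,
and limitations.
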