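# relaxcell

Non-destructive cell classification from two-dimensional T1/T2 NMR
relaxometry, as a tested R pipeline over synthetic data.

## The problem

Identifying cell types, or monitoring stem-cell differentiation,
normally requires staining or lysis. Benchtop NMR relaxometry offers a
label-free alternative: a cell suspension is measured with a combined
inversion-recovery / CPMG sequence, and the joint distribution of
longitudinal (T1) and transverse (T2) relaxation times — the T1/T2
spectrum — acts as a fingerprint. Cell material produces a
short-relaxation "cell peak", excess culture medium a long-relaxation
"media peak", and lipid accumulation during adipogenic differentiation
of mesenchymal stromal cells (MSCs) adds a third peak. Classifiers
trained on these spectra can then call the cell type of an unseen
sample.

`relaxcell` implements the full chain for anyone who wants to study or
extend such a workflow without a scanner:

1. **Forward simulation** — IR-CPMG time-domain signals
   `S(TI, t) = Σ_k A_k (1 − 2 e^(−TI/T1_k)) e^(−t/T2_k)` for a library
   of cell-like phenotypes with replicate jitter and acquisition noise
   (32 log-spaced TI values 5 ms–15 s, 5000 echoes at TE = 3 ms).
2. **Reconstruction** — echo collapse, logarithmic re-gridding to 256
   bins, normalization, PCA denoising, polarity orientation, and a
   Tikhonov-regularized nonnegative 2D inverse Laplace transform
   (`min_{F≥0} ‖S − K₁ F K₂ᵀ‖² + α‖F‖²`) with SVD-compressed kernels,
   solved by accelerated projected gradient descent.
3. **Features** — peak detection (8-connected components), cell /
   media / lipid tagging, intensity-weighted centroids, and cropping to
   the cell window (T1 ≤ 3.0079 s, T2 ≤ 0.4062 s).
4. **Augmentation** — per-peak random shift (std dev in seconds) and
   intensity-preserving stretch (% of peak width) in linear
   coordinates, multiplying small cohorts for network training.
5. **Classification** — a polynomial-kernel SVM (degree 2, coef0 0, 300
   random 50/50 splits) on centroids, and two small VGG-style
   convolutional networks (7-conv/4-dense and 4-conv/4-dense with 25 %
   dropout, Adamax, 12 epochs) on spectral maps under a celltype-aware
   75/20/25 split that keeps augmented copies with their parents.

The methods vignette (`vignettes/relaxometry-classification.Rmd`)
documents the model, parameter defaults, and numerical choices.

## Worked example

```r
library(relaxcell)

# simulate one CHO-like sample and reconstruct its spectrum
td <- simulate_sample(phenotype_library()$CHO, default_protocol(), seed = 42)
spec <- reconstruct_spectrum(td, grid = spectrum_grid(100), alpha = 1e-3)

peaks <- tag_peaks(detect_peaks(spec))
for (p in peaks)
  cat(sprintf("%-5s peak: T1 = %.3f s, T2 = %.3f s\n",
              p$tag, p$centroid_t1, p$centroid_t2))
#> media peak: T1 = 2.560 s, T2 = 2.051 s
#> cell  peak: T1 = 0.505 s, T2 = 0.034 s
```

(The solver warns that its 1e-8 change tolerance was not met within the
5000-iteration cap; that is expected — see the methods vignette.)

The cell peak lands at the CHO phenotype's (jittered) ground truth of
T1 ≈ 0.45 s / T2 ≈ 0.035 s, and the media peak at its 2.5 s / 2 s
position — the two-cluster layout that makes centroid-based
classification work. A cohort-level run:

```r
man <- cohort_manifest(c("CHO", "K562"), c(15L, 15L), seed = 301)
cen <- centroid_table(cohort_spectra(man, grid_n = 100, max_iter = 3000))
run_svm_replicates(cen, svm_config(replicates = 300L, seed = 31))$mean
#> [1] 1
```

i.e. two well-separated lines are classified perfectly, matching the
high two-line accuracies of the emulated study design.

The numbered scripts under `analysis/` run the whole study in order —
`01_simulate.R` (cohort manifests and time-domain data),
`02_reconstruct.R` (spectra and the peak census), `03_features.R`
(centroid tables, cropped PNG maps), `04_augment.R` (factor-5 MSC
augmentation with lineage manifest), `05_svm.R` (accuracy versus class
count, exhaustive 2-line search, MSC task, decision boundaries),
`06_ann.R` (both network variants, replicate-averaged) — each writing
its tables under `results/`.

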