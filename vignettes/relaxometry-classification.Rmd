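---
title: "Methods: from IR-CPMG decays to cell-type calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from IR-CPMG decays to cell-type calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`relaxcell` re-implements, as a tested pipeline over synthetic data, a
non-destructive cell-classification workflow built on two-dimensional
T1/T2 NMR relaxometry: cells in suspension are measured with a combined
inversion-recovery / CPMG sequence on a benchtop scanner, the
time-domain data are inverted into a joint (T1, T2) spectrum, and the
spectra — or their peak centroids — are classified with an SVM or a
small convolutional network.  This vignette explains the model behind
each stage, the tunable parameters and their defaults, the numerical
choices, and what the synthetic tests do and do not demonstrate.

## The forward model

A sample is modelled as a mixture of relaxation components, each with a
longitudinal time constant $T_1$, a transverse time constant $T_2$ and
an amplitude $A$.  With an ideal 180° inversion pulse and an echo train
acquired at times $t = j\,\mathrm{TE}$, the signal at inversion time
$\mathrm{TI}$ is

$$ S(\mathrm{TI}, t) \;=\; \sum_k A_k\,
   \bigl(1 - 2 e^{-\mathrm{TI}/T_{1,k}}\bigr)\, e^{-t/T_{2,k}} . $$

The acquisition protocol mirrors the emulated scanner: 32
logarithmically spaced TI values from 5 ms to 15 s, 5000 echoes at
$\mathrm{TE} = 3$ ms, 40 points per echo.  The signal crosses zero at
the inversion null $\mathrm{TI} = T_1 \ln 2$; rows below the null are
negative, which is why a polarity-orientation step precedes the fit.

Noise is additive i.i.d. Gaussian per acquisition point.  The default
`noise_sigma = 0.0632` (relative to unit equilibrium magnetization)
gives a signal-to-noise ratio of about 100 on the first *collapsed*
echo, since averaging the 40 intra-echo points divides the noise by
$\sqrt{40}$.  Because nothing downstream uses intra-echo shape, the
simulator generates collapsed matrices directly with the equivalent
noise level; a raw-tensor mode exists for small protocols.

### The phenotype library

No per-line $(T_1, T_2)$ values are tabulated in the source study, so
the library ships package defaults chosen to reproduce the qualitative
layout of the published spectra: ten cell lines with cell peaks spread
over $T_1 \in [0.45, 1.2]$ s and $T_2 \in [0.028, 0.15]$ s, a common
media peak at $T_1 = 2.5$ s / $T_2 = 2$ s (slightly stronger than the
cell peak, as the excess-medium signal dominates), and for
differentiated MSCs an additional lipid component.  The lipid default
is $T_1 = 0.15$ s / $T_2 = 0.18$ s — shorter $T_1$ and longer $T_2$
than the aqueous cell peak, as expected for fat at low field — chosen
so that differentiated spectra mostly resolve three peaks, the
phenomenology the study reports.  These are stand-ins, not measured
values, and `phenotype_library()` output can be edited or replaced via
CSV.

Replicate-to-replicate biological variation is modelled as log-normal
positional jitter of each component, default 0.03 decades (about 7 %)
for cell peaks and 0.01 for the media peak.  This was calibrated once
so synthetic centroid clouds show per-line scatter elongated along
$T_2$, as the published centroid plots do; it is a visual calibration,
not ground truth.  One reported inconsistency is preserved rather than
resolved: the per-line replicate counts sum to 339 while the text
states 354, so `paper_manifest()` ships both variants, labelled.

## Reconstruction: the regularized 2D inverse Laplace transform

The postprocessing chain is: collapse intra-echo points (mean), re-grid
the 5000-echo train onto 256 logarithmic bins (bin means, empty bins
interpolated in log-time), max-normalize, PCA noise reduction, T1
polarity orientation, then invert.  PCA denoising truncates the
$32\times256$ matrix to rank 8 by default; the noiseless forward model
of a $p$-component sample has rank $\le p$, so rank 8 is conservative.

With kernels $K_1[i,k] = 1 - 2e^{-\mathrm{TI}_i/T_{1,k}}$ and
$K_2[j,l] = e^{-t_j/T_{2,l}}$ on log-spaced grids (defaults
$T_1 \in [1\,\mathrm{ms}, 15\,\mathrm{s}]$,
$T_2 \in [1\,\mathrm{ms}, 5\,\mathrm{s}]$, spanning every peak the
system produces and the TI range; grid bounds are package choices), the
spectrum $F \ge 0$ minimizes

$$ \lVert S - K_1 F K_2^{\top} \rVert_F^2 \;+\; \alpha \lVert F \rVert_F^2 . $$

Both kernels are compressed by truncated SVD (default ranks
$r_1 = 16$, $r_2 = 32$; exponential kernels have rapidly decaying
singular values, so this is lossless in practice and shrinks the data
to $r_1 \times r_2$).  The compressed problem is solved by projected
accelerated gradient descent (FISTA) with a gradient-based adaptive
restart, which empirically converges several times faster than plain
FISTA on these ill-conditioned kernels.  Defaults: iteration cap 5000,
relative-change tolerance $10^{-8}$.  The tolerance is rarely *met* —
the solver is stopped by the cap and warns; an error mode that carries
the last iterate is available.  Closely spaced peaks (the lipid/water
pair of differentiated MSCs, separated by a factor of ~4.5 in $T_1$)
only split once the iterate is deep into convergence, so the MSC
analyses run the solver to 8000 iterations; single-peak samples are
stable from ~2000.

The regularization weight defaults to $\alpha = 10^{-3}$ on
max-normalized data.  `choose_alpha()` implements the discrepancy
principle — the largest $\alpha$ whose residual stays within
$(1+\tau)$ of the expected noise norm, $\tau = 0.1$ — for use when the
noise level is known or estimable; the fixed default is used in the
analyses because every synthetic sample shares the same noise model.
The expected-noise computation accounts for intra-echo collapse, bin
averaging and normalization but not for the (small) variance removed by
PCA truncation, so chosen weights err slightly conservative.

Grid size 300×300 matches the full-resolution setting; the analyses
and tests run 100×100, which keeps a reconstruction near one second
while leaving grid cells (1.1 % in $T_1$) far finer than the
between-line separations.

## Peaks, tags, centroids, crops

Peaks are connected components (8-connectivity) of the mask
`intensity >= threshold_frac * max`, with components smaller than
`min_area = 4` cells or carrying less than 1 % of total intensity
discarded; `threshold_frac` defaults to 0.05.  The study describes
selection "by size and intensity" without values, so these are package
defaults.  Tagging is by position: centroid $T_1 \ge 2$ s is the media
window (the media peak sits at 2–3 s in every sample); remaining peaks
are cell peaks, and when two occupy the cell window the shorter-$T_1$
one is tagged lipid.  The weighted centroid is the intensity-weighted
mean $(T_1, T_2)$ in linear seconds over the peak mask only (log versus
linear weighting is unspecified in the source; linear is used and
stated).  The network input is the spectrum cropped to
$T_1 \le 3.0079$ s, $T_2 \le 0.4062$ s — the published window, which
removes the media peak.

## Augmentation

Two operators act per detected peak, in linear time coordinates, with
draws redrawn (up to 100 times) if the transformed support would leave
the grid — redraw rather than clipping keeps the applied distribution
unbiased:

* **shift** — translate by $\Delta \sim \mathcal N(0, \sigma^2)$ with
  $\sigma$ in seconds, independently per dimension;
* **stretch** — rescale about the peak centroid by
  $1 + s$, $s \sim \mathcal N(0, \sigma_s^2)$, $\sigma_s$ a fraction of
  the peak's width (its intensity-weighted standard deviation).

Transformed peaks are resampled onto the log grid by bilinear
interpolation in linear coordinates and renormalized so each peak's
total intensity is conserved exactly (bilinear interpolation of
nonnegative data is nonnegative, so the clipping guard never bites in
practice).  One consequence of the log grid worth knowing: *node sums*
are conserved, and moments computed from bare node values carry the
log-measure weighting; integral-weighted moments (weighting each cell
by its width) scale as $(1+s)^2$ under a stretch, which is what the
tests verify.  The study's selected parameters are shipped as presets:
1 % stretch / 5 ms shift for MSCs, 1 % / 1 ms for cell lines, factor 5,
originals kept and flagged (mirroring the "_Original" file convention).
Whether the original belongs to the training pool is only implied by
the source data layout; `keep_original` defaults to `TRUE`.

## Classifiers

**SVM.** Polynomial kernel, degree 2, `coef0 = 0`, on the
two-dimensional centroid features, 50/50 train/test splits repeated 300
times.  Two choices deserve a note.  First, splits are stratified per
class (the source says only "randomly split"); at the small per-class
counts involved, unstratified splits occasionally produce one-class
training sets.  Second, features are *not* standardized by default:
with `coef0 = 0` the kernel $(\gamma\,x^\top y)^2$ contains only even
monomials, so $f(-x) = f(x)$, and centering two well-separated clusters
places them symmetric about the origin — making them provably
indistinguishable (we measured chance accuracy on separable synthetic
lines).  Raw positive centroid coordinates, with the reference
implementation's $\gamma = 1/(d \cdot \mathrm{var}(x))$ scaling, behave
as published; standardization remains available as an option.

**Networks.** Two VGG-style variants, both ReLU-activated, trained with
Adamax (learning rate $10^{-3}$, batch 16) under softmax
cross-entropy for 12 epochs: the MSC variant with seven 3×3
convolutions and four dense layers, batch-normalization + 2×2
max-pooling after every other convolution starting after the first; the
cell-line variant with four convolutions each followed by
normalization and pooling, and 25 % dropout on the hidden dense layers.
Only layer counts, activations, optimizer, dropout and epochs are
published; kernel sizes (3×3), channel widths (doubling from 16 at
each pooling stage), dense widths (256/128/64), learning rate and batch
size are package defaults, configurable and deliberately unremarkable.
"Normalization layers" are realized as batch normalization; the loss is
categorical cross-entropy (implied by the softmax head).  The engine is
implemented in vectorized R (im2col + BLAS matrix products) and its
backpropagation is verified against central finite differences in the
test suite.

Inputs are cell-window maps max-normalized and resampled to 32×32.
The published pipeline exported images of unstated resolution; since
the cropped spectra are smooth one-to-three-blob maps, 32×32 loses no
class-relevant structure (peak position and width remain resolved) and
keeps a 12-epoch training around ten seconds on one CPU.  The
resolution is a constructor argument for anyone wanting more.

The celltype-aware split assigns *parent* samples per class at the
75 / 20-of-train / 25 fractions (rounded per class, at least one parent
per partition), and augmented descendants always follow their parent —
so no augmented copy of a test sample ever appears in training.  Every
class is guaranteed present in train, validation and test, which plain
random splitting does not ensure on unbalanced cohorts.

## Problem sizes in the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run a
reduced synthetic study chosen to finish in minutes while preserving
every qualitative contrast: 8 replicates per cell line (80 cell-line
samples), the full 8 + 7 MSC cohort, 100×100 reconstruction grids,
factor-5 augmentation, 10 training replicates, and 10 SVM replicates
per point of the class-count sweep (300 where a single headline number
is reported).  The full-scale setting — 354 cell-line replicates,
300×300 grids — is reachable through the same functions by changing
the manifest and `grid_n`.

## What the synthetic tests show — and what they cannot

The generator emulates peak layout, mixture structure, replicate jitter
and acquisition noise.  It does **not** emulate: field inhomogeneity or
pulse imperfections (the inversion efficiency is fixed at its ideal
value of 2), temperature drift, magnitude-detection noise floors,
sample-to-sample volume effects, biological covariance between $T_1$
and $T_2$, or any systematic difference between cell lines beyond peak
position and width.  Classification accuracies obtained on synthetic
cohorts therefore validate the *machinery* — reconstruction fidelity,
leakage-free splitting, augmentation benefit, the ordering of task
difficulty — and not the absolute separability of real cell lines.
Where the synthetic cohort reproduces published contrasts (accuracy
falling with class count; augmentation lifting small-cohort network
accuracy; high replicate variance on the 15-sample MSC task), that is
evidence the pipeline behaves like the original, not evidence about
cells.

Known limitations: Tikhonov ($L_2$) regularization spreads peaks and
cannot super-resolve components closer than roughly a factor of two in
both dimensions at this SNR; the discrepancy-based $\alpha$ selection
assumes white noise; the CNN engine is single-threaded R and meant for
maps up to ~64×64, not for large-scale training; and mixture
*quantification* is out of scope — spectrum intensity shares are not
calibrated concentration estimates, a caveat the source study itself
makes.
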