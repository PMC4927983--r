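---
title: "Segmenting and classifying breast lesions in B-mode ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and classifying breast lesions in B-mode ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buscad)
```

## The problem

Breast ultrasound is routinely used alongside mammography, particularly in
dense breasts, but reading B-mode images is subjective: speckle noise blurs
lesion boundaries, and benign and malignant appearances overlap.
Computer-aided diagnosis (CAD) pipelines support the radiologist by
segmenting the lesion in a rectangular region of interest (ROI) and scoring
its morphology, exploiting the classic observation that benign masses tend
to have smooth, near-elliptical margins while malignant masses are
irregular and spiculated.

`buscad` implements such a pipeline end to end:

1. a **synthetic phantom generator** producing speckle-textured ROIs with a
   single hypoechoic lesion and its ground-truth mask;
2. a **preprocessing chain** (adaptive Wiener filter, global histogram
   equalization, median filter);
3. five **segmenters** — region growing, k-means, fuzzy c-means, a
   self-organizing-map (SOM) pixel clusterer, and a two-phase level-set
   active contour — followed by a common postprocessing step;
4. a **ten-metric region-evaluation suite** for scoring automatic masks
   against reference masks;
5. **24 morphological descriptors** per lesion mask with a
   Gaussian-overlap feature-selection stage;
6. a **multilayer perceptron (MLP)** benign/malignant classifier trained by
   online backpropagation, with confusion-matrix statistics and ROC/AUC.

## The synthetic phantom model

No clinical images ship with the package; instead the generator emulates a
balanced phantom study (72 benign + 72 malignant ROIs by default, the
composition used throughout the examples and the acceptance script).

**Lesion shape.** A lesion is a radial-harmonic closed contour
\(r(\theta) = r_0\,(1 + \sum_k a_k \sin(k\theta + \phi_k))\), stretched by an
area-preserving aspect ratio along a random orientation. The two diagnostic
classes differ only in their margin irregularity:

* *benign*: aspect ratio in \[1, 1.25\], total harmonic amplitude
  \(\sum_k |a_k| \le 0.08\) over harmonics \(k \le 3\) — smooth, rounded;
* *malignant*: same aspect range, but \(\sum_{k\ge3} |a_k|\) drawn from
  \[0.15, 0.35\] over harmonics 3–8 — spiculated, irregular.

Both classes share the same mild ellipticity because tissue-mimicking
phantom inclusions are rounded; elongation is deliberately *not* a class
cue, so the classifier must key on margin irregularity. The base radius
\(r_0\) is drawn from 0.26–0.32 of the frame side: ROIs are conventionally
drawn tightly around the lesion plus a band of surrounding tissue, so the
lesion occupies roughly a fifth to a third of the frame. This matters
downstream — after histogram equalization the intensity histogram is nearly
uniform, and intensity-only clusterers can only cut it at mass quantiles, so
the lesion-to-frame ratio controls how well any intensity split can align
with the lesion (see *Numerical choices*). Draws whose contour would leave
the mandatory 2 px frame margin, or whose rasterization pinches off at pixel
resolution, are rejected and redrawn.

**Echo texture.** The image is
\(\mathrm{clip}\!\big(\mathrm{blur}(T \cdot R) + \varepsilon\big)\): an
echogenicity template \(T\) (background mean 0.5; lesion
`echo_contrast` = 0.35 of that — hypoechoic), multiplied by i.i.d. Rayleigh
speckle \(R\) (scale \(\sqrt{2/\pi}\), i.e. unit mean, so \(T\) sets local
brightness), blurred by a Gaussian point-spread function
(`psf_sigma` = 1.5 px), plus additive Gaussian sensor noise (sd 0.02),
clipped to \[0, 1\]. This is the simplest model that reproduces the granular
multiplicative texture of B-mode imaging. It does **not** simulate acoustic
physics: no posterior shadowing or enhancement, no depth-dependent gain, no
log-compression curve, no scan-conversion geometry. Passing tests therefore
demonstrate correct behaviour on idealized speckle phantoms, not clinical
performance.

```{r phantom-example}
ds <- generate_dataset(3, 3, shape = c(128, 128), seed = 1)
ds
```

## Preprocessing

The chain is fixed: Wiener, then equalization, then median.

* `wiener_filter()` (window 5) is the local adaptive (Lee) form: with local
  mean \(\mu\), local variance \(\sigma^2\) and noise power \(\nu^2\)
  estimated as the image-wide mean of \(\sigma^2\), the output is
  \(\mu + \frac{\max(\sigma^2-\nu^2,0)}{\max(\sigma^2,\nu^2)}(I-\mu)\) —
  flat regions collapse to their mean, edges pass through.
* `equalize()` is plain global 256-bin histogram equalization (the CDF
  map). It is global rather than adaptive because only simple equalization
  is called for; it is monotone, so intensity ordering is preserved.
* `median_filter()` (window 3) removes residual salt-type outliers.

Both windowed filters use reflect padding so borders are not darkened —
darkened borders would masquerade as hypoechoic tissue. The window sizes are
package defaults (standard speckle-reduction choices at ROI scale), not
values fixed by the underlying methodology.

## Segmentation

All segmenters run on the preprocessed ROI **except the active contour**,
which operates on the raw image. Every raw mask then passes through
`postprocess_mask()`: keep the largest 8-connected component (ties broken
toward the frame centre) and fill interior holes — this removes disconnected
speckle artifacts and joins internal valleys.

The clustering segmenters (`seg_kmeans()`, `seg_fuzzy_cmeans()`,
`seg_som()`) share `select_lesion_cluster()`: among clusters reaching the
central quarter of the frame, the one with the lowest mean intensity is the
lesion (hypoechoic); a flag inverts this for hyperechoic targets, and an
exact tie goes to the cluster containing the centre.

The SOM is a one-dimensional chain trained online on per-pixel feature
vectors (intensity, 3×3 local mean, 3×3 local std). The learning rate decays
linearly 0.5 → 0.01 and the Gaussian neighbourhood radius 1 → 0 over 10
epochs, with the pixel presentation order reshuffled per epoch under the
seed. Units are initialized at evenly spaced intensity quantiles between the
2nd and 98th percentile.

The active contour minimizes the two-phase piecewise-constant energy
(inside/outside squared deviation from the phase means), initialized from a
centred circle of radius `min(H, W)/4`, advected by the pointwise energy
competition and regularized by Gaussian smoothing of the level-set function;
after convergence (mask change below 0.1% of pixels) the darker phase is
taken as the lesion and the boundary is polished by morphological opening
then closing with a disc of radius 2 px. A region-based rather than
edge-based formulation is used because speckled ROIs have weak, noisy
gradients.

### Numerical choices worth knowing

* **Equalization and cluster counts.** Global equalization is a rank
  transform: whatever the input histogram, the output is near-uniform in
  *mass*. A two-cluster intensity quantizer therefore always cuts near the
  mass median, which matches the lesion boundary only if the lesion is about
  half the frame. For that reason the SOM default is `n_units = 4`: the
  chain quantizes the equalized axis into mass bands, and the darkest
  central band isolates a hypoechoic lesion occupying up to about a quarter
  of the ROI. On noise-free two-level images (where there are exactly two
  tissue classes and no rank pathology) two units recover the partition
  exactly, and that configuration is what the two-level tests exercise.
  k-means and fuzzy c-means intentionally stay intensity-only with k = 2 —
  they are the weakest detectors here, as intensity-only clustering after
  equalization is structurally limited.
* **Convergence.** k-means runs Lloyd iterations (at most 300) from a
  seeded draw of distinct intensities; fuzzy c-means uses fuzzifier
  \(m = 2\); the SOM always runs its 10 epochs; the active contour stops on
  mask stability and warns (returning the current mask flagged
  `converged = FALSE`) if `max_iter` is reached.
* **Determinism.** Every stochastic step takes a seed; fixed config plus
  fixed seed reproduces outputs bit for bit.

## Evaluating a segmentation

`region_metrics()` turns the pixel confusion counts (TP = overlap between
automatic mask S and reference G) into the ten regional percentages: area
overlap AOM (Jaccard), undersegmentation AUM, oversegmentation AVM,
completeness CP, correctness CR, the combined measure
CM = (AOM + CP + CR)/3, per-image quality Q (identical to AOM), pixel
accuracy A, its complement Err, and the pixel false-positive rate FPR.
These definitions satisfy, exactly and by construction: AUM + CP = 100,
AVM + CR = 100, A + Err = 100, and the CM identity — the property suite
checks all four over random counts. Dataset-level rows are unweighted
per-image means (not pooled pixels).

## Morphological descriptors

`trace_contour()` extracts a sub-pixel closed polygon from the mask by
marching squares at level 0.5. Two refinements keep \(P^2/A\)-type
descriptors honest:

* a *corner-preserving* smoothing removes the staircase jitter of the
  marching-squares polygon (which otherwise inflates perimeters by several
  percent on oblique boundaries) while leaving genuine corners and spicule
  tips untouched — vertices are classified by their net direction change
  over a 7-vertex window;
* detected corners chamfered by marching squares are restored to the
  intersection of their adjacent edge lines.

On rasterized discs and squares the test suite verifies the resulting area
and perimeter against the closed forms at 2% tolerance.

`extract_features()` then computes 24 named descriptors. The core set uses
the breast-lesion shape-analysis conventions: perimeter, form factor
\(4\pi A/P^2\), compactness \(P^2/(4\pi A)\), circularity
\(A/(\pi R_{\max}^2)\), convexity \(P_h/P\), solidity \(A/A_h\),
rectangularity \(A/A_{bb}\), residue \((A_h - A)/A_h\), and area ratio
\(\frac{1}{m\mu_R}\sum_{R_i > \mu_R}(R_i - \mu_R)\). The remaining fifteen
are documented auxiliaries: eccentricity, extent ratio, orientation,
equivalent diameter, four normalized-radial-length (NRL) statistics (mean,
sd, 32-bin entropy, zero crossings of \(R_i - \mu_R\)), boundary roughness,
radial variance ratio \(\sigma_R/\mu_R\), hull perimeter and area,
bounding-box aspect, area, and maximum radial length. Exact formulas for
circularity, area ratio and residue follow the conventions cited in the
breast-mass shape literature; where the literature admits variants, the
implemented formula is the one stated in the reference pages.

## Feature selection by Gaussian overlap

Each descriptor is min-max normalized over the dataset; per-class Gaussians
are fitted (sample mean, n−1 sd); and descriptors are ranked by the
overlapping coefficient
\(\mathrm{OVL} = \int \min(N_b, N_m)\,dx\) — the shared area under the two
class density curves (closed form for equal sds, adaptive quadrature
otherwise). Selection by a *numeric* threshold (default
`max_overlap = 0.35`) replaces the visual inspection of distribution curves
that this procedure descends from: clearly bimodal descriptors pass, heavily
overlapping ones fail, and the choice is reproducible. `autoplot()` on the
ranking draws exactly the per-class curves a reader would have inspected.

## Classification

The classifier is deliberately minimal, matching its published
configuration: one hidden layer, two sigmoid outputs (benign, malignant
scores), online backpropagation with a constant learning rate (default 0.5)
and uniform \([-0.5, 0.5]\) initial weights; inputs are min-max normalized
by training statistics; targets are one-hot. Training stops at mean squared
error 0.01 (an "acceptable error" is not otherwise quantified) or at 10,000
epochs. The reference topology is 3-2-2 on (form factor, area ratio,
solidity). Data are split 70/30 by a stratified random partition with
floor-per-class rounding — 72 + 72 cases give 100 training and 44 validation
cases. Malignant is the positive class throughout; a score tie resolves to
benign, the conservative choice for false-positive accounting. ROC curves
sweep the malignancy score; the trapezoidal AUC equals the normalized
Mann–Whitney U statistic, which the tests verify.

```{r classify-example, eval = FALSE}
ds$segmask <- lapply(ds$image, segment_lesion, method = "som")
feats <- feature_table(ds, mask_col = "segmask")
parts <- split_train_validation(feats, 0.7, seed = 1)
model <- mlp_train(mlp_init(3, 2, seed = 1), parts$train,
                   c("form_factor", "area_ratio", "solidity"))
evaluate_classifier(model, parts$validation)$metrics
```

## Problem sizes and design decisions

* The reference experiments run at 128 × 128 px with 72 + 72 images; the
  test suite uses the same composition for the end-to-end property and
  smaller frames (64–96 px, up to 40 images) elsewhere. These sizes keep a
  full pipeline run in the tens of seconds on one core while leaving every
  statistic well-resolved.
* Matrices are indexed 1-based `(row, col)`, the natural convention in R;
  masks are stored on disk as 0/255 8-bit images.
* Images and masks live in tibble list-columns; every tabular result
  (feature tables, metric reports, rankings, predictions, ROC points) is a
  tibble, with `tidy()`/`glance()`/`autoplot()` methods on fitted objects.
* The quantization error of the online SOM is recorded per epoch; it
  decreases over training but is not strictly monotone epoch-to-epoch —
  single-sample updates can transiently raise it, which is expected
  behaviour for online competitive learning.

## Known limitations

* The phantom generator makes no claim of acoustic realism (no shadowing,
  no log compression); conclusions transfer to idealized speckle phantoms
  only.
* Intensity-only clustering segmenters inherit the equalization mass-split
  limitation described above; they are retained for comparison, not as
  recommended detectors.
* The MLP has no momentum, regularization or early-stopping on validation
  error; it reproduces a deliberately simple training scheme.
* Multi-lesion ROIs, 3-D volumes and DICOM ingestion are out of scope.
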