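# buscad

Computer-aided diagnosis (CAD) for breast ultrasound: segment a lesion in a
B-mode region of interest (ROI), describe its shape, and classify it as
benign or malignant.

Reading breast ultrasound is hard because speckle noise obscures lesion
margins and benign/malignant appearances overlap; CAD pipelines give the
radiologist a reproducible second opinion. `buscad` is aimed at researchers
in medical image analysis who want a complete, tested, scriptable reference
pipeline of the classic morphological school: no deep learning, every stage
inspectable.

The pipeline, end to end:

* **Synthetic phantoms** — speckle-textured ROIs with one embedded
  hypoechoic lesion (benign = smooth near-ellipse, malignant = spiculated
  radial-harmonic contour \(r(\theta) = r_0(1 + \sum_k a_k\sin(k\theta +
  \phi_k))\)), rendered as
  \(\mathrm{clip}(\mathrm{blur}(T \cdot R) + \varepsilon)\) with Rayleigh
  multiplicative speckle \(R\), plus ground-truth masks and labels.
* **Preprocessing** — adaptive Wiener filter, global 256-bin histogram
  equalization, median filter, in that order.
* **Segmentation** — five detectors: region growing, k-means, fuzzy
  c-means, a 1-D self-organizing map (SOM) on per-pixel (intensity, local
  mean, local std) features, and a two-phase piecewise-constant level-set
  active contour; all followed by largest-component selection and hole
  filling.
* **Evaluation** — the ten regional measures AOM, AUM, AVM, CM, CP, CR, Q,
  A, Err, FPR (e.g. AOM \(=100\,|S\cap G|/|S\cup G|\),
  CM \(=(\mathrm{AOM}+\mathrm{CP}+\mathrm{CR})/3\)).
* **Shape description** — 24 morphological descriptors per mask (form
  factor \(4\pi A/P^2\), solidity \(A/A_h\), area ratio, normalized radial
  length statistics, ...), computed on a sub-pixel marching-squares
  contour.
* **Feature selection** — per-class Gaussian fits per normalized
  descriptor, ranked by the overlapping coefficient
  \(\mathrm{OVL}=\int\min(N_b,N_m)\,dx\); small overlap = discriminative.
* **Classification** — a one-hidden-layer MLP (logistic activations, two
  outputs) trained by online backpropagation with constant learning rate on
  a stratified 70/30 split; confusion-matrix statistics, ROC and
  trapezoidal AUC.

## Worked example

```r
library(buscad)

ds <- generate_dataset(72, 72, seed = 1)             # 144 phantom ROIs
ds$segmask <- lapply(ds$image, segment_lesion, method = "som")

scores <- purrr::map2_dfr(ds$segmask, ds$mask,
                          ~region_metrics(pixel_confusion(.x, .y)))
round(aggregate_metrics(scores), 2)
#>     AOM   AUM   AVM    CM    CP    CR     Q     A   Err   FPR
#> 1  94.7  2.11  3.22  96.5  97.9  96.8  94.7  98.6  1.45  1.08
```

The SOM detector recovers on average 94.7% of the lesion area (AOM, the
Jaccard overlap with ground truth, in percent), missing 2.1% of true lesion
(AUM) and spilling 3.2% outside it (AVM).

```r
feats <- feature_table(ds, mask_col = "segmask")
sel <- select_features(feats)
tidy(sel)[1:5, c("feature", "mu_b", "mu_m", "overlap")]
#>   feature       mu_b   mu_m  overlap
#> 1 roughness   0.207  0.629    0.176
#> 2 residue     0.0884 0.463    0.195
#> 3 solidity    0.912  0.537    0.195
#> 4 nrl_entropy 0.502  0.819    0.196
#> 5 form_factor 0.874  0.516    0.252
```

Each row is one descriptor with its benign/malignant class means (after
min-max normalization) and the area shared by the two class density curves:
benign lesions are more solid and rounder (solidity 0.91 vs 0.54, form
factor 0.87 vs 0.52), and overlaps below the 0.35 threshold mark the
descriptor as selected.

```r
parts <- split_train_validation(feats, 0.7, seed = 1)   # 100 train / 44 validation
model <- mlp_train(mlp_init(3, 2, seed = 1), parts$train,
                   c("form_factor", "area_ratio", "solidity"), seed = 1)
model
#> <bus_mlp> 3-2-2 sigmoid network (14 parameters), eta = 0.5
#>   trained 10000 epochs, final MSE 0.01007, converged: FALSE

ev <- evaluate_classifier(model, parts$validation)
ev$confusion; round(ev$metrics, 3); ev$auc
#>   TP FN FP TN
#> 1 22  0  0 22
#>   sensitivity specificity accuracy
#> 1           1           1        1
#> [1] 1
```

All 44 held-out phantoms are classified correctly here; across different
split seeds the validation accuracy typically sits in the 0.90–1.00 range.
`autoplot(ev$roc)` draws the ROC curve, `autoplot(sel)` the class density
curves behind the selection.

## Command line

A thin CLI over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/buscad.R", package = "buscad"))')
Rscript $CLI simulate --out data --n-benign 72 --n-malignant 72 --seed 1
Rscript $CLI segment --image data/images/001.png --out mask.png --method som
Rscript $CLI benchmark-seg --data data --out seg_report.csv
Rscript $CLI features --data data --out features.csv
Rscript $CLI select-features --features features.csv --out ranking.csv
Rscript $CLI train --features features.csv --model model.json --metrics metrics.csv
Rscript $CLI evaluate --model model.json --features features.csv --out-prefix eval
```

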