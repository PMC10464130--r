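# radonscar

Texture analysis of left-ventricular (LV) endocardial scar in cardiac CT,
built on Radon-transform descriptors.

Scar tissue after myocardial infarction retains contrast agent on
delayed-enhancement CT and appears hyperintense against healthy myocardium
(Hounsfield units near 59 ± 21 HU). `radonscar` is for image-analysis
researchers who want a reproducible, fully seeded implementation of the
descriptor pipeline that separates "scar" from "normal" tissue patches:

1. **Scar-candidate localization** — a myocardial pixel is a candidate when
   its value strictly exceeds `μ_h + k·σ_h` of healthy tissue (k = 3 by
   default; k = 2 gives the permissive contrast rule), followed by binary
   morphological cleanup (opening then closing). Healthy statistics are
   estimated robustly by first excluding the above-mean "white" pixels of a
   mean-intensity binarization. Seeded region growing is available for
   corroborating the region statistics.
2. **Patch extraction** — fixed-size tiles (default 25×25) sampled fully
   inside each class mask, without replacement, by seeded shuffle.
3. **Radon transform** — for each angle θ in 0°…179°, every pixel's value is
   accumulated onto unit-spaced signed offset bins at its rotated column
   coordinate `t = Δc·cosθ − Δr·sinθ` (bilinear splat ≡ rotate-and-sum).
   Projections conserve the tile total exactly and the transform is applied
   as one cached sparse operator.
4. **LBP features** — the sinogram, rescaled to [0, 255], is encoded by
   rotation-invariant uniform local binary patterns (P = 8, R = 1): uniform
   codes (≤ 2 circular transitions) keyed by set-bit count, non-uniform codes
   pooled, giving the 10-bin normalized histogram used as the feature vector.
5. **Class dissimilarity** — 1-D Wasserstein distance
   `W₁(p,q) = Σ_k |CDF_p(k) − CDF_q(k)|` between the two class mean
   histograms (range 0–9 on 10 bins).
6. **Classification** — stratified 5-fold cross-validation of a decision
   tree, an RBF SVM and a ridge logistic regression; confusion counts are
   pooled over folds and reported as sensitivity, specificity and accuracy
   (scar = positive class).

Because no patient CT data ships with the package, a synthetic short-axis
phantom (`generate_phantom()`) provides images with ground-truth myocardium
and scar masks: an annulus at 59 ± 21 HU with hyperintense scar arcs
(mean + 4 SD) whose noise field is spatially smoothed, so scar differs in
texture as well as intensity.

## Worked example

```r
library(radonscar)

spec <- phantom_spec(seed = 7)            # 256x256 slice, two scar arcs
ph   <- generate_phantom(spec)

healthy <- estimate_healthy_stats(ph$image, ph$myocardium)
print(healthy)
#> region_stats: mean 56.31 HU, SD 18.67 HU over 14399 pixels

scar_mask <- scar_pipeline(ph$image, ph$myocardium, healthy, k = 3)
dice_coefficient(scar_mask, ph$scar)
#> [1] 1

ps    <- phantom_patch_sets(spec, n_per_class = 50)
feats <- patch_features(ps$patches)       # 100 x 10 Radon-LBP histograms
class_dissimilarity(feats)$distance
#> [1] 0.5320052

reports <- run_models(feats, k = 5, seed = 7)
for (r in reports)
  cat(sprintf("%-20s accuracy %.3f  sensitivity %.3f  specificity %.3f\n",
              r$model, r$accuracy, r$sensitivity, r$specificity))
#> decision_tree        accuracy 1.000  sensitivity 1.000  specificity 1.000
#> svm                  accuracy 1.000  sensitivity 1.000  specificity 1.000
#> logistic_regression  accuracy 1.000  sensitivity 1.000  specificity 1.000
```

Reading the numbers: the healthy-tissue estimate (56.3 ± 18.7 HU over the
below-mean myocardium) sits slightly under the generating 59 ± 21 HU because
the estimator truncates the upper tail; the k = 3 threshold it implies
(≈ 112 HU) captures the 143 ± ~7 HU scar while healthy pixels above it are
isolated speckle that the morphological opening removes — hence the perfect
Dice overlap with the ground-truth mask. The Wasserstein distance of ≈ 0.53
between the class mean histograms says the smoothed scar texture visibly
shifts the LBP histogram, and at this separation all three classifiers are
perfect on 50 + 50 patches; a null control with both classes drawn from
healthy tissue drops them to chance (see the test suite).

A command-line front end with `phantom`, `localize`, `patches`, `radon`,
`features`, `dissimilarity`, `train` and `run-all` subcommands is installed
at `inst/cli/radonscar`, and `run_pipeline()` chains every stage with all
intermediates, a config echo and a run log written to an output directory.

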