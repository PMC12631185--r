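# leafstack

Hybrid handcrafted/deep feature stacking for plant leaf disease
classification, in R.

Leaf diseases express themselves as discoloration, surface texture and
outline deformation. `leafstack` implements a complete, testable pipeline
for classifying single-leaf RGB images under controlled imaging conditions,
aimed at plant-pathology and agricultural image-analysis work where both
the predictions and their *reasons* matter:

1. **Handcrafted descriptors** (321 dims): HSV + LAB color histograms
   (`H_c(b) = Σ_i δ(I_c(i) ∈ b)`, 8 bins/channel), dominant colors by
   k-means (k = 3) over RGB pixels, local binary pattern histogram
   (`LBP_{P,R} = Σ_p s(g_p − g_c) 2^p`, P = 8, R = 1), gray-level
   co-occurrence contrast `Σ (i−j)² P(i,j)` and angular second moment
   `Σ P(i,j)²`, and shape area/perimeter/circularity `C = 4πA/P²` from
   Otsu-based segmentation.
2. **Deep features**: `f_deep = GAP(φ(x; θ))` from a pluggable
   convolutional backbone (built-in seeded surrogate, or any pretrained
   network through an `external` adapter), fused as
   `F = [f_trad ‖ f_deep]`.
3. **PCA reduction**: standardize, eigendecompose `C = XᵀX/(n−1)`, project
   `Z = X W_k` (95% retained variance by default).
4. **Two-stage stack**: a base learner (rf / xgb / gb / knn / lr) produces
   class probabilities `p = M(Z)`; a dense neural head —
   512 → 256 → 128 ReLU units with dropout 0.3, softmax output — refines
   them. The head trains on stratified out-of-fold probabilities to avoid
   stacking leakage, with Adam, early stopping, and full seeding.
5. **Evaluation and explanation**: classification report, confusion
   matrix, one-vs-rest ROC/AUC, training-history curves, and a from-scratch
   tabular LIME (`π_x(z) = exp(−D(x,z)²/σ²)`, K-sparse weighted ridge
   surrogate) for per-prediction attributions.

A seeded synthetic leaf-image generator (class-dependent hue, lesions,
texture noise, leaf eccentricity on a uniform background) makes the whole
pipeline exercisable end-to-end without any external dataset or weights.

## Worked example

Fit an lr → DNN stack on a synthetic 3-class feature table with a moderate
class signal (class means 2 noise-sd apart), and evaluate on a held-out
split:

```r
library(leafstack)

tab <- generate_feature_table(n_per_class = 200, n_classes = 3, dim = 10,
                              separation = 2, seed = 42)
set.seed(42)
o <- sample.int(600)
tr <- o[1:420]; va <- o[421:510]; te <- o[511:600]

stack <- fit_hybrid(base_learner_config("lr", seed = 42),
                    tab$X[tr, ], tab$y[tr], tab$X[va, ], tab$y[va],
                    seed = 42)
pred <- predict(stack, tab$X[te, ])
print(classification_report(tab$y[te], pred$labels, stack$classes))
cat(sprintf("macro AUC: %.4f\n",
            roc_auc_ovr(tab$y[te], pred$probabilities, stack$classes)$macro))
```

```
Accuracy: 0.7333
    class precision recall     f1 support
1 class01    0.5882 0.8000 0.6780      25
2 class02    0.7500 0.7000 0.7241      30
3 class03    0.8929 0.7143 0.7937      35
macro    P 0.7437 R 0.7381 F1 0.7319
weighted P 0.7606 R 0.7333 F1 0.7383
macro AUC: 0.8868
```

With overlapping classes (2 sd between means, unit noise) the stack reaches
73% accuracy against a 33% chance floor; the macro AUC of 0.89 says the
ranked probabilities separate classes better than the hard labels alone.
At `separation = 6` the same pipeline is errorless, and at `separation = 0`
it honestly returns chance — both are asserted by the test suite.

The full image pipeline — simulation, balancing, stratified 70/15/15
split, feature extraction and fusion, PCA, stacking, evaluation,
explanations — runs from one config:

```r
res <- run_pipeline(run_config(workdir = "out", learners = "all", seed = 1))
```

writing per-learner `report_*.json`, `confusion_*.csv`, `history_*.csv`
and `explanation_*.json` under `out/`. A thin CLI wrapper is included at
`inst/cli/leafstack.R`:

```sh
Rscript inst/cli/leafstack.R run --out out --seed 1 --learner all
```

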