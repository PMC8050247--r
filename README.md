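# metsum

Balanced sparse logistic classification and ingredient decomposition
for binary metabolomic feature tables.

Untargeted tandem mass spectrometry turns a biological sample into a
binary vector of molecular features: 1 if a compound (or clustered
MS/MS spectrum) was detected, 0 if not. `metsum` provides two analyses
over such presence/absence tables, built on one optimization core:

* **Phenotype classification with artifact auditing.** Repository-scale
  cohorts aggregate studies with different acquisition protocols and
  heavy class imbalance (>90% healthy controls is typical). `metsum`
  fits one-vs-rest logistic regression under a *class-balanced* loss —
  each sample weighted by the inverse of its class multiplicity, so
  every class contributes loss mass exactly 1:

  $$\min_\beta \sum_{t} \frac{L(f(x^t), y^t)}{b^t}
    + \lambda \lVert\beta\rVert_1, \qquad
    b^t = \#\{s: y^s = y^t\}.$$

  The L1 penalty leaves only a handful of nonzero coefficients, so the
  model is interpretable: top-ranked features are candidate biomarkers,
  and features that turn out to track an acquisition protocol (e.g. an
  internal standard spiked under one protocol only) can be blocklisted
  and the model retrained — the remove-and-retrain audit loop.

* **Decomposition of complex samples into raw ingredients.** Under the
  union assumption — a mixture's binary profile is approximately the
  union of its components' profiles — the abundance vector $x$ over a
  reference library $D$ of ingredient profiles minimizes the balanced
  cross-entropy objective

  $$\min_x \sum_{t}
    \frac{\mathrm{CE}\big(c^t,\, \sigma((Dx)^t)\big)}{b^t}
    + \lambda\lVert x\rVert_1,$$

  with $b^t$ the count of entries of $c$ sharing value $c^t$. The
  penalty λ is swept (analytic $\lambda_{\max}$, geometric descent,
  bisection) until exactly *k* coefficients are nonzero; those
  ingredients, ranked by coefficient, are the prediction (default
  k = 5).

A synthetic-data module generates union-composed mixtures, imbalanced
cohorts and protocol-confounded "internal standard" features with full
ground truth, so the entire pipeline is testable without any external
download. The solver (FISTA proximal gradient) is deterministic
throughout; identical inputs give bit-identical results.

## Worked example: decomposing a noisy mixture

```r
library(metsum)

# reference library: 40 ingredients x 800 features, 20-feature supports,
# 20% of each support shared across ingredients
lib  <- make_library(n_features = 800, n_ingredients = 40,
                     support_size = 20, overlap = 0.2, seed = 11)
# a "dish": union of 5 ingredients, 5% dropout, 2% spurious detections
dish <- make_complex(lib, k = 5, dropout = 0.05, spurious = 0.02, seed = 99)

res <- predict_ingredients(lib, dish$sample, k = 5)
res
#> decomposition_result: 5 selected (lambda = 0.08388, objective = 1.378)
#>  ingredient abundance
#>      ING032 0.2994016
#>      ING034 0.1656503
#>      ING022 0.1656503
#>      ING035 0.1656503
#>      ING033 0.1656503

dish$truth$true_ingredients
#> [1] "ING022" "ING032" "ING033" "ING034" "ING035"
overlap_score(res$selected, dish$truth$true_ingredients)
#> [1] 5
```

All five true ingredients are recovered; `res$path_log` records the
λ values visited and the support size at each (here λ_max ≈ 0.105 with
support 0, then 0.084 with support 5, so the path stopped immediately).

## Worked example: auditing a batch-effect biomarker

```r
# training cohort: the "obese" samples all come from one dataset whose
# protocol spikes an internal standard; "healthy" samples do not
train <- make_cohort(c(healthy = 40, obese = 40), n_features = 200,
                     signal_per_class = 5, signal_penetrance = 0.9,
                     background_rate = 0.05,
                     confound = list(class = "obese", dataset_id = "DS_STD",
                                     n_features = 1), seed = 21)
# shifted test cohort: the same standard now appears in healthy samples
shifted <- make_cohort(c(healthy = 40, obese = 40), n_features = 200,
                       signal_per_class = 5, signal_penetrance = 0.9,
                       background_rate = 0.05,
                       confound = list(class = "healthy",
                                       dataset_id = "DS_SHIFT",
                                       n_features = 1), seed = 22)

model <- train_classifier(train$X, train$pheno, penalty = "l1",
                          strength = 0.01)
model
#> balanced_logistic: 2 classes, 200 features (2 nonzero coefs, 0.5%), penalty l1 @ 0.01

rank_biomarkers(model, 4)           # F000011 is the planted standard
#>  feature_id class_label coefficient rank ...
#>     F000011       obese     9.19019    1
#>     ...

evaluate_classification(model, shifted$X, shifted$pheno)$accuracy
#> [1] 0                               # the standard misleads completely

model2 <- remove_and_retrain(model, train$X, train$pheno, "F000011")
evaluate_classification(model2, shifted$X, shifted$pheno)$accuracy
#> [1] 1                               # biology carries the prediction
```

The sparse model leaned almost entirely on the internal standard
(coefficient 9.19), classified the protocol rather than the phenotype,
and collapsed on the shifted cohort; blocklisting the standard and
retraining restores perfect accuracy.

## Command-line interface

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "metsum.R", package = "metsum"))')
Rscript $CLI simulate library --n-features 800 --n-ingredients 40 \
        --support 20 --overlap 0.2 --seed 11 --out sim/
Rscript $CLI decompose --library sim/library.tsv --sample dish.tsv \
        --k 5 --out result.json
Rscript $CLI classify train --features X.tsv --meta meta.tsv \
        --penalty l1 --strength auto --out model.json
```

Feature tables are dense TSV (feature IDs in the first column, sample
IDs in the header) or MatrixMarket coordinate files with `.features` /
`.samples` ID sidecars for repository-scale sparse matrices.

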