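# ddss — surgeon-specific difficulty assessment for third-molar extraction

`ddss` assesses the operative difficulty of impacted mandibular third-molar
(M3M) extraction *per surgeon* rather than per tooth. In a training clinic,
the same case is easy for a fifth-year resident and hard for a first-month
one; rule-based scales (Pell & Gregory depth, Winter angulation,
Delphi-derived scores) ignore that. The package is written for surgical-
education and clinical-ML researchers who want an interpretable,
reproducible pipeline from raw extraction records to per-group difficulty
predictions and resident learning curves.

## Method

Each extraction record carries 14 ordinal difficulty indicators (second-
molar condition and stability, M3M–IAN relationship, Winter angulation,
Pell & Gregory depth, crown condition, root number/morphology/width, crown
resistance, age, mouth opening, BMI, gender) and an operative time in
seconds, graded into three classes: Class 1 (< 600 s), Class 2
(600–1200 s), Class 3 (> 1200 s).

1. **Preference sequences.** For surgeon *s*, fit the Lasso path
   ½n‖y − β₀ − Xβ‖² + λ‖β‖₁ of the per-surgeon z-scored duration on the
   standardized indicator codes, over a geometric grid of 200 penalties
   from λ_max down to 10⁻⁴ λ_max. The order in which coefficients first
   become nonzero as λ decreases is the surgeon's signature.
2. **Decoupling.** Token-level Levenshtein distances between signatures →
   average-linkage hierarchical clustering → two experience groups.
3. **Per-group classifiers.** One SVM-RBF (or random forest / XGBoost) per
   group, hyperparameters chosen by seeded 5-fold CV maximizing
   macro-average one-vs-rest AUC; test records are routed to their
   surgeon's group (centroid routing for unknown surgeons).
4. **Learning curves.** Month-by-month pooled Lasso fits; the factors with
   |β(λ₀ = 0.01)| ≥ 0.05 are the retained difficulty factors of that
   month.

Because the original records are private, the package includes a synthetic
clinic generator (`default_config()`, `generate_dataset()`) that emulates
the published indicator marginals and per-surgeon duration profiles, with
two planted experience groups whose effect supports differ and whose
non-core novice effects decay with tenure. It is first-class, tested code —
the test bed for everything else.

## Worked example

```r
library(ddss)

cfg    <- default_config(seed = 1)     # nine-surgeon synthetic clinic
clinic <- generate_dataset(cfg)        # 604 records, 18 columns

groups <- decouple_surgeons(clinic)
as.data.frame(groups)
#>   surgeon_id cluster
#> 1         s1       1
#> 2         s2       1
#> 3         s3       1
#> 4         s4       1
#> 5         s5       2
#> 6         s6       2
#> 7         s7       1
#> 8         s8       2
#> 9         s9       2
```

Cluster 1 is the experienced group. Its members' signatures start with the
four core factors, novices' with the anatomy factors they still struggle
with:

```r
attr(groups, "sequences")$sequence[c(1, 6)]
#> [1] "Angle>Resistance>Gender>Opening>Morphology>Age>IAN>Roots>Depth>Width>BMI>Crown>Stability>SMC"
#> [2] "IAN>Stability>Depth>Age>Roots>SMC>Gender>BMI>Width>Morphology>Crown>Resistance>Angle>Opening"

group_duration_test(clinic, groups)
#> # A tibble: 1 × 7
#>   statistic    df  p_value mean_cluster1 mean_cluster2 n_cluster1 n_cluster2
#>       <dbl> <dbl>    <dbl>         <dbl>         <dbl>      <int>      <int>
#> 1     -8.36   602 4.38e-16          972.         1301.        364        240
```

The experienced group operates ~330 s faster (p ≈ 4e-16, pooled-variance
t-test). A group-level Lasso retains exactly four factors for them
(impacted type, crown resistance, mouth opening, gender) and all fourteen
for the novices — `retained_features(fit_lasso_path(...))`. Per-group
classifiers then beat a single pooled model:

```r
compare_pipelines(clinic, seed = 1, model_kinds = "svm")
#>   partitioner model accuracy macro_auc n_test
#> 1       lasso   svm    0.788     0.879    118
#> 2         gmm   svm    0.669     0.767    118
#> 3        none   svm    0.720     0.816    118
```

`run_ddss()` wires the whole pipeline together and writes CSV/JSON
artifacts; `run_learning_curve()` emits the monthly retained-factor
timeline; `autoplot()` methods draw coefficient trajectories, the distance
matrix, learning-curve heatmaps and confusion matrices. A thin CLI wrapper
lives at `inst/cli/ddss.R` (`simulate`, `run`, `learning-curve`
subcommands).

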