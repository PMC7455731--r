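# ccsatlas

Curation, prediction and use of **collision cross-section (CCS)** values for
small-molecule identification in ion mobility–mass spectrometry (IM–MS)
metabolomics.

The CCS of an ion — its rotationally averaged collision area with a buffer
gas, in Å² — is a physicochemical identifier orthogonal to *m/z*. Using it in
practice raises three problems that this package addresses for analytical
chemists and computational metabolomics developers:

1. **Heterogeneous experimental records.** Published CCS values for the same
   compound come from different laboratories, datasets and instrument
   families (drift-tube DTIM, travelling-wave TWIM, trapped TIMS) and
   disagree. `unify_ccs()` runs a five-step standardization: quality check
   (structures, adduct whitelist, m/z error > 10 ppm), within-dataset
   replicate consistency (records whose maximum difference exceeds 0.5% are
   dropped, otherwise averaged), per-super-class trend-line outlier removal
   (CCS = a·(m/z)^b fitted on log–log axes; records outside the two-sided 99%
   prediction interval removed), consensus averaging with DTIM priority, and
   a confidence-level cascade (Level 1: ≥2 DTIM datasets within 1%; Level 2:
   ≥2 datasets within 3%; Conflict: ≥2 datasets above 3%; Level 3: single
   dataset; Level 4 is reserved for predictions).

2. **Missing values for most structures.** `train_ccs_model()` fits an
   ε-support-vector regression (RBF kernel) on Z-scored molecular
   descriptors, with KNN imputation, recursive feature elimination driven by
   LASSO coefficients under repeated subsampling (`rfecv_select()`), and
   grid-search hyperparameter tuning by repeated 10-fold cross-validation.
   Every prediction from `predict_ccs()` carries a **representative
   structure similarity** (RSS) reliability score — the mean of the five
   highest Tanimoto coefficients between the query fingerprint and the
   training set,

   RSS(A) = (1/5) Σᵢ TCᵢ, TC(A,B) = |A∩B| / (|A| + |B| − |A∩B|),

   banded into small (≤ 0.6), medium (0.6–0.8] and large (> 0.8) reliability
   groups.

3. **Candidate ambiguity in annotation.** `annotate_features()` matches
   measured features (m/z, CCS, MS/MS) against a candidate database:
   m/z within 25 ppm ([M+H]⁺/[M−H]⁻ by default), a trapezoidal CCS score
   (1 below Δ = 2%, linear to 0 at 4%, candidates beyond 4% removed), a
   reverse dot-product MS/MS score over reference-library peaks, and the
   weighted fusion S = 0.3·S_ccs + 0.7·S_msms that ranks candidates.

A deterministic simulator (`simulate_library()`, `simulate_records()`,
`simulate_spectra()`, `simulate_annotation_benchmark()`) generates compound
libraries of real structures with class-specific power-law CCS ground truth,
multi-laboratory records with injected faults, and toy spectra, so the whole
stack is testable offline.

## Worked example

```r
library(ccsatlas)

cfg <- simulation_config(seed = 7)      # 4 datasets: 2 DTIM, 1 TWIM, 1 TIMS
lib <- simulate_library(cfg)            # 94 real structures, 5 super classes
rec <- simulate_records(lib, cfg)       # 737 records, 13 displaced by ±25%

res <- unify_ccs(rec, lib$compounds)
nrow(res$unified)                       # 187 unified CCS values
table(res$unified$level)
#>   1    2    3
#>  75  103    9
table(res$removed$stage)
#> intra-dataset     trendline
#>            64            11
```

All 13 injected outliers are removed (11 at the trend-line stage, the rest
caught earlier by the 0.5% replicate rule), with no clean record lost at the
trend-line stage. A prediction model on the same library:

```r
inst  <- simulate_training_instances(lib, cfg, polarity = "+")
model <- train_ccs_model(inst, lib$compounds, "+", C = 10, gamma = 2^-5)
model
#> <ccs_model> polarity + | 30 descriptors | 94 training instances
#>   C = 10, gamma = 0.03125, epsilon = 0.1
#>   training MRE 1.82%, ARE 1.85%, R2 0.9939

predict_ccs(model, lib$compounds[1:3, ], "[M+H]+")
#>        compound_id adduct   ccs    rss rss_group level
#> SIM001      SIM001 [M+H]+ 85.05 0.7101    medium     4
#> SIM002      SIM002 [M+H]+ 86.45 0.8170     large     4
#> SIM003      SIM003 [M+H]+ 90.92 0.8014     large     4
```

Predictions are flagged confidence level 4; `rss` tells you how well each
query is represented in the training set. Even a compound that *is* in the
training set does not automatically score RSS = 1: the score averages the
five best Tanimoto coefficients, so it is high only when the query sits in a
well-populated structural neighbourhood.

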