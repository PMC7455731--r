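---
title: "Methods: CCS standardization, prediction and multi-dimensional annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CCS standardization, prediction and multi-dimensional annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccsatlas)
```

This vignette is the package's account of the statistical and
cheminformatic machinery it implements: the models, their assumptions, the
tunable parameters, and the design decisions taken where the procedure was
genuinely open.

## 1. Standardizing heterogeneous CCS records

Experimental collision cross-sections for the same ion differ across
laboratories and instrument families (drift-tube DTIM, travelling-wave TWIM,
trapped TIMS), typically by a few tenths of a percent within a platform and
a few percent across platforms. `unify_ccs()` reduces a multi-source record
table to one consensus value per compound × adduct in five stages.

**Quality check.** Records are dropped when the compound has no parseable
structure, the adduct is off the whitelist (nine positive, six negative
singly charged electrospray species; the seven most common of these form the
model-training whitelist), or the reported m/z deviates from the theoretical
adduct m/z by more than 10 ppm. Records without a reported m/z pass the m/z
sub-check — absence of evidence is not treated as a fault.

**Replicate consistency (0.5% rule).** Within one dataset, replicate records
of one ion are averaged if their maximum difference is at most 0.5%, and all
removed otherwise. We define *maximum difference* as
`(max − min) / mean × 100`: the mean denominator is symmetric in the
replicates, which matters because no replicate is privileged. With Gaussian
replicate noise of σ ≈ 0.3% a noticeable share of duplicate pairs legitimately
exceeds 0.5%; the rule is deliberately strict — inconsistent replicates are
evidence of a calibration problem, not something to average away.

**Trend-line outlier removal.** Within each (chemical super class, polarity)
stratum of at least 10 records, CCS follows a power law in ion m/z closely:
`CCS = a·(m/z)^b`. We fit it by ordinary least squares on log–log axes and
remove records outside the two-sided 99% prediction interval. Points with
gross errors inflate the residual variance of the very fit that screens
them, which widens the interval; this is self-limiting in practice because a
±25% displacement is still ≈5 residual standard deviations out while clean
records stay well inside. The interval is the standard OLS prediction
interval on the log scale (t-quantile, leverage term included),
back-transformed implicitly by screening on log-residuals. The abscissa is
the **theoretical** adduct m/z computed from the neutral mass (reported m/z
as fallback) so that m/z faults cannot corrupt the trend. Strata smaller
than 10, or with degenerate m/z spread, are left unscreened: too little data
to estimate a 99% interval honestly.

**Consensus with DTIM priority.** Drift-tube values are traceable to first
principles, so when at least one DTIM record exists the unified value is the
unweighted mean of DTIM records only; otherwise the mean over all platforms.
Means are unweighted throughout — dataset size reflects publication habits,
not measurement quality.

**Confidence levels.** An ordered cascade: Level 1 (≥2 independent datasets
on DTIM, max difference ≤1%), else Level 2 (≥2 datasets on any commercial
instruments, ≤3%), else Conflict (≥2 datasets, >3%), else Level 3 (single
dataset). *Independent datasets* means distinct dataset identifiers
(publications), not distinct laboratories. The cascade is ordered, so ≥2
DTIM datasets with a difference between 1% and 3% fall to Level 2, not
Conflict. Level 4 marks predicted values and is never produced by the
experimental pipeline. Every input record ends up in exactly one consensus
source list or one removal-report row — an invariant the test suite checks
wholesale.

## 2. Descriptors and selection

Descriptors are computed from SMILES through the OpenBabel/ChemmineR
backend: bulk properties (logP, molar refractivity, TPSA, hydrogen-bond
counts), monoisotopic mass, per-element atom counts, ring and aromatic-ring
counts, functional-group counts and composition ratios — about 50 numeric
features, with the exact catalogue recorded in the matrix provenance. The
package deliberately does not promise a specific historical descriptor set;
descriptor catalogues are backend-specific, and the published
selected-descriptor names of any external study can be supplied to
`train_ccs_model(selection = ...)` to bypass selection.

Preprocessing drops non-differential (zero-variance) columns, imputes
missing cells by K-nearest-neighbour averaging (k = 5, Euclidean distance
over shared observed columns — k = 5 is the conventional default, and the
imputation RMSE on mask-and-recover experiments sits well below the column
standard deviation), and Z-scores every column. The training means and
standard deviations are stored in the model and re-applied verbatim to query
compounds.

`rfecv_select()` implements recursive feature elimination with
cross-validation under repeated subsampling: 50–90% of the rows (five
fractions × 200 repeats = 1000 replicates by default), and within each
replicate a LASSO is fitted, the descriptor with the smallest absolute
coefficient is removed, every set size is scored by 10-fold cross-validation
(score = median relative error of pre-validated predictions at the
CV-selected penalty), and one set is kept per replicate. Descriptors
appearing in more than 70% of replicates are selected.

Two decisions here were genuinely open. First, the CV scoring metric: we use
the median relative error because it is the same statistic the CCS field
reports for prediction accuracy, making selection and evaluation
commensurable. Second, which set a replicate keeps: we keep the **smallest
set whose score is within 25% (relative) of the best score** along the
elimination path. Without this parsimony rule, noise descriptors whose
removal changes the CV score within its own sampling fluctuation ride along
in well over half the replicates, and the 70% frequency threshold loses its
meaning; with it, planted-feature experiments (two informative descriptors
against eighteen pure-noise ones) recover exactly the planted pair at 100%
frequency with the best noise descriptor near 20%. A practical caveat
observed on the simulator: strongly collinear descriptors (several size
measures) split votes, so on mass-dominated targets no single descriptor may
clear the threshold — `rfecv_select()` then falls back to the top-frequency
descriptor rather than returning an empty model, and the frequency table
should be inspected. Elimination stops at two descriptors (the LASSO backend
requires at least two columns); size-one sets are never scored.

## 3. SVR prediction and its hyperparameters

One ε-SVR with an RBF kernel is trained per ionization polarity. The ion
species is encoded by appending the adduct mass shift (Da) and a one-hot
adduct indicator to the descriptor vector — a single per-polarity model over
all adducts, switchable in principle to per-adduct submodels. The backend is
libsvm (e1071) with internal x/y scaling, numerical tolerance 1e-3,
shrinking on, and the default ε = 0.1 recorded in the model metadata.

The canonical tuning contract is a grid of seven costs,
`{0.001, 0.005, 0.025, 0.05, 0.1, 0.25, 0.5}/N_MD`, crossed with fifteen
kernel widths `2^1 … 2^15` — 105 combinations scored by 10-fold
cross-validation with 100 repeats (mean over repeats of the held-out median
relative error; ties broken by smaller C then smaller γ; the full table is
returned for audit). Those *scales* are meaningful only relative to a
descriptor space: on this package's ~50-dimensional Z-scored catalogue the
small costs underfit severely and widths ≥2 localize the kernel beyond the
data density — every point of that grid sits near 10% hold-out MRE on
simulated data, while C ∈ [1, 100] with γ ∈ [2⁻⁸, 2⁻¹] reaches ≈1.4–1.8%.
The bundled studies therefore tune over the backend-matched grid (passed
explicitly through `model_config(C_grid=, gamma_grid=)`), and the canonical
grid remains the documented default contract. Anyone comparing against a
published configuration should treat (C, γ) as tied to that study's
descriptor set and re-tune.

Evaluation (`evaluate_predictions()`) reports the median (MRE) and mean
(ARE) relative error in percent, the squared Pearson correlation on raw CCS,
and the cumulative error curve in 0.5% steps (a valid CDF by construction).
Training MRE is computed in-sample on the final model.

## 4. RSS: structure similarity as a reliability estimate

The representative structure similarity of a query is the mean of its five
highest Tanimoto coefficients against the training-set fingerprints
(path-based OpenBabel FP2: linear fragments up to seven atoms hashed to 1024
bits; the scheme is configurable and recorded in every result, because
absolute RSS values shift by a few hundredths across fingerprint schemes).
Two conventions: a query identical to a training structure contributes
TC = 1 (no self-exclusion; an `exclude_self` flag exists for leave-one-out
experiments), and with fewer than five training structures the mean runs
over what exists. Two empty fingerprints are defined as identical (TC = 1).
Groups: small (RSS ≤ 0.6), medium (0.6 < RSS ≤ 0.8), large (RSS > 0.8), with
both boundaries resolving downward.

The leave-one-super-class-out harness (`leave_class_out()`) quantifies what
RSS is for: withholding a chemical super class from training degrades
held-out predictions of that class (simulator: median relative error ≈8–10%
excluded vs ≈2% included) and the per-compound RSS anticorrelates with the
prediction error (Spearman ρ ≈ −0.3 to −0.45 across seeds). One caution: a
fingerprint hashes connectivity, not size-independent shape — homologous
series (e.g. long-chain fatty acids) can share identical FP2 bitsets, so
RSS = 1 does not certify an identical structure.

## 5. Multi-dimensional annotation

Candidates are retrieved by m/z within 25 ppm, restricted to the
protonated/deprotonated species of the feature's polarity by default. The
CCS dimension first removes candidates whose relative CCS error exceeds the
outer tolerance, then scores survivors with the trapezoid (1 below 2%,
linear to 0 at 4%; a degenerate `tol_min = tol_max` configuration becomes a
step function, not a division error). MS/MS is scored with a reverse
dot-product: each reference peak is paired with the nearest experimental
peak within 25 ppm (absolute floor 0.002 Da for low-mass fragments),
experimental-only peaks are ignored, intensities are square-root transformed
and the squared weighted cosine is returned. Externally computed MS/MS
scores (from in-silico fragmentation tools) can replace the internal score;
they are min–max rescaled to [0, 1] within each feature's candidate set
before fusion. The integrated score is `0.3·S_ccs + 0.7·S_msms`; when a
dimension is unavailable (no spectrum, or no CCS and CCS filtering off), the
remaining dimension's weight renormalizes to 1 and the condition is
flagged. Ranking is dense on the integrated score, ties broken by smaller
|ppm error| then lexical id; per-feature candidate counts after each stage
are kept, which is where the candidate-reduction statistic comes from. When
several spectra arrive for one feature, the most intense one is used.

## 6. What the simulator emulates — and what it does not

`simulation_config()` defines the study conditions: 94 real small-molecule
structures in five structurally distinct super classes (amino acids,
carbohydrates, fatty acyls, nucleosides, benzenoids); ground-truth
CCS = a·(m/z)^b per class (a ∈ [8, 10.5], b ∈ [0.48, 0.52], spanning
≈80–210 Å² over the library's mass range) with 2% log-normal compound-level
jitter; four datasets (two DTIM, one TWIM, one TIMS) with 0.5% calibration
biases, 80% coverage, 0.3% replicate noise, 30% duplicate rate; 2% of
dataset-level measurements displaced by ±25%. Spectra are 5–20 uniform
random fragments; experimental copies lose each peak with probability 0.2,
blur intensities log-normally and gain Poisson contaminants. The annotation
benchmark plants mass decoys inside the ±15 ppm window with CCS scattered
±12% so that roughly two thirds fall outside the 4% tolerance. All draws
are reproducible from the config seed, and fault labels are retained so
tests can use them as oracles.

Real chemistry, synthetic truth: descriptors and fingerprints need valid
structures, but the tests need known answers — hence the hybrid. What the
simulator does **not** emulate: real CCS values (the power laws are
calibrated to realistic ranges, not to measurements), fragmentation
chemistry (fragments are uniform random masses), retention time structure,
correlated inter-laboratory biases, multiply charged ions, or conformer
multiplicity. Passing tests therefore demonstrate that the algorithms do
what they claim under controlled conditions — not that the trained simulator
models transfer to real spectra or real CCS databases.

Problem sizes used by the bundled studies (chosen to keep each experiment in
the seconds-to-a-couple-of-minutes range): curation on ~750 records;
selection at 120 × 20 with 100 replicates; SVR on 500 training / 100
hold-out instances over the nine positive adducts; leave-class-out on 285
validation predictions; annotation on 100 features × 8 decoys.

## 7. Known limitations

* Descriptor and fingerprint catalogues are backend-specific; absolute RSS
  values and selected-descriptor identities are not comparable across
  backends, only the procedures are.
* One CCS per ion: conformer distributions and protomers are out of scope.
* The per-polarity adduct encoding assumes adduct effects are separable from
  structure; strongly adduct-specific conformational changes violate that.
* The 0.5% replicate rule and the 99% interval are calibrated for the
  replicate precision of current commercial IM instruments; substantially
  noisier sources would need the thresholds revisited (all are arguments).
* `stats::spectrum` is masked when the package is attached; use
  `ccsatlas::spectrum()` explicitly in code that also does time-series work.
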