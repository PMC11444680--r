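---
title: "Discovering and validating lipid marker panels with lipidmoe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating lipid marker panels with lipidmoe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmoe)
```

## The analysis problem

Paclitaxel chemotherapy frequently causes peripheral neuropathy, and lipid
mediators — sphingolipids in particular — are plausible molecular correlates
of both drug exposure and the neuropathic outcome. The analysis this package
implements starts from a quantified plasma lipidomics table (samples in
rows, lipid mediators in columns) collected from breast-cancer patients
before (day 1) and after (day 2) paclitaxel therapy, with a post-therapy
neuropathy assessment per patient. Two binary questions drive everything:

* **timepoint** — can a blood sample be assigned to pre- vs post-therapy
  from its lipid profile alone?
* **neuropathy** — among post-therapy samples, can patients with and
  without neuropathy be told apart?

The goal is *knowledge discovery*, not classifier deployment: if any
classifier assigns classes better than guessing, the features it needs
carry information about the class structure. Feature selection therefore
takes precedence over raw classifier performance, and a sparse, validated
marker panel is the deliverable.

## Workflow overview

`run_pipeline()` chains the stages; each is exported on its own:

1. **Data** — `read_lipid_dataset()` or the synthetic generator
   `generate_lipidomics()`.
2. **Preprocessing** — `scan_tukey_ladder()`, `filter_missing()`,
   `rf_impute()`, `z_standardize()`.
3. **Unsupervised structure** — `pca_structure()` (Kaiser criterion +
   cABC variable contributions) and `train_esom()` / `umatrix()` /
   `extract_clusters()` with `cluster_class_association()`.
4. **Consensus feature selection** — `run_moe()`, a mixture of 13 selection
   experts inside repeated subject-grouped cross-validation, aggregated
   with `cabc_categorize()` and `nested_cabc()`.
5. **Validation** — `split_holdout()`, `tune_classifiers()`, `validate()`
   with real and permuted training labels, `external_apply()` for a second
   cohort.
6. **Classical statistics** — `kruskal_wallis()`, `adjust_p()`,
   `fisher_exact()`, `class_enrichment()`.

## The synthetic cohort generator

The patient data behind this design cannot be redistributed, so the package
ships a generator whose defaults emit the study's shape: 48 subjects, 31 of
them with a paired day-2 sample (79 samples total), 255 lipid mediators,
and 17 of the 31 paired subjects neuropathy-positive. A second-cohort
generator emits the external-validation shape (26 paired subjects on a
239-mediator panel) with a configurable attenuation of the effect sizes.

Log concentrations are modeled as

$$\log x_{ij} = b_j + \sqrt{\rho}\, W_{i, B(j)} + \sqrt{1-\rho}\, V_{ij}
  + \Delta_{ij},$$

where $b_j$ is a per-mediator baseline drawn uniformly from a log-abundance
range, $W$ a block-level latent field shared by all mediators of a lipid
class, $V$ a mediator-private field, and both fields split into a subject
random effect (shared between a subject's two samples — the pairing) and
sample-level noise. The class shift $\Delta$ adds
`effect_size * sigma` on the log scale to day-2 samples of the
time-informative mediators (and analogously for neuropathy), with
$\sigma = \sqrt{\sigma_{subject}^2 + \sigma_{noise}^2}$ the within-class SD,
so effect sizes are in Cohen's-$d$-like units. Missingness is injected
MCAR after exponentiation.

Defaults and why:

* `subject_sd = 0.3`, `noise_sd = 0.5` — a within-subject correlation of
  ~0.26 across timepoints, typical of repeated plasma lipid measurements;
  the paired design then genuinely stresses the subject-grouped splitting
  logic.
* `n_blocks = 10`, `block_rho = 0.4` — lipid classes co-regulate;
  0.4 is a realistic within-class correlation of log concentrations. The
  construction makes the within-block correlation equal `block_rho`
  exactly, which the tests verify empirically.
* the first block ("sphingolipid") holds ~18% of the mediators, matching
  the sphingolipid share of the emulated panel, and
  `enriched_class_fraction = 0.4` of the informative mediators are drawn
  from it, so the enrichment statistics have a known truth.
* `n_informative_time = 10` at `effect_size_time = 1.5`,
  `missing_rate = 0.05` — a minority of moderately shifted mediators under
  light missingness: strong enough that a sound pipeline must find them,
  weak enough that a leaky or broken one visibly fails.
* a declared list of `n_decoys` null mediators, disjoint from the truth,
  makes selector specificity measurable.

What the generator does **not** emulate: batch drift, detection-limit
censoring, non-MCAR missingness, heavy-tailed measurement error, and
between-class correlation structure beyond the block model. Passing tests
therefore demonstrate algorithmic correctness and honest information flow,
not robustness to instrument-level artifacts.

## Preprocessing choices

* **Transformation** — candidate powers $\{-2, -1, -\tfrac12, 0, \tfrac12,
  1, 2\}$ along the ladder of powers; per mediator and power, normality is
  assessed with the D'Agostino–Pearson omnibus statistic
  $K^2 = Z(\sqrt{b_1})^2 + Z(b_2)^2 \sim \chi^2_2$, implemented from the
  standard normalizing transforms (it is absent from the installed
  statistics stacks) and requiring $n \ge 20$, below which the kurtosis
  normalization is undefined. The chosen power maximizes the count of
  mediators with $p > 0.05$; ties go to the power closest to 1. On
  log-normal concentrations this selects the log, as intended.
* **Missingness** — mediators with more than 20% missing cells are dropped
  first, then samples are assessed on the retained mediators only; a
  boundary value of exactly 20% is retained (the conservative reading).
  Filtering features first avoids discarding patients because of a few
  globally bad analytes.
* **Imputation** — iterative random-forest imputation (100 trees per
  forest, median initialization, sweep order by increasing missingness,
  stop when the normalized change of imputed values falls below `1e-3` or
  after 10 sweeps), fully seed-controlled. The default pipeline imputes the
  full matrix once, before holdout segregation, mirroring a workflow in
  which imputation precedes data segregation; `rf_impute()` can equally be
  applied per partition for a fully split-aware variant.
* **Standardization** — per-mediator z-scores whose mean/SD are estimated
  on the fitting partition only; holdout and external cohorts are scaled
  with training statistics, so no holdout information reaches the selection
  or tuning stages.

## Computed ABC analysis

cABC analysis partitions a nonnegative importance vector into the
"important few" (A), a middle group (B) and the "trivial many" (C) from the
geometry of the empirical ABC curve (effort fraction $x_i = i/n$ vs
cumulative yield fraction $y_i$ after sorting descending):

* A|B boundary: the curve point closest to the ideal point $(0, 1)$;
* B|C boundary: the last point before the piecewise-linear curve's segment
  slope drops below 1 (break-even: one further item stops contributing
  more than its nominal share); if break-even precedes A|B, B is empty.

Ties are kept in original order, so equal values straddling a boundary are
split deterministically (with a warning). An all-equal vector carries no
concentration signal: every item goes to C and the result is flagged
degenerate. The nested variant re-applies the analysis to the previous
category A until a target depth is reached or A stops shrinking — the
mechanism that distills the consensus score into a sparse panel. Every
boundary is verified in the tests against exhaustive search over all curve
points.

## Unsupervised structure

**PCA** retains components with eigenvalue strictly above 1 (Kaiser
criterion) from the mediator correlation matrix and scores each mediator's
contribution as the sum over retained components of squared loading times
the component's explained-variance fraction; the cABC category A of that
score is both a structure readout and one of the 13 selection experts.

**ESOM/U-matrix**: a 50 x 80 toroidal grid (4000 neurons — far more
neurons than samples, so structure can emerge) trained online for 20
epochs, weights initialized by sampling data rows. Choices the method
leaves open, fixed here and exposed as arguments: Gaussian neighborhood
kernel on toroidal grid distance; learning rate and radius decaying
linearly from $(0.5, \max(\text{rows}, \text{cols})/2)$ to $(0.01, 1)$;
per-neuron U-height as the mean Euclidean distance to all 8 immediate
toroidal neighbors (the 8-neighborhood matches the visual U-matrix
convention). Cluster extraction reads the U-matrix as a watershed: the
height threshold starts just below the highest ridge and is lowered until
the below-threshold neurons split into the target number of BMU-bearing
connected components. Scanning from the top matters: the first split from
above separates the deepest valleys, whereas the lowest usable threshold
routinely shatters a single valley into fragments and misreads the map.
The components carrying the most samples become cluster cores and
remaining samples join the nearest core by toroidal distance. Cluster
versus prior-class association uses Fisher's exact test on the 2 x 2
table.

## The mixture-of-experts consensus selection

Thirteen selection experts vote inside a repeated stratified 5-fold x 20
cross-validation (100 training folds), with folds grouped by subject so a
patient's two samples never straddle a fold border:

* PCA variable importance (category A as above);
* Cohen's $|d|$ (category A of the effect sizes);
* univariate F-based selection at the false-positive rate ($p < \alpha$)
  and family-wise error rate ($p < \alpha/d$, Bonferroni);
* $k$-best by F statistic, SelectFromModel (importance at or above the mean
  importance), and recursive feature elimination, each instantiated for a
  linear SVM, a random forest, and penalized logistic regression.

$k$ is tuned per model over the grid $1..18$ by inner-CV balanced accuracy
of the paired model on the top-$k$ mediators. RFE refits the model and
drops the least important 10% of remaining mediators per step (floor one)
down to $k$; strict one-per-step elimination is available via
`rfe_step = 0` but multiplies the model-fit count roughly 25-fold for no
measurable change in the selected sets at this problem size. Selection-
stage model fits deliberately use light settings (100-tree forests; the
penalized regression reuses the tuned penalty type and strength): they
only need a stable importance ranking, not calibrated predictions.

Aggregation: per method, cABC over its selection counts across the 100
folds defines the method's vote (category A); the **sum score** of a
mediator is the number of methods voting for it (0–13); cABC category A of
the sum score is the **reduced** set and depth-2 nested cABC the
**sparse** set. A method whose fit fails in a fold simply contributes no
selections for that fold; failures are recorded in the tally.

## Validation and the permutation control

A subject-grouped, class-proportional 20% holdout is segregated before any
selection or tuning. Hyperparameters are tuned by 5-fold subject-grouped
grid search on the training partition (SVM: kernel linear/sigmoid x cost;
forest: 200/600/1200 trees x depth 5/10/unlimited; logistic regression:
LASSO/Ridge x penalty strength), scored by mean balanced accuracy.

`validate()` then runs 100 rounds: per round a class-proportional 80%
subject subset of the training partition is drawn and each tuned family is
fitted on the candidate feature set and evaluated on a random 80% sample
subset of the holdout, yielding balanced accuracy (mean of per-class
recalls) and ROC-AUC (Mann–Whitney formulation, ties counted one half;
scores are the SVM margin, forest vote fraction, and modeled probability
respectively). Reported are medians with nonparametric 95% CIs (raw
2.5th/97.5th percentiles of the run values); a family counts as separated
from chance when its CI excludes 0.5. The training-side subsets are
subject-grouped; the holdout subsets are sample-wise, since the holdout is
never used for fitting.

The overfitting control permutes the class labels of each round's training
subset before fitting. Label permutation (rather than permuting the
mediator values) breaks the feature–label link while preserving every
feature marginal and correlation, which is the sharper null for "did the
pipeline learn the labels". On informative synthetic data this collapses
the median balanced accuracy to chance while the unpermuted medians stay
well separated — the package's central honesty check.

One printed configuration of the emulated study cannot be honored
literally: a LASSO penalty and a sigmoid kernel cannot coexist in one SVM
(an L1 coefficient penalty is undefined for kernelized machines). The
resolution here: the linear SVM used *inside selection* honors the L1/L2
penalty choice through its importance vector, while the *validation* SVM
defaults to the sigmoid kernel.

For an external cohort, `fit_frozen()` trains one model per family on the
full training partition and `external_apply()` evaluates them — without any
refitting — on repeated 80% subsamples of the external data for CI
construction.

The neuropathy task in a cohort of this size is only weakly learnable; the
pipeline formalizes that judgement: when every family's balanced-accuracy
CI for a task contains 0.5, multivariate selector votes are deemed
uninterpretable and selection falls back to the univariate experts only
(Cohen's d, FPR, FWE). The fallback criterion is tested on null vs
informative synthetic data.

## Classical statistics

Kruskal–Wallis comparisons (tie-corrected H, $\chi^2_{g-1}$ reference) with
Benjamini–Hochberg adjustment by default (Bonferroni–Holm by flag) screen
the final panel mediators. Fisher's exact tests report the conditional
maximum-likelihood odds ratio with the exact conditional CI — the
convention whose output matches odds ratios printed alongside exact p
values in this literature — with the sample-OR alternative available
through the underlying machinery. `class_enrichment()` asks whether a
lipid class (sphingolipids, canonically) is over-represented in a selected
panel relative to the annotated universe.

## Seeds, problem sizes, and reproducibility

Every stochastic stage draws its seed deterministically from a master seed
and a stage label (`derive_seed()`), so a pipeline run is bit-reproducible
end to end and stages stay independent of each other's random-number
consumption. The test suite exercises most operations on compact cohorts
(20–48 subjects, 30–60 mediators) where oracles are enumerable, and runs
the full default 79 x 255 cohort through selection and validation once;
the end-to-end checks share that state. These sizes are the package's
choice of the smallest instances that still exhibit the study-scale
behavior of every stage.

The pipeline is an R-native API (`run_pipeline()` over a `pipeline_config`
serialized to YAML) rather than a shell tool: its users script analyses in
R, and `scripts/acceptance.R` shows the canonical non-interactive
invocation.

## Known limitations

* The ESOM cluster reading approximates a visual watershed interpretation;
  maps with more than two comparable valleys may need `n_clusters` raised
  and the result inspected via `autoplot()`.
* The CIs of the validation report describe run-to-run variability around
  one fixed holdout; with ~15 holdout samples the balanced-accuracy values
  are coarsely quantized, and medians can sit one lattice step from 0.5 on
  null data.
* The neuropathy task inherits the cohort's small day-2 sample; the
  univariate fallback is a structured judgement call, not a power gain.
* Imputation quality is only benchmarked under MCAR; informative
  missingness would require a different generator and likely a different
  imputation strategy.
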