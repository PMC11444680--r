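# lipidmoe

Mixture-of-experts discovery and validation of lipid marker panels.

`lipidmoe` implements the analysis pipeline used to screen plasma
lipidomics profiles of cancer patients sampled before and after paclitaxel
chemotherapy: does the lipidome carry the pre/post class structure, which
lipid mediators carry it, and does a sparse panel of them survive honest
validation? The same machinery addresses the clinically interesting
follow-up — separating patients with and without post-therapy neuropathy.
It is written for analysts of targeted lipidomics / metabolomics panels
(samples × mediators tables) who want consensus feature selection with
built-in overfitting control rather than a single model's ranking.

## The methods at the core

* **Computed ABC (cABC) analysis** — data-driven partition of a
  nonnegative importance vector into the "important few" (A), middle (B)
  and "trivial many" (C) from the ABC curve's geometry: A|B at the curve
  point closest to (0, 1), B|C at the break-even point where the curve's
  slope falls below 1. Nested cABC re-applies the analysis to category A,
  distilling a sparse core set.
* **ESOM / U-matrix** — an emergent self-organizing map (4000 neurons on a
  50 × 80 toroidal grid, 20 training epochs) whose U-matrix (per-neuron
  mean distance to its 8 toroidal neighbors) is read as a watershed
  landscape; cluster ↔ class association is tested with Fisher's exact
  test.
* **Mixture-of-experts selection** — 13 selection experts (PCA variable
  importance, Cohen's |d|, FPR and FWE F-tests, and k-best / 
  SelectFromModel / RFE for linear SVM, random forest and logistic
  regression) vote inside a subject-grouped stratified 5 × 20
  cross-validation; per-method cABC on selection counts, a cross-method
  sum score (0–13), cABC → *reduced* set, nested cABC → *sparse* set.
* **Permutation-controlled validation** — a subject-grouped 20% holdout is
  untouched by selection and tuning; 100 resampled rounds report median
  balanced accuracy and ROC-AUC with nonparametric 95% CIs, side by side
  with the same procedure on label-permuted training data, which must
  collapse to the 0.5 chance level.
* **Synthetic cohort generator** — log-normal concentrations with lipid-
  class correlation blocks, subject random effects (pairing), known
  informative mediators and declared decoys; defaults emit the emulated
  study's 79 × 255 shape (48 day-1 / 31 day-2 samples, 17/31
  neuropathy-positive) and a 52 × 239 external cohort.

## Worked example

```r
library(lipidmoe)

sim <- generate_lipidomics()   # default synthetic cohort
sim$dataset
#> <lipid_dataset> 79 samples x 255 lipid mediators
#>   timepoints: day1=48, day2=31
#>   neuropathy: no=14, unknown=48, yes=17
#>   missing: 5.1%  log: FALSE  standardized: FALSE
```

79 samples over 255 mediators: every subject contributes a day-1 sample,
31 also a paired day-2 sample, and neuropathy status exists only where it
is observable — on day-2 samples.

Suppose 13 selection methods have voted on ten mediators. Nested cABC
distills the sum score into the panel core:

```r
votes <- c(SA1P = 13, SM_33_1 = 12, SM_43_1 = 11, LPC_18_1 = 9, S1P = 8,
           LPE_18_2 = 5, PC_34_2 = 3, FFA_16_0 = 2, TG_52_2 = 1, CE_18_1 = 1)
res <- nested_cabc(votes, depth = 2)
res
#> <cabc_result> 10 items: A=2, B=1, C=7
tidy(res)
#> # A tibble: 10 × 5
#>    item     value category     x     y
#>  1 SA1P        13 A          0.1 0.2
#>  2 SM_33_1     12 A          0.2 0.385
#>  3 SM_43_1     11 C          0.3 0.554
#>  4 LPC_18_1     9 C          0.4 0.692
#>  5 S1P          8 B          0.5 0.815
#>  ...
```

The first cABC pass keeps the top five mediators; re-applying it to those
five leaves `SA1P` and `SM_33_1` as the sparse core (items removed in the
second pass keep their second-pass category — hence `S1P` as B). The full
pipeline does exactly this to the 0–13 sum score of the 13 experts over
100 cross-validation folds; `run_pipeline(pipeline_config())` chains
simulation, preprocessing, structure scan, selection and validation, and
`autoplot()` methods draw the ABC curve, the U-matrix and the validation
intervals.

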