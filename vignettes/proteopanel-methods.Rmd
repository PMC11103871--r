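---
title: "proteopanel: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proteopanel: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteopanel)
```

# Scope

`proteopanel` analyses a two-group, two-cohort label-free proteomics study:
a discovery cohort quantified by a wide-coverage method (DIA-style) and a
small independent validation cohort quantified by a targeted method
(PRM-style). This vignette explains each model in the chain, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the choices made where the design was genuinely open. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

# Preprocessing

The working unit is the `QuantMatrix`: proteins × samples, log2 scale,
`NA` for unquantified cells. Raw-scale input is log2-transformed exactly
once at ingestion (zeros and negative intensities become `NA`); whether a
file is raw or log2 is declared by the caller, never guessed from
magnitudes, because plausible log2 intensities (say 2–30) overlap plausible
raw ranges.

Three steps run in a fixed order:

1. **Missing-ratio filter.** A protein is kept iff its missing fraction is
   ≤ `max_missing_ratio` (default 0.5) within *each* group. The boundary
   case (exactly 0.5) is kept: with the strict-drop reading the rule is
   monotone in the number of observed samples, so adding an observation can
   never flip a kept protein to dropped. The complementary reading is
   available via `strict = FALSE`.
2. **Median normalization.** Each sample's observed values are shifted
   additively so every per-sample median equals the grand median. On log2
   data this is a per-sample scale factor on the raw scale — the standard
   correction for loading/injection differences. It is idempotent.
3. **k-NN imputation** (default k = 5). Neighbours are *proteins* (rows),
   not samples: at cohort sizes of 10–26 samples, row-space neighbourhoods
   are far better populated than column-space ones, and protein-neighbour
   imputation is the convention for expression matrices. The distance
   between two proteins is the root-mean-square difference over their
   jointly observed samples — dividing the Euclidean distance by the square
   root of the shared-sample count makes neighbour pairs with different
   overlap comparable. Ties break by (distance, row order) for determinism.
   The imputed value is the unweighted mean of the k neighbours observed at
   that sample.

Normalization precedes imputation so imputed values inherit corrected
sample medians; the reverse order would let imputed values drag the
post-hoc medians. Neither order is forced by the mathematics — this is a
design choice, exposed by running the steps individually.

# Differential expression

Per protein: `log2FC = mean(case) − mean(control)` (difference of means of
log2 values, consistent with the matrix being log2 throughout — not the
log2 of a ratio of raw means), and a two-sided **pooled-variance**
Student's t-test. The pooled-variance form is chosen over Welch because it
is what the name "Student's t-test" denotes; Welch is available via
`var_equal = FALSE`. If both groups are constant, p is 1 (equal means) or 0
(unequal) by convention.

Multiple testing uses **Benjamini–Hochberg** by default — the near-universal
default of proteomics differential-expression platforms — with Bonferroni
and BY as alternatives. A protein is a DEP iff `p_adj < alpha` (0.05) and
`|log2FC| > fc_cut` (0.58 ≈ 1.5-fold), both strict, matching the usual
reporting convention that a value exactly at the cut is not called.

# Over-representation

One-sided Fisher's exact test, i.e. the hypergeometric upper tail
`P(X ≥ k)` — over-representation only, since depletion of a gene set among
DEPs is rarely a reportable finding in this setting. The background is the
set of proteins quantified *after* filtering, not the annotation universe:
proteins that could never have been called DEP (because they were not
quantified) must not inflate the expected overlap. Set members outside the
background are discarded before testing; the q-value column equals the
BH-adjusted p (the convention of the standard ORA tooling; a Storey
estimator is out of scope).

A note on calibration: the one-sided hypergeometric p is discrete, so under
the null it is exactly calibrated only at its support points
(`P(p ≤ p_k) = p_k`) and is conservative in between. The test suite
therefore checks null uniformity on the randomized probability integral
transform `u = P(X > k) + U·P(X = k)`, which is exactly Uniform(0,1) iff
the reported p follows the claimed law.

# Network hubs

The PPI graph takes a STRING-style edge list (0–999 scores are rescaled to
0–1 by 1000 when any value exceeds 1), restricted to the DEPs, keeping
edges with combined score strictly > 0.15 and retaining isolated nodes so
the connected fraction can be reported. Centralities are computed on the
unweighted topology — scores only threshold the graph, matching the
behaviour of the usual hub-ranking plugins:

* **degree**; **betweenness** — exact, unnormalized, endpoints excluded,
  each unordered pair once (the raw-count convention; published hub tables
  show values far above 1, which rules out the normalized variant);
* **MNC** — the size of the largest connected component of the open
  neighbourhood;
* **EPC** — Monte-Carlo percolation: each replicate keeps every edge
  independently with probability `keep_prob` (default 0.5) and a node
  scores the number of other nodes left in its component; the mean over
  `replicates` (default 1000) is reported. The percolation law behind the
  published EPC score is under-documented, so this fixed-keep-probability
  Monte-Carlo is adopted with seed, replicates and keep probability in the
  interface — reproducibility is preferred over fidelity to an unpublished
  detail. The limits are exact: `keep_prob = 1` gives component size − 1,
  `keep_prob = 0` gives 0.
* **MCODE** — three stages: (1) each node of degree ≥ `degree_cutoff` (2)
  is weighted by `k × density` of the highest k-core of its closed
  neighbourhood; (2) complexes grow breadth-first from the
  highest-weighted unassigned seed, admitting unassigned neighbours with
  weight ≥ `w(seed)·(1 − node_score_cutoff)` (0.2), depth ≤ `max_depth`
  (100), each node in at most one complex; (3) complexes without a
  `k_core`-core (2) are discarded, a complex scores density × node count,
  and only scores strictly > 5 are reported. Fluff and haircut
  post-processing are off. The per-node MCODE column reports the score of
  the node's containing complex (0 if none) — consistent with published
  hub tables in which co-members of one complex share a value.

Hubs are the four-way intersection of the top-10 lists by degree, EPC,
betweenness and MNC. Ranking uses strict top-n with deterministic
tie-breaks (score descending, then node id ascending) rather than
including rank-boundary ties: determinism is worth more to a pipeline than
tie generosity, and the choice is switchable by passing a different
`top_n`.

# The panel search

* **MDS (pool).** All DEPs fully quantified post-imputation, in matrix
  order. The source pipeline defines this step only by name; the DEP-pool
  reading is a design decision of this package.
* **CCG (candidates).** `n_candidates` random draws (default 26,000;
  2,600 in the test profile) of `combo_size` (5) distinct proteins;
  duplicate panels across draws are intentionally permitted — the search
  is a random walk over a space of ~4·10⁹ 5-subsets, and the duplicate
  rate is itself a diagnostic of pool size.
* **FCP (scoring).** Stratified 5-fold cross-validation (equivalently the
  4:1 train:test ratio); stratification guarantees both classes in every
  training fold at n = 26, which fully random splitting does not. Features
  are z-scored with training-fold statistics only. The learner is a
  two-stage penalized logistic regression: an L1 fit whose zero-weight
  proteins are deleted, then an L2 refit on the survivors. A literal L1/L2
  alternation would need a stopping rule that is nowhere specified; the
  select-then-refit scheme is the standard realization of that intent.
  Penalty strengths are sklearn-style inverse regularization
  (`C`, default 1.0; the glmnet lambda is `1/(nC)`).
* **Totals.** Total AUC and total RMSE are computed on the pooled
  out-of-fold scores — one number per candidate. This is the only reading
  under which "reserve every candidate with total AUC = 1" is well defined.
  A published RMSE range reaching above 1 for probabilistic scores implies
  some other scale (plausibly summed over folds) that cannot be
  reconstructed; the pooled RMSE, which lives in [0,1] here, is the sole
  implementation, and per-fold confusion counts (TN/TP/FP/FN, Sn, Sp at
  threshold 0.5) are recorded alongside.
* **Prioritization.** Reserve AUC = 1 (within 1e-12), sort by RMSE
  ascending (ties by candidate order), take the top 25, deduplicate by
  surviving-protein set.

The AUC itself is the rank-based (Mann–Whitney) estimator — identical to
the trapezoidal area under the (1−Sp, Sn) step curve and invariant under
monotone transforms of scores, which the property tests assert.

# Validation and clinical correlation

A shortlisted panel is refit on the full discovery cohort (refitting is the
default; reusing the stored cross-validation weights is available) and
scored on the validation cohort. Validation features are z-scored **within
the validation cohort**: discovery and validation intensities come from
different acquisition methods, so only within-cohort standardized values
are comparable. A consequence, asserted as a property test, is that the
validation AUC is invariant to per-protein affine rescaling of the
validation matrix — exactly the robustness a platform change demands.

Cross-platform consistency of a protein is pure sign agreement of the two
log2FCs (zero has no sign). Significance is carried through for reporting
only: a 12-sample targeted cohort rarely reaches adjusted significance, and
published consistency tables mark proteins consistent on sign despite
non-significant validation p-values.

Spearman correlation is tie-corrected (rank transform, then Pearson) with
the two-sided t-approximation on n − 2 degrees of freedom. Correlation with
diabetes duration uses case samples only — controls have no diabetes
history, so the covariate does not exist for them — while visual-acuity
correlations may use all samples.

# The synthetic-data generator

`sim_config()` defaults encode the study design the pipeline targets:

| parameter | default | meaning |
|---|---|---|
| `n_case` / `n_control` | 16 / 10 | discovery cohort |
| `n_case_val` / `n_control_val` | 8 / 4 | validation cohort |
| `n_proteins` | 874 | quantified proteins |
| `n_dep`, `effect_log2fc`, `frac_up` | 217, 1.0, 128/217 | planted effects |
| `protein_mean_range` | (16, 26) | log2 baseline means |
| `protein_sd_range` | (0.25, 0.6) | log2 within-group sd |
| `mnar_intercept`, `mnar_slope` | 14.4, 0.8 | censoring law |
| `mcar_rate` | 0.02 | random missingness |
| `val_shift_sd` | 1.0 | per-protein platform shift |

Baselines are Normal(mu_p, sd_p) on the log2 scale (log-normal
intensities); the mean and sd ranges are conventional for DIA log2
intensities, and the implied standardized effect (1.0 / ~0.4) gives a
two-group design at 16 vs 10 realistic power rather than a foregone
conclusion. Cells are censored with probability
`plogis(mnar_intercept − mnar_slope·x)` — low-abundance cells vanish much
more often (missing-not-at-random), which the suite asserts via the mean
true intensity of missing vs observed cells — plus a small
missing-completely-at-random component. These defaults yield roughly a
quarter of cells missing and roughly a quarter of proteins failing the 0.5
per-group filter, emulating the attrition from 874 quantified to ~75% of
proteins analyzable. The intercept 14.4 places 50% censoring at a log2
intensity of 18 (the lower quarter of the abundance range).

Planted effects (identity, sign, size) are drawn in a substream shared by
both cohorts; the validation cohort draws fresh baselines plus a
per-protein Normal(0, `val_shift_sd`) offset, emulating the platform
change as a per-protein affine shift. An optional *panel* of `n_panel`
markers sits at the top of the abundance range (mean 25, sd 0.25, effect
3.0): abundant (hence essentially never censored) and fully separating, the
regime in which a "total AUC = 1" reservation rule is meaningful.

Clinical covariates are attached to case samples by a Gaussian copula: the
protein's case values are rank-transformed to normal scores, a companion
normal with latent correlation `2·sin(π·rho/6)` (the Spearman-to-Pearson
map for bivariate normals) is drawn, and mapped to the covariate scale
(logMAR acuity around 1.6 ± 1.0 clamped at 0; diabetes duration around
14.8 ± 6.0 years clamped at 0, matching the case-group descriptives of the
motivating design). Controls get near-normal acuity and no diabetes
duration, so the duration covariate exists only where it clinically can.

PPI simulation plants `n_modules` disjoint cliques over planted DEP nodes
with high within-module scores, over an Erdős–Rényi background; gene-set
simulation plants one set drawing a configured fraction of its members
from the planted DEPs. The ground-truth ledger (planted ids, signed
effects, module memberships, panel, realized couplings) is what the
recovery tests and the acceptance script compare against.

**What the generator does not emulate:** peptide-level structure and
roll-up, batch effects and run-order drift, correlated protein modules in
the *quantitative* data (network modules are planted in the interaction
graph, not in the covariance), heavy-tailed or multimodal intensity
distributions, and shared missingness across co-eluting peptides. Passing
the recovery benchmarks therefore demonstrates that the pipeline's logic
recovers what it assumes — not that those assumptions hold in any
particular real dataset.

# Numerical and testing choices

* All randomness descends from one master seed through fixed named
  substreams; reruns are byte-identical and the run manifest records the
  seed and per-stage counts.
* Degenerate inputs are defined, not accidental: empty AUC-1 reserve is a
  warned empty result; a constant covariate flags the correlation row; an
  all-deleted L1 stage returns a flagged intercept-only model; a protein
  absent from the validation matrix is a named error.
* Test and acceptance problem sizes are the package's benchmark profile:
  2,600 candidates and 200 EPC replicates in the `test` profile (the
  `full` profile restores 26,000 and 1,000), 10 seeds for the recovery
  benchmarks, exhaustive centrality oracles on all 4-node graphs plus 350
  random graphs up to 15 nodes. At these sizes the whole benchmark suite
  completes in minutes on one CPU while leaving the Monte-Carlo assertions
  (tolerances 0.02–0.25, stated per test) comfortably away from their
  thresholds.

# Known limitations

* The pooled-variance t-test after k-NN imputation treats imputed values
  as observations; with heavy missingness this is anti-conservative. The
  global-null calibration test bounds the effect at the default design but
  not beyond it.
* MCODE here reproduces the published algorithm from its description;
  implementations differ in undocumented corner cases (tie handling among
  equal-weight seeds, depth accounting), so complex boundaries on
  adversarial graphs may differ from any particular GUI implementation.
* The EPC percolation law is a documented stand-in (see above).
* Absolute centrality values and enrichment counts depend on the supplied
  interaction network and annotation collections; only their recovery
  behaviour on planted structure is benchmarked.
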