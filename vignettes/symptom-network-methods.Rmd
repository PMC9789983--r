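---
title: "Modelling co-occurring symptoms with discrete Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling co-occurring symptoms with discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomBN)
```

## The problem

Patients with advanced, life-limiting illness typically carry several
symptoms at once, but consultations surface only the ones the patient
volunteers. A probabilistic model of symptom co-occurrence lets a clinician
ask: *given what I already know this patient has (and does not have), which
other symptoms are likely enough to be worth assessing?*

`symptomBN` implements this idea for the eleven symptoms of the Utrecht
Symptom Diary (USD, the Dutch adaptation of the Edmonton Symptom Assessment
System): pain, sleeping problems, dry mouth, dysphagia, lack of appetite,
constipation, nausea, shortness of breath, fatigue, anxiety and depressed
mood, each self-rated 0–10 on a numeric rating scale (NRS). Scores are
dichotomized at the conventional clinically relevant cut-off (≥ 4), and a
discrete Bayesian network is learned over the eleven binary presence
indicators.

## The model

A Bayesian network factorizes the joint distribution of the binary symptom
vector $X = (X_1, \dots, X_{11})$ along a directed acyclic graph $G$:

$$P(X) = \prod_{v} P\!\left(X_v \mid X_{pa(v)}\right),$$

where $pa(v)$ are the parents of node $v$ in $G$. Each conditional is a
conditional probability table (CPT); because all variables are binary, we
store only $P(X_v = 1 \mid pa)$ per parent configuration — $2^{|pa(v)|}$
numbers per node — and derive the complement. CPT rows are ordered with the
first parent as the most significant position and presence before absence
(`++`, `+-`, `-+`, `--`), matching the conventional tabular presentation of
such models.

All node ordering and tie-breaking in the package refers to one canonical
order — the USD listing order above — so every algorithm is bit-reproducible
across runs.

### Structure learning

The DAG is learned from data. The package implements nine automated
learners spanning the three standard families:

* **Score-based**: greedy hill climbing, hill climbing with random
  restarts, and tabu search, all over single-edge additions, deletions and
  reversals. Tabu search keeps the last `tabu_len` (default 10) visited
  structures forbidden and accepts the best non-tabu move even when it
  worsens the score, returning the best structure encountered.
* **Constraint-based**: PC-stable (order-independent level-wise pruning),
  grow-shrink, IAMB and interleaved IAMB (Markov-blanket discovery with
  AND-rule symmetry correction). All use the $G^2$ conditional-independence
  test at `alpha = 0.05` by default — a conventional level; the choice
  matters mainly through skeleton sparsity. Partially directed outputs are
  completed to a DAG: v-structures from separating sets, Meek-rule
  propagation, then a deterministic consistent extension (Dor–Tarsi with a
  canonical-order fallback), because downstream stages need a DAG, not an
  equivalence class.
* **Hybrid**: MMHC-style search — the PC-stable skeleton restricts which
  edges score-based search may consider — with either hill climbing or
  tabu search inside the restriction.

### Network scoring

Structures are compared with the decomposable AIC in the
*higher-is-better* convention:

$$\mathrm{AIC}(G) = \sum_v \log \hat L_v - \sum_v 2^{|pa(v)|},$$

the maximized log-likelihood minus one penalty unit per free CPT entry.
The textbook $-2\log L + 2p$ form is $-2\times$ this quantity; we keep the
sign convention in which the *highest* AIC marks the lowest estimated
prediction error, because that is how the score is used for selection here.
BIC (penalty multiplier $\log(n)/2$) and the raw log-likelihood are
available through the same `score_spec()` interface.

A consequence worth knowing: AIC's fixed penalty makes it an inconsistent
selector. When data are sampled from a known network, tabu search with AIC
reliably recovers *all* true adjacencies at large $n$ but also admits a few
spurious edges, whose deviance gain exceeds the fixed penalty with
non-vanishing probability; BIC's growing penalty prunes these but can drop
the weakest true strata at moderate $n$. The recovery tests therefore
assert containment of the true skeleton for AIC rather than exact equality.

### Parameter learning and inference

CPTs are estimated on a fixed structure by
$(n(x_v{=}1, pa) + \alpha)/(n(pa) + 2\alpha)$. Two defaults coexist,
deliberately:

* `smoothing_alpha = 0` (maximum likelihood) for descriptive reporting, so
  the table reproduces empirical conditional frequencies exactly; an
  unobserved parent configuration gets the uninformative value 0.5 and is
  flagged.
* `smoothing_alpha = 1` (Laplace) inside cross-validated evaluation, so
  held-out rows with parent configurations unseen in training receive
  finite, non-degenerate predictions.

Queries $P(\text{target} = 1 \mid \text{evidence})$ are computed exactly by
variable elimination, eliminating non-evidence, non-target variables in
reverse topological order. With 11 binary nodes any elimination order is
fast; a fixed order makes results reproducible. Every query is
cross-checked in the test suite against brute-force enumeration of the
$2^{11} = 2048$-row joint table, at $10^{-9}$.

Per-patient prediction (`predict_from_others()`) conditions each symptom on
the observed values of the other ten, which collapses to a ratio over the
target's Markov-blanket factors and is vectorized over rows. If the
evidence within the blanket is impossible under an unsmoothed model, the
prediction falls back to the target's marginal with a warning instead of
aborting an evaluation fold; impossible evidence outside the blanket cannot
affect the ratio and is ignored.

## Evaluation machinery

* **Fourfold cross-validation** (`kfold_split`): seeded shuffle, contiguous
  split, fold sizes within one row of each other, unstratified.
* **Algorithm selection** (`cv_algorithm_selection`): per fold, learn on
  the training portion and score; rank algorithms by mean AIC over folds.
  Whether the per-fold AIC should be computed on training data or as
  held-out log-likelihood is genuinely ambiguous in this design; the
  training-data variant is the default and the held-out log-likelihood is
  always reported alongside, so both readings are available.
* **Per-symptom AUC** (`symptom_auc_cv`): rank-based (Mann–Whitney) AUC of
  the held-out predictions, per fold; mean and SD over folds; a mean of
  ≥ 0.65 is flagged satisfactory — a deliberately modest bar, appropriate
  when the cost of a wrong symptom prompt is a brief unnecessary question.
* **Decile calibration** (`calibration`): held-out predictions pooled over
  the four folds; per symptom, rows sorted by predicted probability
  (stable, row-index tie-break) and cut into ten near-equal-count bins;
  a bin is accurate when |mean predicted − observed frequency| ≤ 0.10.
  The 10-point rule is *absolute* probability difference, consistent with
  plotting both on the same axis. With 11 symptoms this yields 110
  comparisons. Constant predictions keep ten bins by stable row order
  rather than collapsing, so the 110-cell bookkeeping never changes shape.
* **Bootstrap edge directions** (`bootstrap_edge_directions`): rows
  resampled with replacement, structure relearned per replicate, per-edge
  direction fractions tallied; a direction reaching the majority threshold
  (default 0.51) resolves the edge. Production analyses use on the order of
  10,000 replicates; the tests use tens to hundreds, which suffices for
  the identifiable (v-structure) cases they check.
* **Operating thresholds** (`operating_thresholds`): from the empirical
  ROC, the lowest cut-off with specificity ≥ the requested floor (for
  time-limited assessment: few false prompts) and the highest cut-off with
  sensitivity ≥ its floor (when time allows: few missed symptoms).

## The synthetic-data generator

The original survey data are not publicly deposited, so the package ships a
generator whose defaults emulate the published study conditions end to end:

1. `reference_network()` — the 11-node network with structure and CPTs
   transcribed from the published conditional-probability table of the
   532-patient advanced-cancer survey model (fatigue the single root with
   seven children; 19 edges; e.g. $P(\text{anxiety} \mid \text{fatigue}+)
   = 0.331$). One transcription note: the source's running text gives
   79.8% for depressed mood given anxiety and dry mouth both present while
   its table prints 78.9%; the tabulated value is used, and the
   discrepancy is surfaced in the function's documentation rather than
   silently resolved. Exact inference on this network reproduces the
   cohort's published prevalences to within 2 percentage points — a
   consistency check between the published structure, its CPTs and its
   marginals that the test suite performs by enumeration.
2. `sample_binary()` — ancestral sampling in topological order.
3. `expand_to_nrs()` — present cells get a uniform integer score in 4–10,
   absent cells in 0–3. The two ranges sit on opposite sides of the
   cut-off, so dichotomization inverts the expansion *exactly*; raw-score
   distributions were never published, and this choice makes the
   imputation and dichotomization stages testable deterministically.
4. `inject_missing()` — 26 of 532 rows receive 1–3 missing cells, 36 cells
   in total (default composition 18×1 + 6×2 + 2×3), rows and columns
   chosen uniformly: missingness completely at random, since only counts,
   not a mechanism, were reported.

What the generator does *not* emulate: raw NRS score shapes within the
present/absent bands, demographic covariates, informative missingness, and
any violation of the fitted factorization itself (real symptom data need
not be faithful to a sparse DAG). Passing recovery tests on this generator
therefore demonstrates correctness of the algorithms under the model's own
assumptions — not clinical validity on new survey data.

## Imputation details

The data-preparation stage mirrors standard practice for short
patient-reported instruments: k-nearest-neighbour imputation (k = 5) on the
raw 0–10 scores, *then* dichotomization. The imputation reference leaves
the metric unspecified, so the package fixes and documents one convention:
distance between two rows is the root-mean-square difference over the
columns both observe (normalizing for how many columns are shared), rows
sharing no column are infinitely far, neighbour ties break by row index,
and the imputed value is the neighbours' mean rounded half away from zero
and clamped to 0–10. Observed cells are never altered; imputed cells never
feed other imputations.

## Numerical and design choices

* Probabilities are stored as proportions; percentages (one decimal, half
  away from zero) appear only in the reporting layer (`cpt_report`,
  `flowchart`), matching the presentation convention of the tables this
  format follows.
* Score ties during search break by canonical edge order; search starts
  from the empty graph; seeds influence only restarts and resampling.
* The flow-chart's default start node is the one with the most children —
  fatigue in the reference network, which is also among the symptoms
  patients most often volunteer spontaneously, making it a natural system
  input.
* Problem sizes in the test suite were chosen as the smallest that make
  the statistical assertions sharp: $n = 100{,}000$ for sampling-frequency
  checks (binomial SE ≈ 0.0015), $n = 500{,}000$ for CPT recovery to
  within a few tenths of a percentage point, $n = 50{,}000$ across ten
  seeds for skeleton recovery, and $2048$-state enumeration as the exact
  oracle behind 1,000 randomized query checks.
* CPT recovery at $n = 500{,}000$ is asserted entry-wise at four binomial
  standard errors of the generating value: the rarest parent stratum
  (dysphagia's dry-mouth-absent/nausea-present configuration) has SE near
  0.004, so a fixed blanket tolerance would be either slack for common
  strata or statistically unsound for rare ones.

## Known limitations

* Binary variables only; severity categories (mild/moderate/severe) and
  continuous or hybrid networks are out of scope.
* No prior-knowledge constraints (whitelists/blacklists) during search.
* Single imputation: no propagation of imputation uncertainty.
* Equivalence-class limits of observational structure learning apply:
  edge directions outside v-structures are not identifiable from data, and
  the bootstrap direction vote quantifies, not escapes, that limit.
* The published AUC range for the original survey (0.60–0.78) is shipped
  as a reference table for comparison; it cannot be recomputed here
  because the underlying patient data are not available.

## A worked example

```{r example, eval = FALSE}
net <- reference_network()
flowchart(net)              # fatigue as input: 7 children, both branches
query(net, "lack_of_appetite", c(fatigue = 1, dysphagia = 1))  # 0.800

sim <- simulate_survey(seed = 1)           # 532 x 11 scores, 36 NA cells
binary <- dichotomize(knn_impute(sim$scores, k = 5))
ranking <- cv_algorithm_selection(binary, algorithm_menu(), k = 4, seed = 1)
winner <- algorithm_menu()[[ranking$algorithm[1]]]
auc <- symptom_auc_cv(binary, winner, k = 4, seed = 1)
calib <- calibration(binary, winner, k = 4, seed = 1)
```

`run_pipeline()` wires these stages together and writes the full artifact
bundle (network JSON/DOT, AIC ranking, AUC table, calibration table and
plots, CPT report, flow-chart) with every output stamped by configuration
hash and seed.
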