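---
title: "Modeling patient subgroups in bipartite comorbidity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling patient subgroups in bipartite comorbidity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subgroupnet)
```

## The problem

Older adults hospitalized for conditions such as COPD, congestive heart
failure, or hip/knee arthroplasty are frequently readmitted within 30 days
of discharge, and most carry several comorbidities at once. Readmission
risk models built from comorbidity main effects treat the cohort as
homogeneous. `subgroupnet` implements a three-step alternative: discover
*biclusters* — patient subgroups together with their frequently
co-occurring comorbidities — in a bipartite patient–comorbidity network;
train a classifier that can place any patient (case or control) into a
discovered subgroup; and test whether subgroup membership adds predictive
value over a standard logistic readmission model.

Because claims data of this kind are access-restricted, the package ships
a synthetic cohort generator that plants the structure the method is
designed to find, so every stage is testable end to end.

## The bipartite model and Barber modularity

Cases are arranged in a bipartite graph: patient nodes on one side,
comorbidity nodes on the other, an edge wherever a patient carries a
comorbidity. A *partition* assigns every node (both families) a shared
cluster label; the quality of a biclustering is its bipartite (Barber)
modularity

$$Q = \frac{1}{m}\sum_{i,j}\left(A_{ij} - \frac{k_i d_j}{m}\right)
      \delta(g_i, g_j),$$

where $A$ is the $n \times d$ incidence matrix, $k_i$ and $d_j$ the
patient and comorbidity degrees, and $m$ the edge count. $Q$ is the
fraction of edges inside biclusters minus its expectation under a
degree-preserving random bipartite graph; the single-cluster partition
always scores 0 and $K$ equal perfect biclusters score $1 - 1/K$.

`maximize_modularity()` optimizes $Q$ with a BRIM-style alternating
scheme: holding comorbidity labels fixed, each patient takes the label
maximizing its modularity contribution; then the roles swap; the sweep
repeats to a fixed point, along which $Q$ is non-decreasing. The number
of clusters is emergent — it is never supplied by the user, which is the
point of modularity-based biclustering over k-means-style methods. Because
the fixed point depends on the start, the search is repeated from an
agglomerative warm start (average-linkage clustering of the Jaccard
distances between comorbidity columns, cut at depths 2–8), an
all-singleton labeling, and a configurable number of seeded random
labelings whose initial cluster counts cycle over 2..`k_max`. Connected
components are optimized independently. Exact ties in the per-node argmax
go to the lowest label, so the whole procedure is deterministic given the
seed and restart budget.

## Significance and replication

No closed-form variance estimator exists for modularity, so significance
is assessed by permutation. Each permutation rewires the graph with
degree-preserving double-edge swaps (at least $10m$ accepted swaps; a
cruder row-wise shuffle that preserves only patient degrees is available
as a switch), and the optimizer is re-run on the rewired graph with a
reduced restart budget, so the null distribution reflects the same search
procedure that produced the observed $Q$. Degree preservation matters:
with heterogeneous degrees a fully shuffled null understates the null
modularity and inflates z scores. The empirical P value uses the
$(1 + \#\{Q_{null} \ge Q_{obs}\})/(n_{perm} + 1)$ estimator, which cannot
return zero; a normal-approximation P accompanies the z score.

Replication follows the split-half design: cases are split 50/50 (the odd
patient goes to the training half), both halves are biclustered
independently, and agreement is measured with the Rand index *on the
comorbidity nodes only* — the halves share comorbidities but not
patients. The null permutes the replication half's comorbidity labels.

## Feature selection

Before any graph is built, comorbidities are screened on 1:1
demographically matched case–control sets (exact strata on age band, sex,
race and Medicaid eligibility; controls drawn at random without
replacement within a stratum; cases that cannot be matched are reported,
never silently dropped). Screening applies, in order: a prevalence filter
(< 1% of the combined matched set drops the variable; an exact tie at the
threshold is retained), univariable odds ratios from the 2×2 table with
Wald intervals (equivalent to univariable logistic regression for a
binary exposure; the Haldane–Anscombe +0.5 correction handles zero cells
and flags the estimate), and a Bonferroni rule: significance below
`alpha / d_tested` **in both halves**, where `d_tested` counts the
comorbidities that passed the prevalence filter (filtering precedes
testing). The univariable tests are unconditional — they ignore the
matched-pair structure — because the screening statistic juxtaposed on
the network is the plain univariable odds ratio. Patients left with none
of the surviving comorbidities carry no edges and are removed, with the
count logged.

## Classification and subgroup risk

A multinomial logistic model maps the selected comorbidities to the
discovered subgroup labels. Planted or strongly separated data make the
unpenalized maximum likelihood diverge, so the fit carries a small ridge
penalty by default (`decay = 1e-4`, recorded on the model; set it to 0
for the unpenalized fit). Internal validation refits the model on
repeated seeded 75/25 splits and reports training- and testing-fold
accuracy quantiles in percent; splits whose training fold misses a
subgroup are resampled with a cap. Every patient receives the full
softmax probability vector *and* a dichotomized label (highest
probability, exact ties to the lowest subgroup index, flagged) — the hard
label drives the risk table and the hierarchical model, while the
probabilities feed the per-patient importance score
$IS_k = MP_k \times R_k$ (membership probability times subgroup risk),
which ranks subgroups, and thus subgroup-targeted interventions, for an
individual. Subgroup risk is the plain proportion
$\mathrm{cases}_k / (\mathrm{cases}_k + \mathrm{controls}_k)$ among all
classified patients; an empty subgroup is *undefined*, never zero.

## Risk prediction and model comparison

The prediction stage fits two binary logistic models of 30-day
readmission on a 75% training fold: a *standard* model (comorbidities +
demographics) and a *hierarchical* model that adds subgroup membership as
$K-1$ indicator variables with subgroup 1 as reference — an integer
coding would impose an ordering the subgroups do not have. Complete
separation is detected from saturated fitted probabilities and handled by
a recorded ridge refit. On the 25% validation fold the models are
compared by:

* **Discrimination** — the C-statistic (ROC AUC) with DeLong confidence
  intervals, and a paired DeLong contrast whose squared z is reported as
  a 1-df chi-squared. Per-subgroup C-statistics of the standard model
  identify subgroups the pooled model underserves; they are labeled
  non-comparable across populations.
* **Calibration** — the calibration slope (coefficient of the linear
  predictor in a logistic refit; ideal 1) and calibration-in-the-large
  (intercept with the linear predictor as offset; ideal 0).
* **Reclassification** — continuous and categorical NRI and IDI with
  large-sample variances. The categorical NRI needs risk cutpoints; no
  canonical cutpoints exist for this problem, so they are configurable
  and default to tertiles of the standard model's validation risks,
  always echoed in the result.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws each patient a subgroup (uniform by default;
weights configurable), gives them each comorbidity of their subgroup's
block with probability `p_in` and every other comorbidity with `p_out`,
samples demographics independently of subgroup (so exact matching removes
no subgroup signal; a confounding switch correlates them for stress
tests), and draws case status Bernoulli with the subgroup's risk. The
generator then oversamples and truncates to the requested case/control
counts, which keeps the subgroup composition of cases and controls
unbiased. Planted parameters used throughout the tests — `p_in = 0.4`,
`p_out = 0.05`, $K = 4$, $d = 30$, 2000 cases, subgroup risks 12–20% —
mirror the magnitudes the method is reported to work at in its field:
four subgroups over ~30 surviving comorbidities with readmission risks
spread over that range.

The generator does *not* emulate correlated comorbidities within a block
beyond co-membership, overlapping subgroups, comorbidity severity, or
time structure (index admissions and readmission windows are upstream of
this package). Tests passing on planted cohorts therefore demonstrate
correctness of the machinery — recovery of structure that is present,
calibrated null behavior when it is absent — not performance on real
claims data.

## Numerical choices and conventions

* Modularity fixed points stop when a full sweep improves $Q$ by less
  than 1e-12; hitting the sweep cap (default 200) warns and returns the
  best partition so far.
* Partition labels are canonicalized to consecutive integers by first
  appearance (comorbidity nodes first), making results stable across
  restarts that find the same clustering.
* The permutation test refuses `n_perm < 20` (the null standard
  deviation is too unstable to standardize against).
* A degenerate null (zero variance) yields z = 0 when the observed value
  equals the null mean, and z = Inf when it exceeds it.
* 50/50 splits are stratified by case status; odd strata put the extra
  patient in the training half.
* Problem sizes in the test-suite and acceptance script (10–20 seeds,
  200 permutations for the planted significance run, 50–100 validation
  splits, one 50,000-patient comparison run) were chosen as the smallest
  sizes at which the planted effects are comfortably resolvable; the
  pipeline defaults remain at the full 1000 permutations / 1000 splits.

## Design choices where the method was genuinely open

* **Optimizer.** Bicluster modularity maximization does not mandate an
  algorithm; BRIM-style alternating optimization with multi-restart and
  an agglomerative warm start was chosen because it is standard,
  auditable, and deterministic given a seed.
* **Permutation null.** "Random permutations" is under-specified;
  degree-preserving swaps are the default because degree heterogeneity
  otherwise inflates z, with the row-wise shuffle kept as a switch. Null
  modularities are re-optimized per permutation (with a reduced,
  recorded restart budget) rather than scored against the observed
  partition, the conservative reading of a permutation test on an
  optimized statistic.
* **Replication metric.** The Rand index is computed on comorbidity
  nodes only, reading "similarity in comorbidity co-occurrence"
  literally; patients differ across halves, so no patient-level RI
  exists.
* **Univariable screening statistic.** Wald tests on the 2×2 log odds
  ratio; conditional (matched-pair) alternatives are deliberately not
  the default since the reported quantity is the unconditional OR.
* **Membership coding in the hierarchical model.** $K-1$ dummies,
  reference subgroup 1. The hard label (not the probability vector)
  enters the model, matching the dichotomization convention; the
  probabilities are retained on every output for downstream use.
* **Detectability of subgroup effects.** When planted blocks are widely
  separated (`p_in = 0.4` vs `p_out = 0.05`), a linear comorbidity model
  recovers subgroup membership almost perfectly, so subgroup-specific
  risk offsets add nothing detectable — the comparison behaves as a
  null, which is itself a meaningful check. The power scenario for the
  model comparison therefore uses weak separation (`p_in = 0.2`,
  `p_out = 0.1`) with logit offsets $(-0.7, 0, 0.35, 0.7)$, where the
  offsets are genuinely invisible to comorbidity main effects.

## Known limitations

* The optimizer guarantees a local optimum of the alternating scheme,
  not the global maximum; the brute-force equivalence tests cover graphs
  up to 10 nodes only.
* NRI and IDI variances use the classical large-sample formulas, which
  are known to be anti-conservative for nested models fit on the same
  data; they are reported for comparability, not as definitive tests.
* The classifier is a plain multinomial logit; no probability
  calibration or alternative classifiers are provided.
* Subgroup-specific prediction models (separate slopes per subgroup) are
  out of scope.

## A small worked run

```{r pipeline, eval = FALSE}
cfg <- run_config(
  seed = 42, out_dir = "run1",
  synthetic = list(n_cases = 600, n_controls = 1800, n_comorbidities = 15,
                   n_subgroups = 3, p_in = 0.5, p_out = 0.05,
                   subgroup_risks = c(0.08, 0.2, 0.4)),
  restarts = 8, perm_restarts = 3, n_perm = 200, n_splits = 100)
summary <- run_pipeline(cfg)
```

The run directory then contains the cohort, the feature report, partition
tables, the GraphML network and annotated figure, classifier memberships
and validation summary, the subgroup risk table, the model-comparison
JSON, and a run log in which every stage records its derived seed and
input/output counts. The same stages are available from the shell via the
`inst/cli/subgroupnet` script (`simulate`, `select-features`, `bicluster`,
`classify`, `predict`, `report`, `run`).
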