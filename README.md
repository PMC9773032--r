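# subgroupnet

Patient subgroup discovery in bipartite comorbidity networks, with
classification of patients into the discovered subgroups and a test of
whether subgroup membership improves 30-day hospital readmission risk
prediction.

## Who this is for

Biostatisticians and epidemiologists working with case/control cohorts of
hospitalized patients (e.g. elderly COPD, heart-failure, or arthroplasty
admissions) who want to move beyond pooled comorbidity main-effect models:
first find *which* comorbidities co-occur in *which* patients, then ask
whether that structure carries outcome information. Restricted claims data
cannot ship with the package, so a synthetic cohort generator with planted
structure makes every stage runnable and testable out of the box.

## The method

1. **Visual-analytical step.** Readmitted cases form a bipartite graph
   (patients x comorbidities, after 1:1 matched-control univariable
   screening with Bonferroni correction in both split halves). Biclusters
   — patient subgroups plus their co-occurring comorbidities — maximize
   bipartite (Barber) modularity

   *Q* = (1/m) Σᵢⱼ (Aᵢⱼ − kᵢdⱼ/m) δ(gᵢ, gⱼ),

   optimized by BRIM-style alternating label updates with multi-restart.
   Significance comes from a degree-preserving permutation test (the
   optimizer is re-run on every rewired graph); replication across split
   halves is measured by the Rand index on comorbidity labelings with a
   label-permutation null.
2. **Classification step.** A (lightly ridged) multinomial logistic model
   learns the discovered subgroup labels from the selected comorbidities,
   is internally validated over repeated 75/25 splits, classifies all
   cases *and* controls, and yields per-subgroup readmission risks and
   per-patient importance scores IS = membership probability x subgroup
   risk.
3. **Prediction step.** Standard (comorbidities + demographics) vs.
   hierarchical (+ K−1 subgroup dummies) logistic readmission models are
   compared on a validation fold: C-statistics with DeLong intervals, a
   paired DeLong chi-squared contrast, calibration slope and
   calibration-in-the-large, per-subgroup C-statistics, and NRI/IDI.

## Worked example

```r
library(subgroupnet)

cfg <- run_config(
  seed = 42, out_dir = file.path(tempdir(), "run1"),
  synthetic = list(n_cases = 600, n_controls = 1800, n_comorbidities = 15,
                   n_subgroups = 3, p_in = 0.5, p_out = 0.05,
                   subgroup_risks = c(0.08, 0.2, 0.4),
                   demographic_levels = list(
                     age_band = c("66-75" = 0.6, "76+" = 0.4),
                     sex = c(F = 0.55, M = 0.45),
                     race = c(White = 0.8, Other = 0.2),
                     medicaid = c(no = 0.85, yes = 0.15))),
  restarts = 8, perm_restarts = 3, n_perm = 30, n_splits = 10)
run_pipeline(cfg)
```

The run log prints one line per stage; this exact run produced:

```
simulate: generated 600 cases / 1800 controls (seed 6873734)
match: 300 pairs, 0 unmatched cases
match: 300 pairs, 0 unmatched cases
select-features: 15 tested, 8 survived (alpha_bonf = 0.00333)
bicluster: train half: 230 cases after dropping 70 empty
bicluster: replication half: 229 cases after dropping 71 empty
bicluster: K = 7, Q = 0.373, z = 1.97, P = 0.06452; RI = 0.893 (P = 1)
classify: training accuracy 100.00%; median testing accuracy 98.28%
predict: C 0.694 vs 0.691, P = 0.53; NRI cont 0.058; IDI 0.0007
```

Reading it: 8 of 15 comorbidities survived matched univariable screening
in both halves (the middle-risk block is screened out — its odds ratio is
near 1); the 230 training cases bicluster with modularity Q = 0.373, not
significant against the degree-preserving null at this small size
(z = 1.97, 30 permutations); the multinomial classifier reproduces the
discovered subgroups almost perfectly; and the hierarchical readmission
model does not significantly out-discriminate the standard model
(DeLong P = 0.53) — at this separation the comorbidity main effects
already carry the subgroup signal. At study-scale settings (2000+ cases,
200+ permutations, `restarts = 20`) the planted structure is recovered
with ARI 1.0, z > 3 and empirical P at the floor; see the acceptance
script below. The run directory also holds `network.graphml`, an
annotated SVG figure (comorbidities ranked by odds ratio, subgroup risks
as percentages), and CSV/JSON tables for every stage.

A shell entry point wrapping the same stages is installed at
`inst/cli/subgroupnet`:

```sh
Rscript inst/cli/subgroupnet run --config config.yaml
Rscript inst/cli/subgroupnet simulate --seed 7 --out run2
```

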