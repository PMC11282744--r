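# convprofiler

Survival-tree discovery of patient profiles associated with earlier or later
conversion across Alzheimer's disease (AD) stages, from right-censored
memory-clinic visit records.

## What it does

Patients progress from mild cognitive impairment (MCI) through mild,
moderate and severe AD dementia at very different speeds. Given
longitudinal visit records (diagnosis label, MMSE, socio-demographics,
comorbidity and drug flags per patient), `convprofiler`:

1. applies inclusion/exclusion rules (age 50–90 at first visit, ≥ 2 visits,
   no excluded etiology) with full flowchart accounting;
2. assigns stages from diagnosis + MMSE (MCI requires MMSE > 20; dementia
   bands: mild 20–26, moderate 11–19, severe < 11) and builds three
   overlapping cohorts with the right-censored **time to conversion**
   `TTC = first visit at a more advanced stage − index date` (days);
3. encodes predictors for trees: continuous variables median-imputed,
   categoricals one-hot, and every binary recoded to three states
   (0 known-FALSE, 1 missing, 2 known-TRUE) so trees can split on
   missingness at 0.5 or 1.5; variables ≥ 20% missing are dropped;
4. estimates survival with its own Kaplan-Meier
   (S(t) = ∏_{t_i ≤ t} (1 − d_i/n_i), Greenwood band), screens each
   variable with the two-sample log-rank test
   (χ² = (Σ(O_t − E_t))² / ΣV_t with hypergeometric V_t), and fits Cox
   models by Breslow partial likelihood for adjustment;
5. grows an ensemble of survival trees (split quality = log-rank statistic
   between children; exhaustive threshold scan; deterministic tie-breaks),
   pruned by cross-validated cost complexity;
6. mines tree nodes for subgroups whose median TTC (or Q3 = 25%-converted
   time when the median is not reached) deviates ≥ 15% from the cohort
   reference while covering ≥ 6% of the cohort, confirms each against its
   complement with a log-rank test, and — for rules involving anti-dementia
   treatment — a Cox model adjusted for the number of comorbidities.

A seeded synthetic registry generator (`sim_config` / `generate_registry`)
with planted proportional-hazards subgroups makes the whole pipeline
verifiable without patient data; latent conversion times travel with the
registry as a truth payload for recovery tests.

## Worked example

```r
library(convprofiler)

cfg <- sim_config(
  n_patients = 1600, age_range = c(50, 90),
  stage_distribution = c(MCI = 1, mild = 0, moderate = 0),
  baseline_hazards = c(
    mci_to_dementia = log(2) / 500,
    mild_to_moderate_severe = log(2) / 700,
    moderate_to_severe = log(2) / 1675
  ),
  planted_effects = list(
    planted_effect(list(hypertension = TRUE, anxiety = TRUE), 3,
      "mci_to_dementia", label = "earlier"),
    planted_effect(list(anti_dementia = TRUE), 0.4,
      "mci_to_dementia", label = "later")
  ),
  excluded_etiology_rate = 0, seed = 7
)
registry <- generate_registry(cfg)
cohort   <- build_cohort(registry, "mci_to_dementia")
profiles <- mine(cohort, control = mine_control(n_trees = 20), seed = 11)
print(profiles)
```

Output (abbreviated):

```
Subgroup mining on 'mci_to_dementia': n = 1529, 20 tree(s), reference median TTC = 20.6 months
  [1] earlier (anti_dementia: known-False & anxiety: True-or-missing & hypertension: True-or-missing):
      median TTC 10.6 mo (-49%), n=225 (15%), log-rank p=6.11e-54, adj. HR=2.99 (p=1.15e-38)
  [2] earlier (anxiety: True-or-missing & hypertension: True-or-missing):
      median TTC 11.1 mo (-46%), n=271 (18%), log-rank p=7.44e-49
  ...
  [7] later (anti_dementia: True-or-missing):
      median TTC 35.3 mo (+72%), n=257 (17%), log-rank p=4.38e-17, adj. HR=0.49 (p=3.99e-17)
```

Reading it: the planted hypertension ∧ anxiety profile converts to dementia
in about half the cohort's median time (the HR ×3 effect), and the planted
anti-dementia-treatment profile in nearly double (HR ×0.4); `adj. HR` is the
comorbidity-adjusted Cox hazard ratio for treatment-linked rules, and the
percentages are relative deviations from the cohort reference quantile.

The full pipeline (simulate/ingest → filter → cohorts → encode → describe →
screen → mine → report, with a reproducibility manifest) is `run_pipeline()`
or, from a shell, the thin wrapper:

```sh
Rscript inst/cli/convprofiler.R all --config run.yaml --seed 7 --out results/
```

## Layout

- `R/` — simulation, cohort pipeline, encoding, survival estimators, trees,
  mining, reporting
- `tests/testthat/` — unit, property and acceptance suites (oracle
  cross-checks against the `survival` package)
- `vignettes/conversion-profiles.Rmd` — methods: model, parameters,
  pruning design, generator assumptions and limitations
- `inst/cli/convprofiler.R` — command-line front-end
- `scripts/acceptance.R` — headline-quantity recomputation
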