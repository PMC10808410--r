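# comorbnet

Multimorbidity co-occurrence networks and emotional distress in EMR-style
cohorts of older patients with osteoporosis.

Hospital inpatients with osteoporosis typically carry many additional
diagnoses (multimorbidity), and a substantial minority screen positive for
clinically significant anxiety and/or depression (CSAD, defined as a Huaxi
Emotional-distress Index total score ≥ 11). `comorbnet` implements the full
analysis pipeline for such cohorts: ICD-10 three-character normalization,
multimorbidity counting and CSAD flagging, descriptive group comparisons,
multivariable logistic risk models, and — the core — construction of
disease co-occurrence networks from pairwise relative risks, exported in
Gephi-ready formats. A Gaussian-copula synthetic-cohort generator,
calibrated to a published 13,359-patient reference cohort, stands in for
the (unavailable) hospital EMR so that every stage is testable.

## The statistic at the core

For diseases A and B with cohort prevalences `p_A`, `p_B` among `N`
patients:

    O  = #{patients with both A and B} / N        (observed prevalence)
    E  = p_A * p_B                                (expected under independence)
    RR = O / E  =  N * n_AB / (n_A * n_B)         (relative risk)

An edge joins A and B when `RR > 1`; nodes require cohort prevalence
\> 1%. Node size carries prevalence, node color degree, edge weight the raw
co-occurrence count. CSAD enters as a pseudo-disease column so that
disease–distress associations use the identical machinery, ranked by
co-occurrence count. Risk factors for CSAD (sex, age, marital status,
multimorbidity count) are estimated by maximum-likelihood logistic
regression with Wald 95% intervals, overall and sex-stratified.

## Worked example

```r
library(comorbnet)

cfg   <- default_config()                  # the calibrated stated world
coh   <- generate_cohort(cfg, seed = 101)
ic    <- ingest_cohort(coh$patients, coh$diagnoses)
dm    <- build_matrix(ic)
net   <- build_network(all_pairs(dm), dm$prevalence)
cn    <- csad_network(dm, ic$records$csad)
head(net$edges, 3)
```

Running the numbered workflow (`analysis/01_simulate.R` …
`analysis/04_network.R`) on this seed prints:

```
realized prevalences within 0.0049 of targets
CSAD rate: 6.8%; mean multimorbidity count: 2.63
16 diseases exceed 10% prevalence; most common: I10 (44.0%), M51 (20.3%), E11 (19.9%)
all patients: maritalwidowed OR 1.46 (95% CI 1.202-1.763, p = 0.000119)
all patients: n_multimorbidity OR 1.07 (95% CI 1.021-1.116, p = 0.00403)
multimorbidity network: 16 nodes, 51 edges
strongest links by co-occurrence: E11-I10 (1753, RR 1.50); I10-I70 (1640, RR 1.53); I10-I67 (862, RR 1.01)
```

Reading this: the simulator hit every target prevalence to within half a
percentage point; essential hypertension (I10) is the most common
multimorbidity at 44%; the two planted disease associations —
hypertension–diabetes (E11) and hypertension–atherosclerosis (I70) — emerge
as the two strongest network links with RR ≈ 1.5, exactly the structure the
generator was told to plant; and the planted risk-factor directions
(widowhood and multimorbidity count increase CSAD risk) are recovered by
the logistic refit. Tables land under `results/tables/`, the edge list and
GEXF/GraphML graphs under `results/network/`.

With real data, point `read_cohort()` (or `run_pipeline()`) at two CSVs:
`patients.csv` (patient_id, age, sex, marital, hei_total) and
`diagnoses.csv` (patient_id, icd_code).

## Acceptance script

`scripts/acceptance.R` re-runs the entire pipeline from scratch against the
installed package — simulating the default cohort, ingesting it, and
building every table and network — and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The pipeline artifacts for the run are written next to the report under
`results/pipeline_seed<seed>/`.

## Layout

- `R/` — package implementation (generator, ingest, descriptives, logistic
  models, pair statistics/networks, exporters)
- `analysis/` — numbered narrative workflow scripts
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/multimorbidity-networks.Rmd` — models, assumptions, parameter
  choices and limitations
- `inst/extdata/` — reference summary tables (plain CSV)
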