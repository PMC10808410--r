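---
title: "Multimorbidity networks and emotional distress: models and methods"
author: "comorbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity networks and emotional distress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

## The scientific problem

Older inpatients with osteoporosis rarely present with osteoporosis alone.
Their diagnosis lists carry hypertension, type 2 diabetes, atherosclerosis,
degenerative joint and spine disease, and much else; this co-occurrence of
chronic or acute conditions in one patient is *multimorbidity*. Many of the
same patients also screen positive for clinically significant anxiety
and/or depression (CSAD). This package implements an analysis pipeline that
quantifies which diseases cluster together in such a cohort, and which
diseases travel with emotional distress, as co-occurrence networks built
from electronic-medical-record (EMR) style data.

The pipeline is calibrated against a published tertiary-hospital cohort of
13,359 Chinese Han inpatients with osteoporosis aged 50–101 (mean 69.9,
SD 10.2; 80.2% female), whose summary tables ship with the package as plain
CSV (`reference_table()`). The patient-level EMR behind those tables is not
publicly available, so a synthetic-cohort generator reproduces its stated
statistical structure; everything downstream is tested against that
generator and against arithmetic recomputed from the printed tables.

## The core statistic: observed/expected relative risk

For a disease pair $(A, B)$ in a cohort of $N$ patients, with marginal
prevalences $p_A$ and $p_B$:

* observed pair prevalence: $O = \frac{\#\{A \text{ and } B\}}{N}$,
* expected prevalence under independence: $E = p_A \, p_B$,
* relative risk: $\mathrm{RR} = O / E = \frac{N \cdot n_{AB}}{n_A\, n_B}$.

$\mathrm{RR} > 1$ marks a positive association and defines a network edge.
The edge criterion is the *bare* ratio, with no sampling-noise test —
that is the reference procedure, implemented as printed. Users who want
noise control can enable an optional one-sided Fisher exact filter
(`fisher_alpha` in `build_network()`), which is off by default precisely
because it is not part of the reference criterion. Network inclusion also
requires each disease's cohort prevalence to exceed 1%. We read that
prevalence filter as applying to the individual disease's marginal
prevalence (not the pair's joint prevalence); node degree is computed after
edge filtering, and the node set is the set of endpoints of surviving
edges. The index-disease codes (osteoporosis, `M80`/`M81` by default) are
excluded from the node set, since the network is a network of
multimorbidities; a flag restores them for sensitivity analyses.

Emotional distress enters the same machinery as a pseudo-disease: the CSAD
flag becomes a binary column with prevalence equal to the cohort CSAD rate,
and `csad_network()` computes the CSAD–disease pair statistics, retains
diseases with $\mathrm{RR} > 1$, and ranks them by co-occurrence count
(ties by RR, then by code — the reference ranks its strongest links by raw
co-occurrences, so we rank the same way). The reference map shows eight
such diseases; `top_k = 8` is therefore the default, and it is an explicit
parameter because the original selection rule (RR cutoff, count cutoff, or
visual salience) is not stated.

## Cohort definitions

* **ICD-10 normalization.** Diagnoses are grouped at the three-character
  category: first letter plus two digits (`"M81.0"` → `"M81"`), applied
  case-insensitively with dots and whitespace stripped. Codes that do not
  reduce to letter+digit+digit are rejected and logged.
* **Multimorbidity count.** Any category other than the index osteoporosis
  codes counts once per patient (set semantics); a patient with only index
  codes counts 0. The index set defaults to `{M80, M81}` (osteoporosis with
  and without pathological fracture) because the source analysis says only
  "osteoporosis"; it is configurable.
* **CSAD.** HEI (Huaxi Emotional-distress Index) total score ≥ 11, the
  scale's validated cutoff. Records without a score are excluded from all
  CSAD analyses (in the reference cohort only 13,359 of 18,417 unique
  patients were screened).
* **Admission merging.** The reference reports unique patients without
  stating its merge rule. Our documented policy: diagnosis codes are
  unioned across a patient's rows, demographics come from the earliest row,
  and the HEI total from the earliest row carrying a score.
* **Age groups.** 50–59, 60–69, 70–79, ≥80, matching the reference strata.

## The synthetic cohort generator

`default_config()` states the emulated world once:

| parameter | default | source |
|---|---|---|
| n | 13,359 | reference cohort size |
| age | normal(69.9, 10.2), truncated \[50, 101\], integer years | reference Table 1 |
| female share | 0.802 | reference Table 1 |
| marital | married/unmarried/widowed/divorced = .868/.006/.110/.015, renormalized (printed values sum to 0.999) | reference Table 1 |
| diseases | the 16 >10%-prevalence categories at their printed prevalences | reference Table 2 |
| latent correlations | 0.4 for (I10,E11) and (I10,I70), zero elsewhere | see below |
| CSAD model | logit$^{-1}$(−1.0 + 0.21·female − 0.03·age + 0.42·widowed + 0.058·count) | free parameters, see below |
| HEI maximum | 27 | assumption, see below |

**Copula mechanism.** Disease presence is drawn by Gaussian-copula
thresholding: one latent multivariate-normal vector per patient with the
configured correlation matrix, disease $j$ present iff the latent value
exceeds $\Phi^{-1}(1 - p_j)$. This was chosen because the source states no
generative model, and it gives exact marginal control (each disease's
prevalence is hit regardless of the correlations) with tunable pairwise
dependence. The matrix must be symmetric PSD with unit diagonal;
`validate_config()` rejects anything else with the offending eigenvalue.
Optional sex/age prevalence multipliers are applied as probit-scale shifts
of the threshold (centred at the mean age), so marginals stay interpretable.

**Why 0.4 for the planted correlations.** The reference arithmetic implies
an observed-scale RR ≈ 1.56 for the hypertension–diabetes pair
(O = 1,835/13,359 against E = 0.439 × 0.201). A latent (tetrachoric)
correlation of 0.4 at those prevalences reproduces that magnitude
(realized RR ≈ 1.5), so 0.4 is the single documented default for both
planted pairs.

**Why those CSAD coefficients.** The reference's fitted odds ratios are
*outputs* of a model conditioned on the real covariate distribution, not
generative truth, so the generator's `csad_betas` are free parameters. The
defaults point the same way as the reference risk-factor analysis (female
and widowhood up, age down, count up, magnitudes near the published ORs)
and give a ≈7% CSAD rate. They were chosen once and are recovered — not
reproduced as the published numbers — by refitting.

**HEI totals.** The scale is nine items with a cutoff of 11, but item
scoring is not specified in our sources; totals are drawn directly, uniform
on \[11, `hei_max`\] for CSAD patients and \[0, 10\] otherwise, with
`hei_max = 27` (nine items scored 0–3) as a configurable assumption. This
makes the flag and the score consistent by construction; nothing downstream
uses the total beyond the cutoff.

**Ages by rejection.** Ages are rejection-sampled from the normal within
\[50, 101\] and rounded to whole years; the lower bound is a validated
invariant because the cohort is defined as aged 50 or older.

**What a green test does not establish.** The generator has 16 diseases,
not the 669 categories of the real EMR, so the simulated mean
multimorbidity count (≈2.6) is far below the reference's 6.4, and simulated
networks are 16-node networks, not the published 67-node/407-edge map.
Those headline numbers depend on the unavailable patient-level data; the
pipeline reproduces their *format* end-to-end, and the tests establish
correctness of the statistics (exact oracles), calibration of the generator
(marginals, planted associations), and recoverability of planted parameters
— not the published values themselves.

## Statistical choices

* **Group comparisons.** Chi-square without continuity correction and the
  Welch $t$ test are the defaults; the corrected chi-square and
  pooled-variance $t$ sit behind flags, because the source states only
  "$t$-test or $\chi^2$ test". Significance is read at a two-tailed
  $\alpha$ = 0.05. Strata with zero counts are dropped before the
  chi-square; degenerate constant groups report $t = 0, p = 1$ when equal.
  One recomputation note: the printed sex-by-CSAD counts
  (843/10,717 vs 174/2,642) give $\chi^2$ $p \approx 0.025$ — significant
  at 0.05, though smaller than the "<0.001" printed beside them; the tests
  freeze the recomputed value.
* **Logistic model.** Maximum likelihood via IRLS (binomial GLM; ≤100
  iterations, tolerance 1e-8), Wald intervals
  $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$ — the reference CIs are symmetric
  on the log scale, consistent with Wald rather than profile likelihood.
  Age and multimorbidity count enter linearly (per year, per condition);
  marital status uses treatment coding with married as reference. No
  regularization: separation is detected and reported via the `converged`
  flag. Strata with fewer than two events are flagged and not fit.
* **Ranks and ties.** Prevalence-table ranks are descending by count within
  each column, ties broken by code lexicographic order (the reference
  tables show no ties, so the rule only matters for synthetic edge cases).
* **Percent formatting.** One decimal place, matching the reference tables;
  every printed percentage is recomputable from its numerator/denominator
  pair, and the test suite does exactly that for all rows.

## Numerical and testing notes

* RR is computed as the literal ratio `observed / expected`; the identity
  with the count form $N n_{AB} / (n_A n_B)$ holds to machine precision and
  is asserted in tests.
* Exhaustive oracle checks enumerate *all* binary matrices up to 4 patients
  × 3 diseases against a per-patient brute-force loop, plus hundreds of
  random matrices up to 500 × 20. (Enumerating all 8 × 4 matrices would be
  $2^{32}$ cases and is not feasible; the random 8 × 4 sweep covers that
  shape.)
* The independence-calibration check runs at $N$ = 50,000 with six diseases
  at prevalences 0.25–0.50, chosen so every pair's expected co-occurrence
  count is ≥ ~3,000 and the ±5% RR band is a ≥3-SD criterion; at 10%-scale
  prevalences the band would be within sampling noise and the check would
  be uninformative.
* Graph exports serialize numeric attributes with 17 significant digits, so
  GEXF and GraphML round-trips reproduce node/edge sets and attributes
  exactly; `igraph::read_graph()` serves as an independent reader
  cross-check for GraphML.
* Determinism: identical `(config, seed)` produces byte-identical cohorts
  and pipeline bundles; the run manifest records seed, thresholds,
  rejection counts and versions, and deliberately omits timestamps so
  reruns compare byte-for-byte.

## Known limitations

* Sixteen modelled diseases versus 669 real categories (see above);
  multimorbidity counts and network size are correspondingly smaller.
* No longitudinal structure: admissions, onset ordering and treatment are
  out of scope, as is any causal reading of the edges.
* HEI psychometrics beyond the total-score cutoff are not modelled.
* The bare RR > 1 edge criterion admits sampling noise by design (it is the
  reference criterion); the Fisher filter exists for users who want to
  tighten it, and raising `rr_threshold` can only remove edges
  (monotonicity is tested).

## A short tour

```{r tour, eval = FALSE}
cfg <- default_config(n_patients = 5000)
cohort <- generate_cohort(cfg, seed = 1)
ic <- ingest_cohort(cohort$patients, cohort$diagnoses)
dm <- build_matrix(ic)

table_one(ic)                      # demographics by CSAD status
prevalence_table(dm, ic)           # >10% diseases by sex and age group
table_three(ic)                    # logistic CSAD risk factors

pairs <- all_pairs(dm)
net <- build_network(pairs, dm$prevalence)
hubs(net)
cn <- csad_network(dm, ic$records$csad)
write_gexf(net, "multimorbidity_network.gexf")
```

The numbered scripts under `analysis/` run the same stages as a narrative
workflow and write their tables under `results/`.
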