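# scnpdx

Single-cell network profiling (SCNP) classifiers for predicting response to
induction chemotherapy in elderly AML.

## What this package is for

In patients over 55 with newly diagnosed non-promyelocytic AML, standard
cytarabine + daunorubicin induction produces a complete response (CR or CRi)
in only about half of cases, at considerable toxicity. SCNP measures — by
multiparameter phospho-flow cytometry on pre-treatment bone-marrow or blood
samples — how strongly each patient's leukemic blasts activate apoptosis when
exposed ex vivo to the same drugs for 24 hours. That functional readout turns
out to predict the clinical response.

`scnpdx` implements the complete analysis chain for this kind of assay, for
biostatisticians and cytometrists building or validating functional response
classifiers:

* a **synthetic cohort simulator** (patients, plates, wells, single-cell
  events, calibration beads) with a latent per-patient chemosensitivity
  linking the ex-vivo apoptosis response to the induction outcome — the
  original clinical samples are private, so all methods are exercised on
  simulated data with known ground truth;
* **bead calibration** (8-peak rainbow particles → Equivalent Reference
  Fluorophores) and the four-level **gating hierarchy** (intact ⊇ viable ⊇
  blast ⊇ cPARP-negative blast);
* the five **node metrics** per signaling node — Basal, log2Fold, the scaled
  Mann-Whitney statistics `Uu`/`Ua`, and PhIntact (percent cPARP-negative
  blasts at the autofluorescence 98th-percentile split);
* the **locked two-node classifier**

  ```
  N1 = Uu(AraC+Dauno 24 h → cPARP)    C1 = (N1−0.5)² if N1 > 0.5 else 0
  N2 = Uu(AraC+Dauno 24 h → CD34)     C2 = (0.5−N2)² if N2 < 0.5 else 0
  score = plogis(−1.26004 + 95.60133·C1 + 34.94358·C2)
  ```

  shipped as a read-only JSON artifact, plus clinical comparator models
  (LASSO on at-diagnosis clinical inputs, with and without
  cytogenetic/molecular markers);
* the **classifier-development pipeline**: node prescreening (univariate
  test ∪ random-forest importance ∪ LASSO), all 2–4-node combination
  logistic models, ranking by bootstrap **optimism-adjusted AUROC**, and
  out-of-bag AUROC;
* the **validation-statistics suite**: trapezoidal AUROC (= scaled
  Mann-Whitney U), an exact one-sided test of AUROC = 0.5 (dynamic-programming
  null distribution), BCa and DeLong confidence intervals, power simulation,
  paired BM/PB concordance, subgroup analysis;
* **Pocock-Simon minimization** randomization, analysis-set construction
  with exclusion logging, and clinical imputation rules.

## Worked example

Simulate a 40-patient bone-marrow cohort, compute the node-metric table,
apply the locked classifier and test its association with outcome:

```r
library(scnpdx)

cfg <- scnp_sim_config(n_patients = 40, mean_events = 2000,
                       tissue_prob = c(BM = 1, PB = 0), seed = 7)
coh <- simulate_cohort(cfg)
coh
#> <scnp_cohort> 40 patients, 40 patient-tissue units, 320 wells, 2 plates (seed 7)
#>  CR CRi  RD TRM
#>  17   8  10   5

nt <- compute_node_table(coh)
head(nt[, c("patient_id", "modulator", "time_hr", "readout", "metric", "value")], 3)
#>   patient_id  modulator time_hr readout metric value
#> 1      P0001 AraC+Dauno      24   cPARP     Uu 0.925
#> 2      P0001 AraC+Dauno      24    CD34     Uu 0.121
#> 3      P0001       AraC      24    CD34     Uu 0.241

sc <- score_cohort(nt)                       # locked DX_SCNP scores
y  <- coh$patients$outcome[match(sc$patient_id, coh$patients$patient_id)]
keep <- !is.na(sc$score) & y %in% c("CR", "CRi", "RD")   # TRM excluded

auroc_trapezoid(sc$score[keep], y[keep] %in% c("CR", "CRi"))
exact_mw_test(sc$score[keep], y[keep] %in% c("CR", "CRi"))$p.value
bca_ci(sc$score[keep], y[keep] %in% c("CR", "CRi"), B = 2000, seed = 1)
```

This prints, for this seed:

```
locked-classifier AUROC 0.936, exact one-sided p = 4.7e-06, 95% BCa CI (0.79, 0.98)
```

The first patient's cPARP `Uu` of 0.93 means 93% of (treated, untreated)
blast-cell pairs had higher cleaved-PARP signal in the treated well — strong
drug-induced apoptosis — while the CD34 `Uu` of 0.12 reflects depletion of
the CD34+ blast compartment; both push the locked score toward predicted
response. An AUROC of 0.94 with p < 10⁻⁵ says the score ranks responders
above resistant patients far better than chance in this simulated cohort
(a 40-patient cohort with the default planted effect; the average across
seeds is lower).

Power planning for a 50-patient validation set:

```r
power_simulation(n_total = 50, response_rate = 0.72, true_auroc = 0.75,
                 alpha = 0.05, reps = 2000, seed = 1)$power
#> 0.909
```

## Package layout

```
R/                  implementation (simulator, calibration/gating, metrics,
                    classifiers, validation statistics, cohort operations)
inst/extdata/       locked classifier artifact (JSON), default node panel (YAML)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/scnp-methods.Rmd   methods vignette (models, assumptions, choices)
```
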