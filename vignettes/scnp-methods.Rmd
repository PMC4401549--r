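---
title: "Methods: simulation, metrics and classifier validation in scnpdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, metrics and classifier validation in scnpdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnpdx)
```

## The problem

Elderly (> 55 y) AML patients respond to standard cytarabine-based induction
chemotherapy at rates of roughly 35–50%, and treatment-related mortality is
substantial. Single-cell network profiling (SCNP) measures, by multiparameter
phospho-flow cytometry, how intracellular signaling in leukemic blasts reacts
to ex-vivo modulators — in particular how strongly the apoptosis machinery
responds to a 24-hour exposure to cytarabine + daunorubicin. `scnpdx`
implements the full analysis chain around such an assay: event-level
simulation, bead calibration, gating, node metrics, a locked two-node
response classifier, the classifier-development pipeline, and the
validation-statistics suite.

Because the underlying clinical samples are private, the package ships a
synthetic-data module that emulates the statistical structure the analysis
assumes; every downstream method is exercised and tested against data from
this generator plus analytic and brute-force oracles.

## Node metrics

A *signaling node* is a (modulator, exposure time, proteomic readout)
triple. For each node and patient sample the package computes, on gated cell
populations (see below), with `a` = autofluorescence well, `u` = unmodulated
well, `m` = modulated well:

* **Basal** `= log2(ERF_u / ERF_a)` and **log2Fold** `= log2(ERF_m / ERF_u)`
  where `ERF` is the population median of bead-calibrated intensities
  (the median is the default location statistic; the mean is available).
* **Uu** — the Mann-Whitney U statistic comparing modulated vs unmodulated
  single-cell intensities, scaled to (0, 1) by `n_m * n_u`, with midrank
  (half-credit) tie handling so identical wells give exactly 0.5. **Ua** is
  the same with the autofluorescence reference. The scaling `U/(n_m * n_u)`
  is the only scaling consistent with a (0, 1) range.
* **PhIntact** — the percentage of blast cells negative for cleaved PARP,
  with the positive/negative split at the 98th percentile of the
  autofluorescence well. Percentiles use linear interpolation between order
  statistics (R type 7); the choice matters because the split point is
  quantitatively consequential, so it is fixed and documented.

Short-term signaling nodes are computed on cPARP-negative ("healthy")
blasts. The 24-hour apoptosis nodes (AraC+Dauno → cPARP, → CD34) are
computed on total viable blasts *without* the cPARP-negative restriction —
the induced cPARP shift is precisely the signal, and restricting to
cPARP-negative cells would erase it — with the 24-hour untreated well as the
unmodulated reference.

## Calibration and gating

Each plate carries an 8-peak rainbow-bead well. Per channel, a least-squares
line through (log10 median peak intensity, log10 assigned reference value)
maps raw intensity to Equivalent Reference Fluorophores; the line is stored
as `log10(intensity) = a + b*log10(ERF)` and inverted on application, so a
plate with a pure gain `g` fits slope 1 and intercept `log10(g)`, and
calibration removes plate-to-plate gain differences. Saturated or
nonpositive peaks are excluded; at least 3 resolvable peaks are required.

Gating follows a four-level hierarchy: *intact* cells by a rectangular
scatter region between per-well quantile bounds (default 2nd–98th
percentile on FSC and SSC); *viable* cells with the amine viability dye
below the 98th percentile of an unstained reference (the same percentile
rule as the cPARP split, for internal consistency); *blasts* as the
CD45-dim cluster among viable cells with an SSC upper bound; and
*cPARP-negative blasts* below the autofluorescence cPARP split. The CD45
split is a deterministic one-dimensional 2-means on log10 CD45 — if the two
cluster centers are closer than 0.4 log10 units the well is treated as a
single population (no split), which keeps pure-blast wells intact. Gating
operates on raw intensities and metrics on calibrated values; rank-based
metrics are invariant to this choice, ratio metrics inherit the plate-gain
correction. Nesting (healthy ⊆ blast ⊆ viable ⊆ intact) holds by
construction for every input.

## The locked classifier

The locked response classifier scores the probability of complete response
(CR/CRi) from two 24-hour apoptosis node metrics via hinge-squared
transforms:

```
N1 = Uu(AraC+Dauno 24 h -> cPARP)   C1 = (N1 - 0.5)^2 if N1 > 0.5 else 0
N2 = Uu(AraC+Dauno 24 h -> CD34)    C2 = (0.5 - N2)^2 if N2 < 0.5 else 0
score = plogis(-1.26004 + 95.60133 * C1 + 34.94358 * C2)
```

The coefficients are locked — shipped as a JSON artifact and read, never
refitted; a test guards the artifact against drift. Only a cPARP *increase*
(apoptosis induction) and a CD34 *decrease* (blast-compartment depletion)
contribute: the score is nondecreasing in N1, nonincreasing in N2 and
continuous at both hinge boundaries. The refinement that produced these
transforms is not reconstructed; the generic development pipeline fits
linear logistic models on node metrics.

## The synthetic-data generator

`simulate_cohort()` draws, per patient, a latent chemosensitivity
`s ~ U(0, 1)` that drives the induction outcome through a logistic link and
scales the ex-vivo apoptosis response. Defaults encode the study conditions:

* 72% responder rate among CR/CRi/RD patients (the intercept is solved
  numerically for this rate); 15% TRM, drawn independently of `s` (the assay
  measures blast chemosensitivity, not comorbidity); responders split
  70/30 CR/CRi; 15% secondary AML; BM/PB availability 0.60/0.76 with at
  least one tissue each; ~20% unknown cytogenetics, with true cytogenetic
  risk shifting the response log-odds by ±0.6.
* Events per well are Poisson with mean 10,000 (configurable; the assay
  acquires 100,000, scaled down for tractability) from a four-component
  lognormal mixture (debris, dead, lymphocytes, blasts) with the blast
  fraction tied to the patient's blast percentage. Lognormal intensities are
  a modeling choice — flow intensities are right-skewed — not a claim about
  the original data.
* In the 24 h AraC+Dauno well, blast cPARP shifts up by `1.2 * s` and CD34
  down by `1.0 * s` (natural-log scale). Each node measures `s` with its own
  per-patient biological noise (sd 0.10 for cPARP, 0.25 for CD34, 0.35 for
  the secondary AraC-alone/etoposide exposures): without node-level noise
  all apoptosis nodes would be perfectly rank-correlated and node selection
  would be arbitrary. The outcome-link slope (6) and these noise scales were
  calibrated so the locked classifier's training OOB AUROC on simulated
  cohorts falls in the reported 0.81–0.89 range, with the direct cPARP
  execution-marker readout the most reliable single node — mirroring its
  presence in all five development candidates.
* The 24 h viability loss (amine-dye shift) is deliberately weak
  (`effect_death = 0.05`): a bare cell-death readout lacked resolution to
  predict response (AUROC ≈ 0.53), and the generator preserves that
  negative result.
* Per-plate lognormal channel gains (sd 0.10) emulate batch structure and
  are removable by bead calibration; per-patient channel offsets (sd 0.15)
  add biological baseline variation. For secondary-AML PB samples the
  latent value is mixed with an independent draw (weight 0.8 by default),
  reproducing the observed BM/PB discordance of secondary AML.

What the generator does *not* emulate: spectral compensation, doublets,
acquisition-time drift, real marker correlation structure, or the full
53-node panel (a 13-feature panel covering the classifier's nodes plus
survival-pathway, basal, phenotyping and viability readouts is shipped).
Passing tests therefore demonstrate the correctness and calibration of the
*methods*, not clinical performance on real samples.

## Classifier development pipeline

`train_dx_pipeline()` mirrors the development procedure: (1) prescreen nodes
by the union of a univariate Mann-Whitney screen (level 0.05), random-forest
permutation importance (500 trees, top 15) and non-zero LASSO coefficients
(penalty by 10-fold cross-validated deviance, one-standard-error rule);
(2) fit a logistic model for every 2-to-4 node combination of the
candidates on per-subset complete cases; (3) rank by optimism-adjusted
AUROC — apparent AUROC minus the bootstrap estimate (default B = 500) of
the optimism, each resample refitting the model and comparing its AUROC on
the resample vs on the original data; (4) report the top model's out-of-bag
AUROC (per-patient OOB scores averaged over resamples). Candidate sets are
sorted internally so rankings are order-invariant; bootstrap draws with a
degenerate class are redrawn and counted.

The clinical comparators use the same penalized machinery: level 1 on the
at-diagnosis clinical inputs only, level 2 adding cytogenetic risk, the
CD34+ percentage from the SCNP phenotyping well, FLT3-ITD (continuous and
binary) and NPM1. An all-zero LASSO solution marks the model "not
constructible" — the expected outcome for level 1 on outcome-independent
clinical data.

## Validation statistics

* **AUROC** is computed by the trapezoidal rule, which equals the scaled
  Mann-Whitney statistic `U/(n1*n0)` with half-credit ties. (A printed
  form `U/(n1+n2)` circulates; it is inconsistent with U's maximum `n1*n2`
  and with the (0, 1) range of an AUROC, and `U/(n1*n0)` is used
  throughout.)
* The **exact one-sided test** of `AUROC = 0.5` computes the exact null
  distribution of U by a dynamic-programming count over rank assignments
  (`N(u; m, n) = N(u-n; m-1, n) + N(u; m, n-1)`), verified against full
  enumeration and the reference distribution function. With ties the exact
  count does not apply and a 10^4-draw permutation null is substituted.
* **BCa bootstrap intervals** stratify resampling within outcome class,
  take the bias correction from the fraction of bootstrap AUROCs below the
  estimate and the acceleration from jackknife skewness, and fall back to
  the percentile interval (with a warning) when the bootstrap distribution
  degenerates, as under perfect separation.
* **DeLong intervals** use the structural-components variance. Because the
  AUROC is bounded, the Wald interval is constructed on the logit scale by
  default (the plain AUROC-scale Wald, available as an option, covers only
  ~92.5% at n = 50 — a known small-sample deficiency — while the logit
  construction holds ~95%). Perfect separation yields a zero-width interval
  flagged as degenerate.
* **Power** for a prospective validation cohort is simulated from the
  binormal model (`mu = sqrt(2)*qnorm(AUROC)`), applying the exact test per
  replicate; the null distribution is cached per `(n1, n0)`, making 2000
  replicates essentially instantaneous.
* **Subgroups** (sex, age and WBC at the median, cytogenetic risk with
  unknown imputed to intermediate) are scored with DeLong intervals; values
  equal to the median go to the lower side, and subgroups missing an
  outcome class are flagged rather than scored.
* The **combined logistic model** of response on the SCNP and clinical
  scores jointly tests whether the SCNP information is redundant; exact
  collinearity is refused rather than silently producing a p-value. Wald
  inference is the default, likelihood-ratio optional.

## Cohort operations

Randomization into Training/Validation uses Pocock-Simon minimization with
the range imbalance measure, unit factor weights and deterministic-assignment
probability 0.8 (config-exposed; the balancing factors are induction
response, sample types, cytogenetic risk, parent trial arm, FLT3-ITD and
readout availability, with "missing" as a level). Analysis sets exclude TRM
patients and patients with no assessable sample, with logged reasons; a
patient with both tissues appears once in each tissue's set. Imputation
maps unknown cytogenetics to intermediate and fills other missing
covariates with the reference (training) median or mode, recording
provenance per field — reference-based statistics avoid leaking validation
information.

## Numerical choices and problem sizes

Tie handling is midrank everywhere; percentiles are type 7; the CD45
cluster split is deterministic (no RNG); logistic refits inside the
bootstrap loops use an in-package Newton/IRLS solver (ridge 1e-8,
iteration cap 30) whose agreement with `stats::glm` is asserted by a test —
the iteration cap also bounds coefficients under separation, where
rank-based AUROC remains well defined. All stochastic steps take explicit
seeds; cohort simulation is byte-reproducible given its config.

The shipped tests exercise the pipeline at reduced but statistically
adequate sizes chosen by us: simulated test cohorts use ~100 patients and
~2,000 events per well (node-level Uu sampling error at 2,000 × 2,000
events is negligible next to between-patient spread), optimism adjustment
uses B = 50 per model in pipeline recovery runs (the ranking is stable well
below the production default of 500), interval-coverage checks use 500
simulated cohorts, and the power calculation uses 2,000 replicates.

## Known limitations

The generator's channel distributions and gate geometry are idealized;
absolute gate parameters are tuned to the generator's scales and would need
re-tuning for real FCS data. The FCS3.0 reader/writer is minimal
(list-mode float32, single data segment) — sufficient for round-tripping
the package's own tables, not a general FCS parser. The piecewise-quadratic
transforms of the locked model are taken as given; re-deriving the printed
coefficients would require the original private samples.
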