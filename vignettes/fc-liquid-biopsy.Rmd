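---
title: "Modeling a fluorescent COBRA liquid-biopsy panel: assay, scores, and treatment monitoring"
author: "cobraMonitor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a fluorescent COBRA liquid-biopsy panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobraMonitor)
```

## The problem this package models

Monitoring colorectal cancer (CRC) treatment response through circulating
cell-free DNA (ccfDNA) usually requires knowing patient-specific somatic
mutations first. An alternative is to track tumor-specific DNA
*methylation*: promoter hypermethylation of *EFEMP1*, *SFRP2* and *UNC5C*
is so frequent in CRC (two promoter regions per gene, six loci in all)
that a fixed panel can be assayed in any patient without prior tumor
profiling. The readout is a fluorescent combined bisulfite restriction
analysis (COBRA) run as a multiplex "Hi-SA" assay, performed twice per
blood sample ("two-time" measurement) to stabilize detection near the
assay floor.

`cobraMonitor` implements this whole analysis chain as tested, reusable
code: an in-silico model of the assay chemistry, the scoring system built
on it, cohort-level diagnostic evaluation, and longitudinal monitoring —
plus synthetic-data generators calibrated so that every stage can be
exercised, end to end, without access to patient data.

## The in-silico assay

A `LocusPanel` holds the six amplicon templates with their CpG offsets,
HhaI (GCGC) recognition sites, and the primer end that carries the
fluorophore. The packaged default panel is *synthetic* — constructed
sequences, not genomic ones — but reproduces the structural features the
assay depends on: CpG-dense interiors, one or two GCGCG restriction sites,
COBRA-sized products (about 100–140 bp).

The chemistry chain is modeled explicitly:

1. **Bisulfite conversion** (`bisulfiteConvert`): every cytosine outside a
   methylated CpG reads as thymine; methylated CpG cytosines are
   protected.
2. **Site retention** (`retainedHhaISites`): a GCGC site survives only if
   its internal CpG cytosines were methylated. A consequence of the
   chemistry worth spelling out: the cytosine at offset +3 of the 4-mer
   must itself be a CpG cytosine (the motif is effectively GCGCG), because
   a non-CpG cytosine deaminates unconditionally and destroys the site.
   Retention of a site therefore requires *both* of its CpGs, and under
   independent per-CpG Bernoulli states the retention frequency is the
   product of their methylation probabilities. For pools in which
   molecules are either fully methylated or fully unmethylated — the
   regime COBRA quantifies — retention equals the molecule fraction.
3. **Digestion** (`digestFragments`): cleavage after the third base
   (GCG^C). Any fixed cut convention would do, since only the identity of
   the labeled-end fragment matters; this one is the enzyme's.
4. **Readout** (`quantifyPool`, `methylationRatio`): one fluorophore per
   molecule, so peak area is proportional to molecule count and the COBRA
   quantity — cut labeled area over total labeled area — is a direct
   molecule fraction. The total labeled area doubles as the *recovery
   signal*, a proxy for amplifiable, non-apoptotically fragmented
   template. Optional multiplicative log-normal peak noise and a
   detection floor emulate capillary readout; both default to off.

Zero total signal is a distinguished "no recovery" outcome: the ratio is
undefined (`NA`), not zero, and downstream scoring treats the region as
non-evaluable rather than negative — imputing a negative would fabricate
data.

## The scoring system

All tunables live in `scoringConfig()`:

* **Positivity** is a closed threshold on the methylation ratio: 0.05
  ("5% or more") for tissue COBRA, 0.01 for ccfDNA Hi-SA, where tumor
  fractions are far lower.
* The **methylation score** counts positive regions among the six
  (0–6 per replicate). The regions-vs-genes ambiguity is resolved in
  favor of *regions*, because the stage-stratified tissue frequencies are
  reported for "1 or more" and "2 or more" regions; a per-gene spread
  call (`unmethylated` / `partial` / `extensive`, i.e. neither / one /
  both regions positive) is exposed alongside.
* The **two-time methylation score** M combines the duplicate runs by
  *sum* (0–12) by default: a detection in either replicate contributes,
  which is the point of running the assay twice near its detection
  floor. The mean rule is available.
* The **recovery score** grades each locus signal 0–3 by ordered
  cutpoints and sums over the six loci (0–18 per replicate); the
  **two-time recovery score** R averages the two replicates (default;
  sum available). Whether the original two-time recovery quantity was a
  mean or a sum cannot be decided from printed summaries alone — the
  group means of 15.8 and 14.1 sit naturally in a 0–18 range, which is
  why the mean is the default — and the calibration machinery is
  rule-aware either way.
* The **combination score** is exactly linear:
  `Fc = beta1 * M + beta2 * R`. The logistic estimates motivating it
  (0.95 for M, 0.99 for R) are statistically indistinguishable from 1,
  so both coefficients default to 1.

## Synthetic cohorts and what they are calibrated to

`cohortSpec()` encodes the blood-cohort study conditions: 97 CRC patients
(23/26/27/21 at UICC stages I–IV) versus 62 controls (46 no-neoplasia,
16 adenomatous-polyp). Published cohort summaries give group means with
95% CIs of the mean; group SDs are back-derived as
`half-width / 1.96 * sqrt(n)` (`sdFromCI()`).

* **ccfDNA concentration** is log-normal (non-negative, right-skewed),
  matched in mean and SD per group (15.2 ng/ml CRC, 9.5 ng/ml control).
  A mild stage gradient (stage IV highest) is applied inside the CRC
  group and renormalized so the group mean is preserved exactly.
* **Recovery scores** use a latent per-sample level plus per-replicate
  noise, rounded and clamped to the integer 0–18 grade range. Rounding
  and the 18-point ceiling shift the observed moments — a truncated
  normal naively centered at 15.8 would undershoot the mean by about
  0.2 — so `calibrateRecoveryModel()` solves the latent mean and SD by
  deterministic quadrature so the *post*-clamping mean and SD match the
  targets. The generator then distributes each integer replicate score
  into six per-locus grades and draws signals inside the corresponding
  grade bands, so scoring recovers the programmed score exactly.
* **Methylation ratios** are zero-inflated Beta draws (a point mass at
  zero for non-shedding loci) coupled by a Gaussian copula: a per-sample
  shedding factor links loci within a subject, and the
  `replicate_correlation` parameter links the duplicate runs (1 makes
  replicates identical; the induced correlation is monotone in the
  parameter).
* **Per-locus ccfDNA positivity is not published.** It is therefore
  calibrated *indirectly*: the defaults (per-locus per-replicate
  positivity 0.38 in CRC, 0.05 in controls, cross-locus loading 0.8,
  replicate correlation 0.7) were fixed once so that the two-time
  methylation score separates the groups at an AUC near the reported
  0.85; with these defaults the recovery score and Fc land near their
  reported AUCs (0.77 and 0.90) as a by-product rather than by direct
  tuning. Combination-score simulations should be read with this
  indirect calibration in mind.

Tissue cohorts (`simulateTissueCohort()`) face a subtler constraint: the
reported per-stage frequencies of "at least one" and "at least two"
positive regions (e.g. 96.1% and 94.8% at stage I) are *incompatible
with independent loci* — conditional on one positive region, a second is
nearly certain. Methylation of the panel loci is strongly coordinated
within a tumor, so the generator uses a one-factor Gaussian copula per
stage, and `calibrateTissueModel()` solves the marginal positivity and
factor loading deterministically so both tail frequencies match.

## Diagnostic evaluation

* **Logistic fit** (`fitLogisticScores`): maximum likelihood via IRLS,
  Wald 95% CIs; separation or non-convergence is flagged, never hidden.
* **ROC/AUC** (`rocAuc`): the Mann-Whitney AUC with mid-rank tie
  handling, with DeLong 95% CIs (bootstrap optional, since the original
  CI method is not identifiable from the printed intervals). The test
  suite checks the AUC against exhaustive case-control pair counting.
* **Paired ROC comparison** (`delongTest`): the DeLong
  variance/covariance test, the standard choice for correlated ROC
  curves on the same subjects; identical scores are an exact tie
  (P = 1).
* **Cross-validation** (`stratifiedKfoldCv`): label-stratified folds,
  logistic model refit per fold, and — because the published
  cross-validated result is shown as a *single* ROC curve — the pooled
  out-of-fold predictions form one ROC rather than averaging per-fold
  AUCs. Fixed seed gives identical folds.
* **Dunn's test** (`dunnTest`): mid-ranks over the merged sample, z
  statistics of each group against the control, Bonferroni adjustment
  over the control comparisons (Dunn's classical procedure; the original
  adjustment is unstated). Verified against a permutation null.
* `wilcoxonRankSum` and `regionAssociation` cover the rank-sum test
  (exact below combined n = 20, tie-corrected normal approximation
  otherwise) and the region-1 vs region-2 regression with its pointwise
  95% band.

Mid-ranks are the tie convention everywhere (AUC, Dunn, Wilcoxon).

## Monitoring and lead time

The published clinical courses overlay three channels — Fc, serum CEA,
and imaging tumor burden (sum of maximum equators of metastatic lesions)
— as "approximation curves". No curve definition is given, so the
package uses tricube-weighted local *linear* regression over a
`span_days` window (default 60 days), which reproduces straight lines
exactly, is linear in the value scale, and never extrapolates beyond the
observed draws. Windows holding fewer than two points widen to the two
nearest observations. `stats::loess` was not reused because its span is
a fraction of points, not a day window, and draw spacing is irregular in
practice.

The rise rule (`detectRise`) is likewise a reconstruction, since the
original dating of the Fc "increase" is not operationalized anywhere:
within each treatment line (a new regimen resets the baseline), detection
occurs when the series exceeds its running nadir by a relative threshold
(default +30%) for at least two consecutive draws; the reported day is
the interpolated crossing between the last sub-threshold and first
supra-threshold draw, which removes most of the draw-spacing
quantization. Lead time is the gap from detection to the first PD event
at or after it; radiological and clinical PD are treated identically and
the event type is carried through. All lead times are therefore
*rule-dependent* and are reported together with the rule parameters.

The trajectory generator (`trajectorySpec`) drives a latent burden that
shrinks during each line's response phase (default 70 days at
1.2%/day, a partial response) and regrows exponentially (default
4.5%/day, roughly a 15-day doubling); radiological PD fires when burden
exceeds its line nadir by a factor 1.2. Fc tracks the latent burden
*advanced* by `fc_lead_days` — methylated-template shedding reacting
before imaging — so the programmed lead is structural. Two deliberate
asymmetries deserve note. First, the detection threshold (+30%) and the
PD factor (1.2) differ, so detection corresponds to a slightly later
point on the regrowth curve than PD does; at the default regrowth rate
this costs `log(1.3/1.2)/0.045`, about 1.8 days, of the programmed lead
— visible in simulations as a small negative bias, well inside one
draw interval (7 days). Second, `fc_base` defaults to 0, i.e. Fc is
modeled as the tumor-coupled excess over the patient's own baseline; a
large additive baseline would dilute relative rises and delay
nadir-relative detection, which is a realistic caveat for low-shedding
patients. CEA is burden-coupled for secretors and flat below the normal
limit (5 ng/ml) for non-secretors, reproducing the patient whose CEA
never moved while Fc and imaging agreed.

`trendConcordance` compares two curves by the Spearman correlation of
their first differences on the common daily grid; a flat curve has no
trend and concordance 0 by convention.

## Numerical choices and degenerate inputs

* All randomness flows from explicit seeds; identical spec + seed gives
  byte-identical cohorts and trajectories.
* Thresholds are closed bounds; boundary ratios (exactly 0.05 or 0.01)
  are positive.
* Logistic convergence: IRLS to a deviance change below 1e-8 or 100
  iterations; coefficients beyond ±15 on these bounded score scales are
  treated as a separation signal.
* Degenerate cases are errors, not silent results: single-class labels,
  constant scores in a DeLong comparison, zero-variance region-1 ratios,
  fewer than three points to smooth, trajectories without a PD event.

## What passes and what that does (not) show

The synthetic generators emulate the *statistical structure* of the
study: group sizes, concentration and recovery summaries, stage-wise
tissue positivity, duplicate-run correlation, and trajectories whose Fc
leads imaging progression by a programmed number of days. They do not
model clonal hematopoiesis, incomplete bisulfite conversion, sequencing
or NGS reads, inter-locus biological heterogeneity beyond a single
shared factor, or real inter-patient kinetics. Green tests therefore
demonstrate that the *methods* are implemented faithfully and recover
known truths under the documented conditions — not that the biomarker
performs as reported in any new patient population.

Problem sizes in the test suite were chosen to keep the default run
quick while leaving Monte-Carlo error well below the asserted margins:
200 replicate cohorts for calibration and AUC consistency checks, 500
for logistic-coefficient recovery, 30–40 seeds per programmed lead for
monitoring, 10,000 draws for permutation and bootstrap oracles.

## Reproducing the cohort-level numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates, from
scratch, the mean recovery-score AUC, the mean recovered logistic
coefficient for the methylation score, and the grand means of CRC-group
ccfDNA concentration and two-time recovery score, writing them as JSON.
See the README for a worked example.
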