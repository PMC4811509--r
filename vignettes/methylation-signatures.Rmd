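---
title: "Selecting robust DNA-methylation signatures: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting robust DNA-methylation signatures: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methsig)
```

# The problem

Neuroblastoma outcome is highly heterogeneous: some high-risk patients die
of disease (HR-DOD) while others with apparently similar tumours survive
(HR-SURV), and low-risk patients almost always survive (LR-SURV). Aberrant
promoter hypermethylation is a candidate prognostic marker class. The
workflow implemented here has two arms:

1. **Discovery** — rank differentially methylated regions (DMRs) between
   prognostic groups from MBD-seq style count data, where read density over
   a region proxies its methylation level.
2. **Signature building** — given a panel of methylation-specific PCR (MSP)
   assays designed against top-ranked DMRs, binarise each (sample, assay)
   measurement into methylated / unmethylated / missing, and select a
   multimarker signature whose per-sample *methylation score* (the
   percentage of methylated assays) predicts outcome, trained on one cohort
   and validated frozen on a second.

# DMR ranking

## Regions and counting

Promoter regions span −1500 bp to +500 bp around each transcription start
site in transcript orientation; on the minus strand the window is mirrored
in genomic coordinates (−500/+1500), preserving the upstream/downstream
asymmetry. Genome-wide scans use 5 kb windows advancing by 2.5 kb, so every
interior base is covered by exactly two windows and a differential region
is never lost to an unlucky window boundary. A fragment increments every
region it overlaps by at least one base; a fragment in the overlap zone of
two windows therefore counts twice, which is intended — the windows are
analysed independently. Coordinates are 0-based half-open (BED convention)
throughout, converted only at I/O boundaries.

## Normalisation and test

Per-sample size factors are median-of-ratios: the median over regions
(restricted to regions with positive counts in every sample) of the log
ratio between a sample's count and the region's geometric mean, then
exponentiated. This matches the standard count-normalisation convention
used by negative-binomial differential tools.

The differential test is deliberately a *reduced-fidelity* negative-binomial
test: normalised group means are compared by a Wald-type statistic whose
variance follows `var = mu + phi * mu^2`, with one pooled method-of-moments
dispersion `phi` (the median across regions of the per-region
moment estimate, floored at 0 so the Poisson model is the boundary case).
The statistic is referred to a t distribution with `nA + nB − 2` degrees of
freedom rather than a normal: with moment-estimated variances at 20 samples
per group this gives a visibly better-calibrated null (Kolmogorov–Smirnov
distance to uniform ≈ 0.03 at 1000 null regions in the test suite). The
pseudocount in the fold change is 0.5.

Regions are ranked by the pi score, `pi = −ln(p) × log2FC`, which rewards
joint strength of significance and effect; its sign equals the sign of the
fold change, so only regions hypermethylated toward the poor-outcome group
(positive fold change) enter the ranking. A region is excluded as a
background artifact when the same test run on the matched input
(non-enriched) data is itself significant at `background_alpha = 0.05` with
a same-direction fold change — such shifts are visible without methylation
enrichment (e.g. copy-number differences) and would otherwise be falsely
called DMRs. Ties in pi are broken lexicographically by region id so
rankings are reproducible.

# MSP calling

A measurement is called methylated only if it amplifies no later than
`delta_cq_max = 2` cycles after the fully methylated positive control, with
melting temperature within `delta_tm_max = 1` °C, amplicon size within
`size_tol_bp = 5` bp and melt-peak height at least `min_height_frac = 0.1`
of the control's. These tolerances are plausible qPCR values and are
config-exposed; the downstream framework consumes only the ternary matrix,
so their exact values matter less than their consistency within a study.
Failures that can be evaluated yield *unmethylated*; *missing* is reserved
for measurements that amplify but cannot be evaluated (e.g. absent melt
data), keeping the binary dataset dense. Tightening any tolerance can only
move calls toward unmethylated (a property-tested monotonicity).

The ACTB assay contains no CpG sites and must amplify in every sample with
adequate bisulfite-converted DNA; its melting-temperature criterion is
skipped (Tm carries no methylation information for a CpG-free amplicon).
Samples failing ACTB are removed before any analysis.

The methylation score of a sample over an assay set is
`100 × n_methylated / n_non_missing`; missing calls drop out of the
denominator, and a sample with no evaluable call in the set gets an
undefined score and is excluded (and counted) rather than imputed.

# The signature-selection framework

Step 1 builds candidates: each of TPR, TNR and BAC ranks the assays by
their single-assay performance against outcome (event = positive class,
methylated call = positive prediction), a percentile cutoff from
{0, 5, …, 100}% selects the top `ceiling(p/100 × n)` assays (minimum one,
so the 0% cutoff selects the single best assay rather than an empty set),
and a methylation-score cutoff from the same grid converts scores to risk
predictions — *strictly above* the cutoff is high-risk, so a 0% cutoff
does not automatically flag every sample with any methylation. The full
grid is 3 × 21 × 21 = 1323 candidates.

Step 2 evaluates each candidate by

* **BAC** of its risk predictions against outcome;
* **event-percentage score** `1 − |p̂_high − p_event|`, the simplest [0, 1]
  score maximised exactly when the predicted high-risk fraction equals the
  event fraction — this anchors the score cutoff against pathological
  all-high or all-low solutions;
* **mean Jaccard stability**: 100 subcohorts of `floor(n/2)` samples are
  drawn *without replacement* (a subcohort "containing half of the
  samples", not a with-replacement resample), the assay set is reselected
  with the candidate's metric and cutoff on each, and the Jaccard
  similarity `|A∩B|/|A∪B|` to the full-cohort set is averaged. A subcohort
  that loses an outcome class is redrawn (bounded retries). The same 100
  subcohorts are shared by all candidates, which is both faster and a
  paired comparison.

Step 3 combines the three values in a weighted harmonic mean
`Σw / Σ(w_i/x_i)` with equal default weights; any zero component zeroes
the combination, so a degenerate candidate can never win on the strength
of the other two components. The weighted harmonic mean lies between the
smallest component and the arithmetic mean, punishing imbalance. Ties are
broken toward the larger assay set, then the lower score cutoff, then
enumeration order — fully deterministic given the seed.

The whole fit is a pure function of (data, grid, weights, seed): the
bootstrap draws come from a dedicated substream derived from the seed, so
reruns are bit-identical and stages can be rerun independently.

```{r example}
cfg    <- sim_config(n_patients = 132, seed = 1)
cohort <- simulate_survival(simulate_cohort(cfg), cfg)
panel  <- simulate_calls(cohort, cfg)
fit    <- meth_signature(panel$calls, cohort$os_event, seed = 1)
summary(fit)
plot(fit)
```

# Validation statistics

Kaplan–Meier survival uses Greenwood variance with log(−log S) 95%
intervals — a standard transform choice; the untransformed ("plain")
interval can escape [0, 1] near the boundaries where five-year survival
estimates live. Log-rank tests, logistic regression (Wald intervals,
`exp(coef ± 1.96 SE)`) and Fisher's exact test (two-sided by
probability-mass ordering) back the per-assay and per-signature association
tables. Raw p-values are reported without multiple-testing correction,
matching common practice for confirmatory marker panels; users scanning
many assays should apply `p.adjust` themselves. Power for a two-sided
log-rank test uses the Freedman normal approximation with the hazard ratio
derived from the two groups' horizon survival probabilities; with equal
survival it degenerates to the size of the test (alpha).

# What the synthetic cohorts emulate — and what they do not

The generator reproduces the *structure* the analysis assumes: three
prognostic groups with configurable mixing proportions (default
0.40/0.30/0.30 LR-SURV/HR-SURV/HR-DOD, giving event fractions comparable
to a mixed-risk neuroblastoma cohort); covariates (MYCN amplification,
INSS stage, age at diagnosis) enriched in the high-risk groups; a 78-assay
panel of which 20 are truly prognostic with methylation probability 0.6 in
HR-DOD patients versus 0.1 otherwise and 0.1 background everywhere; 2%
per-call missingness, completely at random; and negative-binomial region
counts with log-normal base means, per-sample depth factors and planted
fold changes, plus background-artifact regions that shift in both enriched
and input data.

Survival is exponential with group-specific hazards (death hazard
5e-4/day for HR-DOD, i.e. median ≈ 3.8 years; follow-up hazard 3e-4/day
for survivors, median ≈ 6.3 years; 20% of survivors additionally censored
early at a uniform point of their follow-up). Event-free survival is the
minimum of a latent relapse time and overall survival, with group-specific
relapse hazards at least the death hazard for deceased patients, so
EFS ≤ OS always holds and every death is an EFS event. The generator ties
events to group membership deterministically (only HR-DOD patients die of
disease), which is why predicted low-risk groups in clean runs show 100%
five-year survival — real cohorts have late deaths in every stratum.

Important features of real data that are *not* modelled: assay-to-assay
correlation (planted calls are independent given the group), batch and
plate effects, informative missingness (ACTB failures correlate with DNA
quality, which correlates with tumour content), competing mortality, cure
fractions, and covariate-outcome confounding beyond group membership.
Passing tests therefore demonstrate correctness of the machinery and
recoverability of planted signal under the stated noise model — not
clinical performance.

One generator subtlety matters for cross-cohort work: the identity of the
prognostic assays is a property of the assay *panel*, not of a cohort.
`simulate_calls()` accepts the panel of a previous call so that training
and validation cohorts share their prognostic assays, as they would in
reality; simulating the two cohorts with independently drawn panels
destroys transferability by construction.

# The permutation null

A natural specification of a selection-bias check — permute the training
outcomes, rerun the framework, and expect validation BAC near 0.5 — is
*wrong* for data with planted signal: a signature selected under permuted
labels still contains genuinely prognostic assays (any sizeable random
subset of the panel does), and the event-percentage score anchors the
score cutoff near the event fraction, so validation BAC against the true
validation outcomes stays well above 0.5 (≈ 0.76 under the default
conditions). The meaningful null breaks the outcome link in **both**
cohorts: the permuted-training signature is evaluated against permuted
validation outcomes. That distribution is centred at 0.5, which is what
the test suite and the acceptance script verify.

# Problem sizes and runtime choices

The test suite and acceptance script use the study-scale conditions
directly where they are cheap — cohort pairs of 132 and 177 patients, 78
assays, the full 1323-candidate grid, 100 bootstraps (50 simulated cohort
pairs in the recovery check; 30 permutation runs at 25 bootstraps; 20 DMR
runs of 1000 regions × 40 samples; 500 replicates for the log-rank
type-I-error check; 10^4 permutations for the log-rank reference). A full
fit takes well under a second, so these sizes keep the whole suite around
a minute while leaving the study conditions untouched.

# Known limitations

* The differential count test is intentionally simplified (single pooled
  dispersion, no shrinkage, no GLM offsets); it is calibrated and powerful
  on the generator's data but is not a substitute for a production
  differential-methylation tool on real MBD-seq data.
* The exact MSP calling tolerances and the harmonic-mean weights of the
  original framework are not public; the defaults here are declared
  stand-ins, config-exposed, and the conclusions of the test suite do not
  depend on their exact values.
* Logistic fits reject separated designs outright rather than switching to
  penalised likelihood; with small strata and strong markers, collapse
  categories or use Firth regression from a dedicated package.
* Fisher tests on tables larger than 16 cells fall back to seeded
  Monte-Carlo (≥ 10^5 tables) with a reported standard error.
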