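---
title: "Methods: quantifying and classifying ctDNA dynamics under ICI therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and classifying ctDNA dynamics under ICI therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnadyn)
```

## The measurement model

Droplet digital PCR partitions a reaction into roughly 10,000–20,000
droplets and reports, per fluorescence channel, how many droplets contain
at least one template molecule. Template molecules distribute across
droplets approximately as a Poisson process, so a droplet is positive with
probability $1 - e^{-\lambda}$ where $\lambda$ is the mean occupancy.
`poisson_concentration()` inverts the observed positive fraction $k/N$:

$$\lambda = -\ln(1 - k/N), \qquad c = \lambda / V_d \;\text{copies/µL},$$

with $V_d$ the droplet volume. $V_d$ is an instrument constant that vendors
do not report per run; the default, 0.85 nL, is the nominal droplet volume
of the QX200 class of instruments and is overridable in
`assay_constants()`. The correction matters only at high occupancy: below
1% positive droplets it differs from the naive $k/N$ estimate by less than
1% relative, which is why the low-level samples that dominate ctDNA
monitoring are insensitive to it.

Copies per mL plasma back-calculate through the workflow volumes
($c \times V_{rxn} \times V_{elu}/V_{in} / V_{pl}$; defaults 20 µL
reaction, 52 µL eluate, 13 µL loaded, 2 mL plasma). Only $V_{rxn}$,
$V_{elu}$ and $V_{pl}$ are anchored to the laboratory workflow the package
models; $V_{in}$ is workflow-dependent and is therefore an explicit
configuration value. All four enter as a single multiplicative factor, so
mis-specifying them rescales copies/mL uniformly — and the dynamics
classification below is deliberately scale-free, which makes the clinical
calls robust to this entire block of constants.

Replicate wells are pooled by summing droplet counts before the Poisson
correction (`merge_wells()`), the standard merged-well practice; it
weights wells by their droplet counts and has lower variance than
averaging per-well concentrations.

## Positivity, negativity, and the third state

A sample is called positive at ≥ 3 mutant droplets. Negativity additionally
requires ≥ 330 informative (mutant-positive + wildtype-positive) droplets:
claiming "no mutant DNA" is only meaningful if enough amplifiable template
was present. At exactly 3 of 330 droplets the Poisson-corrected mutant
fraction is $-\ln(1 - 3/330) = 0.91\%$, so the rule guarantees an
analytical sensitivity below 1% (`limit_of_detection()`). "Informative"
counts each droplet once; the input schema carries no double-positive
column, so no double-counting question arises in practice.

Samples that fail both rules — fewer than 3 mutant droplets but too few
informative droplets — are **invalid**, an explicit third state. Treating
them as negative would misclassify low-input samples as mutation-free;
every downstream stage excludes them as missing instead, and reports the
exclusion.

## Classifying dynamics

Repeated measurements of the same sample with these assays scatter with a
coefficient of variation of about 30%. A change between baseline and
follow-up is therefore only interpreted when it exceeds 30% in relative
terms; `classify_dynamics()` labels patients decreasing / stable /
increasing / negative. Numerical conventions, each of which the tests pin
down:

* a change of exactly ±30% is **stable** (the stable band is closed,
  decrease/increase are strict inequalities);
* baseline-positive, follow-up-negative is a **decrease** with relative
  change −1: a valid negative call bounds the follow-up level below the
  detection limit, which is itself below any meaningful baseline;
* baseline-negative, follow-up-positive is classified **increasing** (new
  detection). This situation is genuinely ambiguous — such patients could
  also be set aside — so the choice is a documented convention and
  `negative_baseline = "exclude"` switches to exclusion;
* classification depends only on ratios, never on absolute copies/mL, so
  any uniform rescaling of the quantification (e.g. different volume
  constants) leaves every call unchanged.

More stringent thresholds (40%, 50%) are evaluated with
`threshold_sweep()`; since a larger relative change is strictly harder to
achieve, the decreasing set can only shrink as the threshold grows, a
property the tests check on randomly generated cohorts.

Two binary conventions feed the survival comparisons (`group_binary()`):
decrease vs no-decrease with plasma-negative patients excluded (their
dynamics are unobservable), and the same with negatives folded into
no-decrease, used within PD-L1 TPS strata where the negative stratum alone
would be too small.

## Survival analysis

PFS and OS are weeks from the start of ICI to progression/death, censored
at last follow-up. Kaplan–Meier estimation, the Mantel–Cox log-rank test
and univariate Cox models are computed by the `survival` package; the
wrappers fix the conventions (median = earliest time the curve reaches
0.5, reported as "not reached" when the curve ends above it; Breslow tie
handling, adequate for weekly-resolution times; Wald 95% intervals;
monotone likelihoods flagged as non-converged rather than raised). The
test suite cross-checks these against independent brute-force oracles: a
hand product-limit estimator, direct evaluation of the Mantel–Cox sums, a
5,000-draw permutation null for the log-rank p, and full enumeration for
the Mann–Whitney p at small n. The permutation comparison allows for both
Monte-Carlo noise and the chi-square reference's small-sample
approximation error (up to a few hundredths at 8 patients per group),
which no implementation using the standard chi-square reference can avoid.

Durable clinical benefit is at least stable disease lasting ≥ 26 weeks
(six months), evaluated at the PFS landmark. Patients censored before 26
weeks are **indeterminate** and are excluded from DCB-rate denominators;
counting them either way would bias the rate, and the rates' difference is
assessed by a rank test on the benefit indicator. Two-sided tests and a
0.05 significance level are used throughout.

## Candidate follow-up timepoints

Responders often show a transient ctDNA spike in the first one to two
weeks of ICI — tumor DNA released by early cell death — before levels
fall. A follow-up drawn during the spike misclassifies responders as
increasing, which is why the follow-up sits at 4–6 weeks.
`separation_by_timepoint()` quantifies this: for each candidate week it
aligns each patient's nearest observation (within ±1 week by default; ties
break toward the earlier sample; the alignment rule is a package
convention, as irregular sampling admits no canonical one), classifies the
change from baseline, and scores the week by the sum of the responder
decrease fraction and the non-responder non-decrease fraction. "Responder"
defaults to the durable-benefit flag; RECIST best response is an
alternative framing the caller can supply instead.

## The synthetic cohort

`simulate_cohort()` generates every input the pipeline consumes, with one
deterministic seed governing all levels. Its defaults are fixed study
conditions, not tuning knobs:

* archetype mix CR 5% / PR 20% / SD 14% / PD 30% / plasma-negative 31% —
  the negative fraction matches the ~31% of patients whose tissue mutation
  is not recoverable in plasma; CR+PR+SD are set so that roughly 39% of
  patients achieve durable benefit;
* baseline copies/mL lognormal (meanlog $\ln 100$, sdlog 1.5) — advanced
  disease spans roughly 1–10,000 copies/mL over ~3 orders of magnitude,
  and under the default detection floor only a few percent of
  plasma-positive patients fall below it at baseline;
* kinetics $L(w) = L_0 \, r^w$ with decay $r = 0.45$/week (CR, clearing
  below the detection floor within weeks) and $0.70$/week (PR), flat for
  SD, growth $1.2$/week for PD; a ×2 spike multiplier at week ≤ 1 in 70%
  of responders (the amplitude is a placeholder — no quantitative spike
  height is established — but any value above 1.3 produces the
  spike-masking phenomenon);
* every observation carries lognormal noise with CV 0.30, the assay's
  technical variance; droplet counts add binomial sampling noise on top;
* PFS exponential with group medians (weeks) CR 85, PR 43, SD 6, PD 6,
  negative 12; OS = PFS + an exponential remainder targeting medians 150,
  125, 29, 29, 60 — anchored on the reported decrease vs no-decrease
  medians (43 vs 6 PFS, 125 vs 29 OS), with the negative group
  intermediate; administrative censoring at week 260 (~5 years of
  follow-up);
* PD-L1 TPS drawn as 34% / 17% / 35% / 14% (<1% / 1–49% / ≥50% /
  unavailable), independently of dynamics, reflecting the observed
  independence of the two markers.

The generator reproduces the statistical *structure* of real monitoring
data, not its full messiness: no clonal-hematopoiesis false positives, no
pre-analytical batch effects, no informative censoring, no
dynamics-dependent sampling dropout, and independence of TPS from outcome
beyond the archetype medians. Passing end-to-end tests therefore
demonstrates that the pipeline recovers planted structure through its own
measurement model — not that the clinical effect sizes would replicate in
any particular patient population.

## Problem sizes and determinism

The test suite runs the end-to-end recovery at 200 patients × 100 seeds —
checking that the decrease group's estimated median PFS exceeds the
no-decrease group's in ≥ 95 runs, the log-rank p is below 0.05 in ≥ 90,
and the recommended follow-up week falls in {4, 6} in ≥ 95 — and the
quantification-recovery property at 200 replicate wells per concentration
across three concentrations spanning 1–1000 copies/mL plasma. These sizes
give the binomial pass-count bounds comfortable margins while keeping the
whole suite around two minutes. All randomness flows through explicit
seeds; identical seeds reproduce every table byte-identically.

## Known limitations

Single-target monitoring is blind when the tissue mutation is not shed
into plasma (~31% of patients at baseline here); the package therefore
keeps "negative" as a first-class stratum rather than discarding those
patients. Confidence intervals on individual concentrations are not
computed (the clinical decisions use only the thresholded change), no
copackaging correction is applied to the two channels (counts are low in
plasma work, making the correction negligible), and multivariable or
time-varying survival models are out of scope.
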