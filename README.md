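# ctdnadyn

Tumor-informed monitoring of treatment response from circulating tumor DNA
(ctDNA), for advanced lung adenocarcinoma patients on immune checkpoint
inhibitors (ICI). A driver mutation found in the pretreatment tissue biopsy
is tracked in plasma by droplet digital PCR (ddPCR) at baseline (t0) and at
the 4–6-week follow-up (t1), before the first radiological evaluation; the
direction of the change in mutant ctDNA is then used as an early proxy of
durable clinical benefit, progression-free survival (PFS) and overall
survival (OS). The package is aimed at translational researchers and
biostatisticians who have vendor-gated droplet counts and a clinical
follow-up table and want the full analysis — quantification, dynamics
classification, survival stratification, cross-platform concordance,
follow-up-timepoint evaluation — as composable, pipe-friendly functions.

## The method

**Quantification.** A ddPCR reaction partitions the template into
10,000–20,000 droplets. With `k` of `N` droplets positive in a channel, the
mean template occupancy per droplet is Poisson-corrected,

λ = −ln(1 − k/N),  concentration = λ / V_d  (copies/µL of reaction),

with V_d the droplet volume (default 0.85 nL). Copies per mL plasma
back-calculates through the workflow volumes, c × V_rxn × (V_elu/V_in) /
V_pl, and the variant allele frequency is the mutant fraction of total
template. A sample is **positive** when ≥ 3 mutant droplets are detected,
**negative** when < 3 mutant droplets are seen among ≥ 330 informative
(mutant + wildtype) droplets — which caps the analytical sensitivity below
1% (−ln(1 − 3/330) ≈ 0.91%) — and **invalid** otherwise.

**Dynamics.** The assay's ~30% technical coefficient of variation sets the
minimum meaningful change: between t0 and t1 each patient is classified
**decreasing** (> 30% fewer copies), **increasing** (> 30% more),
**stable** (|change| ≤ 30%), or **negative** (mutation undetected in plasma
at both timepoints); 40% and 50% thresholds are available as a sweep.

**Endpoints.** Kaplan–Meier curves, log-rank tests and univariate Cox
hazard ratios (Breslow ties) compare PFS/OS across the four categories,
across decrease vs no-decrease (negatives excluded), and within PD-L1
tumor proportion score (TPS) strata (≥ 1% vs < 1%, negatives folded into
no-decrease). Durable clinical benefit (DCB) is at least stable disease
lasting ≥ 26 weeks.

A synthetic-data module generates droplet-level and cohort-level inputs
with the statistical structure the analysis assumes (lognormal baseline
burden, kinetic archetypes with an early responder spike, ~31%
plasma-negative patients, 30% technical CV, group-dependent exponential
survival, the cohort TPS mix), so every stage can be exercised and tested
without patient data.

## Worked example

```r
library(ctdnadyn)

cohort <- simulate_cohort(100, seed = 1)          # synthetic inputs
quant  <- quantify_wells(cohort$droplets)         # droplet counts -> copies/mL
calls  <- classify_dynamics(quant, threshold = 0.30)
report <- endpoint_report(cohort$clinical, calls)
report
#> ctDNA dynamics survival endpoint report
#>   patients analysed: 100
#>   DCB landmark: 26 weeks
#>
#> Decrease vs no-decrease (plasma-negative excluded):
#> # A tibble: 2 × 4
#>   group           n n_events median_weeks
#>   <chr>       <int>    <int>        <dbl>
#> 1 decrease       30       30        44.7
#> 2 no_decrease    43       43         6.34
#>   PFS log-rank p = 7.18e-09
#>   PFS HR (decrease vs no_decrease) = 0.16 [0.08-0.32]
```

Thirty of the 100 synthetic patients show a > 30% ctDNA decrease at t1;
their median PFS (44.7 weeks) is roughly sevenfold that of the no-decrease
arm (6.3 weeks), with a hazard ratio well below 1 — the planted
responder/non-responder structure, recovered end to end from simulated
droplet counts. `glance(report)` condenses the comparison to one row
(including DCB rates per arm: 0.63 vs 0.00 here), `tidy(report)` returns
every stratum as a tibble, and `autoplot(report)` draws the KM curves.
Candidate follow-up weeks are compared with
`separation_by_timepoint(cohort$series, ...)`, which on this cohort ranks
weeks 4–6 far above weeks 1–2 (the early spike masks the decrease), and
cross-platform agreement is summarised by
`platform_concordance()` / `cohens_kappa()` / `pearson_r2()`.

A thin command-line wrapper over the same functions is included at
`inst/cli/ctdna_monitor.R` (subcommands `simulate`, `quantify`, `classify`,
`survival`).

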