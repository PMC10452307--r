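# cortexmr

Two-sample Mendelian randomization (MR) for GWAS summary statistics,
built around a concrete study design: do genetically proxied sleep traits
(morningness, ease of getting up, insomnia, long sleep, short sleep)
causally influence cortical anatomy — the surface area (SA) and thickness
(TH) of the 34 Desikan–Killiany regions? That is a 5 × 68 grid of
exposure–outcome analyses, each one a complete two-sample MR with
instrument selection, allele harmonization, five estimators and a
sensitivity suite. The package is for analysts who have per-SNP summary
statistics (effect allele, frequency, beta, SE, p, N) for an exposure and
an outcome from non-overlapping cohorts and want the whole pipeline —
plus a synthetic-data generator with known ground truth so every stage
can be validated without any external download.

## What it computes

For harmonized SNP effects (exposure γ̂ⱼ ± σₓⱼ, outcome Γ̂ⱼ ± σᵧⱼ), with
ratio estimates θⱼ = Γ̂ⱼ/γ̂ⱼ and weights wⱼ = γ̂ⱼ²/σᵧⱼ²:

- **Wald ratio** — θⱼ with delta-method SE (first or second order).
- **IVW** — β̂ = Σwⱼθⱼ / Σwⱼ, the weighted regression of Γ̂ on γ̂ through
  the origin; multiplicative random-effects SE scaled by
  max{1, √(Q/(J−1))}.
- **MR-Egger** — weighted regression with a free intercept; the intercept
  tests directional pleiotropy (t, J−2 df).
- **Weighted median** — consistent when valid instruments carry ≥ 50% of
  the weight; parametric-bootstrap SE.
- **Simple & weighted mode** — kernel-density mode of the θⱼ, bandwidth
  0.9·min(sd, mad)·J^(−1/5).

Sensitivity: Cochran's Q, Egger intercept test, leave-one-out IVW,
funnel/forest tables, and MR-PRESSO (global RSS test, per-SNP outlier
test with Bonferroni, outlier-corrected estimate and distortion test,
5000 simulations by default). Instrument selection: p < 5×10⁻⁸,
MAF > 1%, greedy LD clumping (r² < 0.001, 10,000 kb), confounder
exclusion lists, F > 10. The grid layer applies the study's
multiple-testing tiers (Bonferroni 0.05/340 = 1.47×10⁻⁴, stronger
suggestive < 0.01, suggestive < 0.05).

## Worked example

Simulate a study-scale dataset with a true causal effect of 0.3, select
instruments, harmonize and run everything:

```r
library(cortexmr)

sim <- simulate_pair(scenario_preset("causal", seed = 42))
rep <- select_instruments(sim$exposure, sim$ld)
rep
#> Instrument report: 50 SNPs selected (mean F = 103.6)

set  <- harmonize(rep$table, sim$outcome)   # drops palindromic SNPs
ests <- run_all_estimators(set, list(seed = 1, n_boot = 1000))
ests[, c("method", "beta", "se", "ci_low", "ci_high", "pval", "n_snp")]
#>                          method  beta     se  ci_low ci_high     pval n_snp
#> ivw                         ivw 0.301 0.0424  0.2180   0.384 1.20e-12    37
#> mr_egger               mr_egger 0.155 0.1638 -0.1780   0.487 3.52e-01    37
#> weighted_median weighted_median 0.312 0.0596  0.1953   0.429 1.62e-07    37
#> simple_mode         simple_mode 0.349 0.1303  0.0934   0.604 7.44e-03    37
#> weighted_mode     weighted_mode 0.355 0.1210  0.1179   0.592 3.34e-03    37

sensitivity_report(set, list(run_presso = TRUE, n_sim = 5000, seed = 2))
#> Cochran's Q = 33.52 (df 36, p = 0.587); Egger intercept = 0.004337 (p = 0.362)
#> MR-PRESSO: RSS = 35.42, global p = 0.5767 (5000 simulations)
#> Outliers: none
```

The IVW estimate recovers the true effect (0.30, 95% CI 0.22–0.38); 13 of
the 50 instruments were palindromic and dropped during harmonization
(hence 37 SNPs); no heterogeneity, pleiotropy or outliers are detected —
as it should be for a clean simulated dataset. MR-Egger is noisier, as
expected: its slope spends statistical power on the free intercept.

A published results table can be audited for internal consistency
(recovering the SE from the printed CI and recomputing the p):

```r
audit <- check_printed_consistency(
  read.delim(table1_path(), colClasses = c(printed_p = "character")))
sum(audit$match)   # 11 of 16 rows reproduce at printed precision
```

There is also a command-line front end (`inst/cli/mrtool`) with
subcommands `simulate`, `harmonize`, `select`, `mr`, `sensitivity`,
`grid` and `check-table`; see `?mr_cli`.

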