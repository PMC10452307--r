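---
title: "Two-sample Mendelian randomization in cortexmr: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization in cortexmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexmr)
```

## The design being implemented

`cortexmr` implements the two-sample Mendelian randomization (MR) design
used to ask whether genetically proxied sleep traits (morningness, ease of
getting up, insomnia, long sleep, short sleep) causally influence cortical
anatomy — the surface area (SA) and thickness (TH) of the 34
Desikan–Killiany regions, giving a 5 × 68 = 340-cell analysis grid. Genetic
variants serve as instrumental variables for the exposure under the three
classical assumptions: they associate with the exposure (relevance), share
no confounder with the outcome (exchangeability), and affect the outcome
only through the exposure (exclusion restriction). Because exposure and
outcome effects come from non-overlapping GWAS cohorts, only per-SNP
summary statistics are needed: for SNP $j$, the exposure effect
$\hat\gamma_j$ with standard error $\sigma_{xj}$ and the outcome effect
$\hat\Gamma_j$ with standard error $\sigma_{yj}$, all expressed for the
same effect allele.

## Instrument selection

`select_instruments()` applies, in order: genome-wide significance
($p < 5\times10^{-8}$, strict), minor-allele frequency
($\min(p, 1-p) > 0.01$), greedy LD clumping ($r^2 < 0.001$ within
10,000 kb, lowest p kept, ties broken by chromosome, position, then SNP
id so the result is independent of row order), removal of SNPs named on a
static confounder exclusion list (standing in for an interactive
phenotype-database lookup), and an instrument-strength gate $F > 10$. Two
F formulas are provided: the squared z-score $(\beta/\mathrm{se})^2$
(default) and the variance-explained form via
$R^2$; they agree closely at GWAS sample sizes. LD information is supplied
as a long-format pair table rather than computed from genotypes — real
reference panels are out of scope, and the synthetic generator emits a
matching table. An in-window pair with no recorded $r^2$ is treated as
independent by default (`missing_ld_policy`), since an omitted pair in a
sparse table usually means "below reporting threshold".

## Harmonization

`harmonize()` intersects the two tables by SNP id (both study sources use
rsIDs; positional matching is deliberately not attempted) and aligns each
outcome record to the exposure's effect allele, resolving swapped alleles
(beta negated, frequency complemented) and strand complements. Palindromic
SNPs (A/T, C/G) cannot be oriented from alleles alone; the default
`drop_all` removes them, matching the conservative reading of the study
protocol, while `drop_intermediate_freq` keeps those whose frequencies on
*both* sides are far from 0.5 (tolerance 0.08) and orients them by
frequency agreement. Requiring both sides to be informative is slightly
stricter than common practice but avoids orienting a SNP on one
uninformative frequency. Every intersected SNP ends up either in the
harmonized set or in the exclusion log — nothing is silently dropped.

## Estimators

With ratio estimates $\theta_j = \hat\Gamma_j/\hat\gamma_j$ and IVW
weights $w_j = \hat\gamma_j^2/\sigma_{yj}^2$:

- **Wald ratio** (single SNP): $\theta_j$, first-order SE
  $\sigma_{yj}/|\hat\gamma_j|$ (default) or the second-order delta
  expansion including the exposure-side variance.
- **IVW**: $\hat\beta = \sum w_j\theta_j / \sum w_j$, identical to the WLS
  slope of $\hat\Gamma$ on $\hat\gamma$ through the origin with weights
  $1/\sigma_y^2$. The default is the multiplicative random-effects
  variant: the fixed-effect SE $(\sum w_j)^{-1/2}$ is scaled by
  $\max\{1, \sqrt{Q/(J-1)}\}$, which responds continuously to
  heterogeneity instead of requiring a discrete fixed-vs-random trigger,
  and never undercuts the fixed-effect SE.
- **MR-Egger**: WLS of $\hat\Gamma$ on $\hat\gamma$ with a free intercept
  after orienting every $\hat\gamma_j \ge 0$; the intercept estimates the
  mean directional pleiotropy, the slope is the causal estimate.
  Inference uses $t_{J-2}$ for both coefficients (the WLS convention), so
  Egger's CI uses the t quantile while the other estimators use normal z —
  this is why the CI-to-p round-trip identity is only exact for the
  z-based methods.
- **Weighted median**: the ordered $\theta_{(j)}$ interpolated against
  cumulative weight midpoints $p_j = \sum_{i\le j} w'_i - w'_j/2$ at
  $p = 0.5$; consistent while valid instruments carry at least half the
  weight.
- **Simple / weighted mode**: the mode of the normal-kernel density of the
  $\theta_j$ (unit or IVW weights), bandwidth
  $h = \varphi\,0.9\,\min(\mathrm{sd}, \mathrm{mad})\,J^{-1/5}$, evaluated
  on a 512-point grid over $[\min\theta - 3h, \max\theta + 3h]$. When all
  ratios coincide the bandwidth degenerates and the heaviest atom is
  returned.

Median and mode SEs come from a parametric bootstrap (default 1000
replicates) redrawing $\hat\gamma_j^* \sim N(\hat\gamma_j, \sigma_{xj})$
and $\hat\Gamma_j^* \sim N(\hat\Gamma_j, \sigma_{yj})$; a seed is
mandatory so results are reproducible — there is no wall-clock seeding
anywhere in the package. `run_all_estimators()` dispatches on set size:
one SNP gives the Wald ratio, two give per-SNP Wald ratios plus IVW,
three or more give the full five-method battery.

## Sensitivity suite

Cochran's $Q = \sum w_j(\theta_j - \hat\beta_{IVW})^2$ against
$\chi^2_{J-1}$; the Egger intercept test; leave-one-out IVW; funnel and
forest plot tables; and MR-PRESSO. MR-PRESSO computes, per SNP, the
leave-one-out IVW slope and a weighted squared residual, compares the
observed residual sum of squares with `n_sim` datasets simulated under the
no-pleiotropy model (outcome effects redrawn about their leave-one-out
predictions; exposure effects held fixed, matching the reference
procedure's outcome-side focus), and flags SNPs whose per-SNP empirical p
falls below $\alpha/J$. Empirical p-values use the
$(1 + \#\{\cdot\})/(n_{sim}+1)$ convention so they are never zero; the
smallest achievable global p with the study's $n_{sim} = 5000$ is
$1/5001$. When outliers exist, the outlier-corrected IVW estimate is
reported together with a distortion test whose null distribution removes
equally many randomly chosen non-outlier SNPs — the reference
publication leaves this bootstrap under-specified, so the convention is
documented here and in the function help.

## The analysis grid and multiple testing

`run_grid()` crosses every exposure with every outcome, selecting
instruments once per exposure (cached — verified bit-identical to
uncached runs), harmonizing per cell, and classifying each cell's IVW
p-value into the study's tiers: Bonferroni-significant
($p < 0.05/340 = 1.47\times10^{-4}$), suggestive of a stronger
association ($p < 0.01$), suggestive ($p < 0.05$), or null. The other
estimators enter as a direction-of-effect concordance flag, mirroring how
the study reports them. Cells with too few instruments are reported with
a failure status rather than dropped, keeping the grid cardinality at
exactly 340.

`check_printed_consistency()` audits a published table of (beta, 95% CI,
p): it recovers $\mathrm{se} = (\mathrm{CI_{high}} -
\mathrm{CI_{low}})/(2\,\Phi^{-1}(0.975))$ — the full-precision quantile,
not 1.96 — recomputes the two-sided normal p and compares at the printed
precision. On the bundled 16-row transcription of the study's headline
IVW table, 11 rows reproduce exactly; three thickness rows miss by
±0.001, which is exactly the information lost by printing a CI of
magnitude ~0.1 to two decimals; and two rows (insomnia/parahippocampal,
morningness/frontal pole) are genuinely inconsistent with their printed
CIs (recomputed 0.007 vs printed 0.037, and 0.016 vs 0.025). The audit
flags these rather than forcing agreement.

## The synthetic generator

`simulate_pair()` emulates the statistical structure the analysis
assumes, not any particular cohort. Traits are standardized, so sampling
SEs follow $1/\sqrt{2p(1-p)n}$; defaults use exposure/outcome cohort
sizes of 350,000 and 50,000, the order of the sleep and cortical GWAS.
Instrument effects are sized to a target per-SNP F (default 60, jittered
±20%, random allele-coding sign). Direct (pleiotropic) effects
$\alpha_j$ are drawn in the canonical exposure-increasing-allele
orientation — the frame in which "directional" pleiotropy is meaningful —
and the allele-coding sign is applied to $\gamma_j$ and $\alpha_j$
jointly, exactly what relabeling an effect allele does. On top of the
effect model the generator lays allele pairs (15% palindromic by
default), outcome-side allele swaps (20%) that harmonization must undo,
optional equicorrelated LD blocks emitting a matching LD table, and null
decoy SNPs. Everything is reproducible bit-for-bit from the mandatory
seed. P-values are floored at $10^{-300}$ to avoid underflow for very
strong instruments.

Two presets deserve their calibration rationale:

- `directional_pleiotropy` uses strong instruments (per-SNP F ≈ 1000).
  MR-Egger's intercept is only unbiased under the NOME condition
  ($I^2_{GX}$ near 1); at F ≈ 60 a small part of the causal slope
  demonstrably dilutes into the intercept. The preset exists to test
  intercept recovery of $\mu = 0.05$, so it is placed in the regime where
  that recovery is an estimator property rather than a bias trade-off.
- `majority_invalid` gives 40% of ten very strong instruments a one-sided
  direct effect sized so IVW is biased by roughly half the true effect.
  The weighted median's bias under one-sided contamination is about one
  per-ratio standard error even with full separation (the median of a
  60/40 mixture sits at the valid cluster's 83rd percentile), so the
  per-ratio noise must be small — hence F ≈ 1000 and an outcome cohort as
  large as the exposure cohort. This is a stress regime, not a realistic
  cohort.

What the generator does **not** emulate: genome-wide LD structure, binary
traits on the log-odds scale (z-based p-values are used throughout,
sufficient for threshold gates), sample overlap, population
stratification, or the real effect-size distributions of the sleep GWAS —
so passing tests demonstrate correctness of the statistical machinery
under the assumed model, not reproduction of the study's empirical
results, which require the external consortium data.

## Numerical and testing choices

- CI multiplier $\Phi^{-1}(0.975) = 1.959964\ldots$ everywhere.
- Greedy clump tie-break: ascending (chromosome, position, SNP id).
- Degenerate inputs: zero exposure effect is a domain error for the Wald
  ratio; identical ratios give $Q = 0$, $p = 1$; degenerate mode bandwidth
  returns the heaviest atom; a single SNP is allowed in IVW only behind an
  explicit `allow_single` flag (where it equals the Wald ratio).
- Monte-Carlo problem sizes in the test suite are scaled for a desk run:
  1000 replicates for the IVW type-I error check (band 0.03–0.07), 500
  for Egger intercept recovery (within 2 MC SEs), 200 for the
  weighted-median contamination regime, 150 for coverage (band widened at
  the top to 0.99 to absorb binomial noise at that replicate count), and
  a 2 × 8 grid over 15 seeds for the ranking property. The full 340-cell
  grid is exercised once per run.
- Oracles in the tests are independent of the implementation: `lm()`
  normal equations for IVW/Egger, `stats::approx` for the weighted
  median, an $O(n^2)$ transcription of the clumping rule, and brute-force
  fine grids for the mode.

## Known limitations

Proxy-SNP substitution, Steiger filtering, multivariable and bidirectional
MR, $I^2$ statistics and radial MR are deliberately out of scope. The
Egger intercept inherits its weak-instrument dilution; the package does
not compute $I^2_{GX}$ to warn about it. The printed-table audit can only
ever be as sharp as the published rounding.
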