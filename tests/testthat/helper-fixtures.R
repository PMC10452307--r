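# Shared fixture builders and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small, valid exposure-style GWAS data frame (all non-palindromic,
# aligned alleles).
make_gwas_df <- function(n = 5, beta = NULL, se = 0.01, pval = NULL,
                         eaf = 0.3, n_sample = 300000, chrom = NULL,
                         pos = NULL, snp_id = NULL) {
  beta <- beta %||% seq(0.05, by = 0.01, length.out = n)
  se <- rep_len(se, n)
  data.frame(
    snp_id = snp_id %||% sprintf("rs%03d", seq_len(n)),
    chrom = chrom %||% rep("1", n),
    pos = pos %||% seq(1e6, by = 5e7, length.out = n),
    effect_allele = rep("A", n),
    other_allele = rep("G", n),
    eaf = rep_len(eaf, n),
    beta = beta,
    se = se,
    pval = pval %||% (2 * pnorm(-abs(beta / se))),
    n = rep_len(n_sample, n),
    stringsAsFactors = FALSE
  )
}

make_gwas <- function(...) gwas_table(make_gwas_df(...))

# Harmonized set straight from ratio estimates: gamma = 1 per SNP so the
# ratios equal Gamma, with controllable outcome SEs.
set_from_ratios <- function(theta, sigma_y = 0.1, gamma = 1,
                            sigma_x = 0.01) {
  j <- length(theta)
  gamma <- rep_len(gamma, j)
  harmonized_set(gamma, rep_len(sigma_x, j), theta * gamma,
                 rep_len(sigma_y, j))
}

# Independent weighted-least-squares oracle via lm(); the package
# implements its estimators from explicit sums, lm() is R's own fitter.
wls_oracle <- function(x, y, w, intercept = TRUE) {
  fit <- if (intercept) stats::lm(y ~ x, weights = w)
  else stats::lm(y ~ x + 0, weights = w)
  summary(fit)$coefficients
}

# Brute-force greedy clumping oracle: direct transcription of the rule,
# O(n^2) over a long-format r2 table.
clump_oracle <- function(df, ld_pairs, r2_threshold, window_kb) {
  ord <- order(df$pval, df$chrom, df$pos, df$snp_id)
  kept <- character()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      krow <- df[df$snp_id == k, ]
      if (krow$chrom != df$chrom[i]) next
      if (abs(krow$pos - df$pos[i]) > window_kb * 1000) next
      hit <- ld_pairs[(ld_pairs$snp_a == k & ld_pairs$snp_b == df$snp_id[i]) |
                        (ld_pairs$snp_b == k & ld_pairs$snp_a == df$snp_id[i]), ]
      r2 <- if (nrow(hit) > 0) hit$r2[1] else 0
      if (r2 >= r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, df$snp_id[i])
  }
  kept
}

# Exhaustive weighted-median oracle: evaluate the piecewise-linear
# interpolation of ordered ratios against cumulative weight midpoints with
# stats::approx instead of the package's own arithmetic.
weighted_median_oracle <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  stats::approx(p, theta, xout = 0.5)$y
}

# Harmonize a simulated pair and return the set (drop-all palindromes).
sim_harmonized <- function(cfg) {
  sim <- simulate_pair(cfg)
  harmonize(sim$exposure, sim$outcome)
}
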