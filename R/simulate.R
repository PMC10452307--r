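# Synthetic paired GWAS summary statistics with known ground truth.

#' Configuration for the synthetic summary-statistics generator
#'
#' Defines the data-generating model behind [simulate_pair()]. Traits are
#' treated as standardized, so a SNP with effect-allele frequency `p`
#' genotyped in `n` individuals has sampling standard error
#' `1 / sqrt(2 p (1 - p) n)` — the classical approximation for a
#' standardized continuous trait. Instrument effects are scaled to a target
#' per-SNP F-statistic, mirroring cohorts where genome-wide-significant
#' sleep-trait SNPs are strong instruments.
#'
#' @param n_snps Number of instrument SNPs (true exposure effects).
#' @param n_exposure,n_outcome GWAS sample sizes; defaults (350,000 and
#'   50,000) are of the order of the UK-Biobank sleep GWAS and the ENIGMA
#'   cortical GWAS.
#' @param beta_causal True causal effect of exposure on outcome.
#' @param pleiotropy List describing the direct (horizontal) SNP-outcome
#'   effects `alpha_j`: `list(type = "none")`,
#'   `list(type = "balanced", tau = ...)` (`alpha ~ N(0, tau)`), or
#'   `list(type = "directional", mu = ..., tau = ...)`
#'   (`alpha ~ N(mu, tau)`).
#' @param invalid_fraction Fraction of instruments receiving the pleiotropy
#'   draw (the rest have `alpha = 0`); 1 applies it to all.
#' @param inside_violation If `TRUE`, adds a component of `alpha`
#'   proportional to the SNP's exposure effect, correlating instrument
#'   strength with pleiotropy and breaking the InSIDE assumption.
#' @param f_target Expected per-SNP F-statistic for instruments (default
#'   60).
#' @param maf_range Range the minor-allele frequency is drawn from.
#' @param palindromic_fraction Fraction of SNPs given A/T or C/G allele
#'   pairs.
#' @param flip_fraction Fraction of outcome rows written with swapped
#'   effect/other alleles (beta negated, frequency complemented), which
#'   harmonization must undo.
#' @param n_null_snps Number of decoy SNPs with zero exposure effect.
#' @param ld_blocks Optional `list(n_blocks, snps_per_block, r2_within)`
#'   turning the first `n_blocks * snps_per_block` instruments into
#'   equicorrelated position-clustered LD blocks (emitted via the returned
#'   [ld_info()]).
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 50, n_exposure = 350000, n_outcome = 50000,
                       beta_causal = 0, pleiotropy = list(type = "none"),
                       invalid_fraction = 1, inside_violation = FALSE,
                       f_target = 60, maf_range = c(0.05, 0.45),
                       palindromic_fraction = 0.15, flip_fraction = 0.2,
                       n_null_snps = 0, ld_blocks = NULL, seed) {
  if (missing(seed) || !is_scalar_number(seed)) {
    config_error("sim_config requires an integer seed")
  }
  if (length(maf_range) != 2L || maf_range[1] >= maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    config_error("maf_range must be an increasing interval within (0, 0.5]")
  }
  fracs <- c(palindromic_fraction, flip_fraction, invalid_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    config_error("fractions must lie in [0, 1]")
  }
  if (n_exposure < 2 || n_outcome < 2) {
    config_error("sample sizes must be at least 2")
  }
  if (!pleiotropy$type %in% c("none", "balanced", "directional")) {
    config_error("pleiotropy$type must be none, balanced or directional")
  }
  structure(list(n_snps = n_snps, n_exposure = n_exposure,
                 n_outcome = n_outcome, beta_causal = beta_causal,
                 pleiotropy = pleiotropy,
                 invalid_fraction = invalid_fraction,
                 inside_violation = inside_violation, f_target = f_target,
                 maf_range = maf_range,
                 palindromic_fraction = palindromic_fraction,
                 flip_fraction = flip_fraction, n_null_snps = n_null_snps,
                 ld_blocks = ld_blocks, seed = as.integer(seed)),
            class = "sim_config")
}

NON_PALINDROMIC_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                                  "G", "A", "G", "T", "T", "C", "T", "G"),
                                ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)

#' Simulate a paired exposure/outcome GWAS with known truth
#'
#' Generates, per SNP j: a minor-allele frequency from `maf_range`;
#' sampling SEs `sigma_x = 1/sqrt(2 maf (1-maf) n_exposure)` and
#' `sigma_y` analogously; a true exposure effect with magnitude
#' `sqrt(f_target) * sigma_x` (jittered by 20%) and random sign, so the
#' expected per-SNP F is close to `f_target`; a pleiotropy effect `alpha_j`
#' per the configured regime; the true outcome effect
#' `Gamma_j = beta_causal * gamma_j + alpha_j`; and observed effects
#' `gamma_hat ~ N(gamma, sigma_x)`, `Gamma_hat ~ N(Gamma, sigma_y)` with
#' two-sided z p-values. Decoy SNPs have `gamma = 0`. Allele pairs,
#' palindromic SNPs, outcome-side allele swaps and (optional) LD blocks are
#' laid on top so the selection and harmonization stages have real work to
#' do. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` ([gwas_table()]s), `ld`
#'   (an [ld_info()]), and `truth` (class `sim_truth`: `beta_causal`,
#'   per-SNP data frame with `true_gamma`, `true_alpha`, `is_instrument`,
#'   and the config echo).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_inst <- cfg$n_snps
  n_tot <- n_inst + cfg$n_null_snps
  if (n_tot < 1L) config_error("need at least one SNP")

  withr::with_seed(cfg$seed, {
    maf <- stats::runif(n_tot, cfg$maf_range[1], cfg$maf_range[2])
    eaf <- ifelse(stats::runif(n_tot) < 0.5, maf, 1 - maf)
    sigma_x <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exposure)
    sigma_y <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_outcome)

    is_inst <- c(rep(TRUE, n_inst), rep(FALSE, cfg$n_null_snps))
    # effects are generated in the canonical orientation (exposure-increasing
    # allele), where "directional" pleiotropy is defined; a random allele
    # coding sign is then applied to both gamma and alpha together, which is
    # what relabeling a SNP's effect allele does
    gamma_mag <- numeric(n_tot)
    gamma_mag[is_inst] <- sqrt(cfg$f_target) * sigma_x[is_inst] *
      stats::runif(n_inst, 0.8, 1.2)
    coding <- sample(c(-1, 1), n_tot, replace = TRUE)

    alpha_canon <- numeric(n_tot)
    if (cfg$pleiotropy$type != "none" && n_inst > 0L) {
      n_invalid <- round(cfg$invalid_fraction * n_inst)
      invalid <- seq_len(n_inst) %in% sample(seq_len(n_inst), n_invalid)
      mu <- if (cfg$pleiotropy$type == "directional") cfg$pleiotropy$mu else 0
      tau <- cfg$pleiotropy$tau %||% 0
      alpha_canon[which(is_inst)[invalid]] <-
        stats::rnorm(sum(invalid), mu, tau)
    }
    if (isTRUE(cfg$inside_violation)) {
      alpha_canon[is_inst] <- alpha_canon[is_inst] + 0.3 * gamma_mag[is_inst]
    }

    gamma <- coding * gamma_mag
    alpha <- coding * alpha_canon
    Gamma <- cfg$beta_causal * gamma + alpha
    gamma_hat <- stats::rnorm(n_tot, gamma, sigma_x)
    Gamma_hat <- stats::rnorm(n_tot, Gamma, sigma_y)

    snp_id <- sprintf("rs%07d", seq_len(n_tot))
    # alleles: palindromic_fraction of SNPs get strand-ambiguous pairs
    pal <- stats::runif(n_tot) < cfg$palindromic_fraction
    pair_idx_np <- sample(nrow(NON_PALINDROMIC_PAIRS), n_tot, replace = TRUE)
    pair_idx_p <- sample(nrow(PALINDROMIC_PAIRS), n_tot, replace = TRUE)
    ea <- ifelse(pal, PALINDROMIC_PAIRS[pair_idx_p, 1],
                 NON_PALINDROMIC_PAIRS[pair_idx_np, 1])
    oa <- ifelse(pal, PALINDROMIC_PAIRS[pair_idx_p, 2],
                 NON_PALINDROMIC_PAIRS[pair_idx_np, 2])

    # positions: LD-block members clustered within 50 kb, everything else
    # spread far apart (> the clumping window) across chromosomes
    chrom <- character(n_tot)
    pos <- numeric(n_tot)
    ld_pairs <- data.frame(snp_a = character(), snp_b = character(),
                           r2 = numeric(), stringsAsFactors = FALSE)
    blocked <- 0L
    if (!is.null(cfg$ld_blocks)) {
      nb <- cfg$ld_blocks$n_blocks
      spb <- cfg$ld_blocks$snps_per_block
      blocked <- nb * spb
      if (blocked > n_inst) config_error("ld_blocks exceed instrument count")
      for (b in seq_len(nb)) {
        idx <- ((b - 1L) * spb + 1L):(b * spb)
        chrom[idx] <- as.character((b - 1L) %% 22L + 1L)
        pos[idx] <- 1e6 * (1 + (b - 1L) %/% 22L) * 40 +
          seq_len(spb) * 5000
        combs <- utils::combn(idx, 2)
        ld_pairs <- rbind(ld_pairs, data.frame(
          snp_a = snp_id[combs[1, ]], snp_b = snp_id[combs[2, ]],
          r2 = cfg$ld_blocks$r2_within, stringsAsFactors = FALSE))
      }
    }
    free <- seq_len(n_tot) > blocked
    n_free <- sum(free)
    if (n_free > 0L) {
      chrom[free] <- as.character(seq_len(n_free) %% 22L + 1L)
      pos[free] <- 5e8 + (seq_len(n_free) %/% 22L + 1L) * 2e7
    }

    exposure_df <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = gamma_hat, se = sigma_x,
      # floor against underflow for very strong associations
      pval = pmax(2 * stats::pnorm(-abs(gamma_hat / sigma_x)), 1e-300),
      n = cfg$n_exposure, stringsAsFactors = FALSE)

    flip <- stats::runif(n_tot) < cfg$flip_fraction
    outcome_df <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = ifelse(flip, oa, ea),
      other_allele = ifelse(flip, ea, oa),
      eaf = ifelse(flip, 1 - eaf, eaf),
      beta = ifelse(flip, -Gamma_hat, Gamma_hat), se = sigma_y,
      pval = pmax(2 * stats::pnorm(-abs(Gamma_hat / sigma_y)), 1e-300),
      n = cfg$n_outcome, stringsAsFactors = FALSE)
  })

  truth <- structure(list(
    beta_causal = cfg$beta_causal,
    per_snp = data.frame(snp_id = snp_id, true_gamma = gamma,
                         true_alpha = alpha, is_instrument = is_inst,
                         stringsAsFactors = FALSE),
    config = cfg), class = "sim_truth")

  list(
    exposure = gwas_table(exposure_df, trait_label = "sim_exposure",
                          source_label = "simulate_pair"),
    outcome = gwas_table(outcome_df, trait_label = "sim_outcome",
                         source_label = "simulate_pair"),
    ld = ld_info(ld_pairs, data.frame(snp_id = snp_id, chrom = chrom,
                                      pos = pos, stringsAsFactors = FALSE)),
    truth = truth
  )
}

#' Shift one SNP's outcome effect by a fixed pleiotropic offset
#'
#' Fixture builder for outlier-detection tests: adds `offset` to the named
#' SNP's outcome beta, leaving everything else untouched.
#'
#' @param outcome A [gwas_table()].
#' @param snp_id SNP to perturb (must be present).
#' @param offset Amount added to its beta.
#' @return The modified [gwas_table()].
#' @export
inject_outlier <- function(outcome, snp_id, offset) {
  i <- match(snp_id, outcome$snp_id)
  if (is.na(i)) data_error(sprintf("SNP '%s' not present in outcome", snp_id))
  outcome$beta[i] <- outcome$beta[i] + offset
  outcome
}

#' Named simulation scenario presets
#'
#' Documented parameter bundles for the standard test scenarios:
#' \describe{
#'   \item{`null`}{no causal effect, no pleiotropy, 50 strong instruments.}
#'   \item{`causal`}{true effect 0.3, 50 strong instruments (per-SNP F
#'     around 100), no pleiotropy.}
#'   \item{`balanced_pleiotropy`}{true effect 0.1, zero-mean direct effects
#'     (`tau = 0.003`) on all instruments.}
#'   \item{`directional_pleiotropy`}{true effect 0.1, direct effects with
#'     mean 0.05 (`tau = 0.01`) on all instruments — the regime the Egger
#'     intercept estimates. Instruments are strong (per-SNP F around 1000)
#'     so the NOME condition behind Egger regression holds; with weaker
#'     instruments part of the causal slope dilutes into the intercept.}
#'   \item{`weak_instruments`}{target per-SNP F of 5, to exercise the
#'     F > 10 gate.}
#'   \item{`majority_invalid`}{10 very strong instruments (per-SNP F around
#'     1000, outcome cohort as large as the exposure cohort, so per-ratio
#'     noise is small) of which 40% carry a one-sided direct effect
#'     (`mu = 0.04`) sized to bias IVW by roughly half the true effect —
#'     the regime where the weighted median stays consistent while IVW
#'     fails.}
#' }
#'
#' @param name Preset name.
#' @param seed Integer seed stored in the returned config.
#' @return A [sim_config()].
#' @export
scenario_preset <- function(name = c("null", "causal", "balanced_pleiotropy",
                                     "directional_pleiotropy",
                                     "weak_instruments", "majority_invalid"),
                            seed) {
  name <- tryCatch(match.arg(name),
                   error = function(e) config_error(
                     sprintf("unknown scenario preset '%s'", name[1])))
  switch(name,
    null = sim_config(n_snps = 50, beta_causal = 0, seed = seed),
    causal = sim_config(n_snps = 50, beta_causal = 0.3, f_target = 100,
                        seed = seed),
    balanced_pleiotropy = sim_config(
      n_snps = 50, beta_causal = 0.1,
      pleiotropy = list(type = "balanced", tau = 0.003), seed = seed),
    directional_pleiotropy = sim_config(
      n_snps = 50, beta_causal = 0.1, f_target = 1000,
      pleiotropy = list(type = "directional", mu = 0.05, tau = 0.01),
      seed = seed),
    weak_instruments = sim_config(n_snps = 30, beta_causal = 0.1,
                                  f_target = 5, seed = seed),
    majority_invalid = sim_config(
      n_snps = 10, beta_causal = 0.3, f_target = 1000,
      n_outcome = 350000,
      pleiotropy = list(type = "directional", mu = 0.04, tau = 0),
      invalid_fraction = 0.4, seed = seed)
  )
}
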