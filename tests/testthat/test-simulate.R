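test_that("sim_config validates its inputs", {
  expect_error(sim_config(), class = "mr_config_error")  # seed mandatory
  expect_error(sim_config(maf_range = c(0.4, 0.2), seed = 1),
               class = "mr_config_error")
  expect_error(sim_config(flip_fraction = 2, seed = 1),
               class = "mr_config_error")
  expect_error(sim_config(pleiotropy = list(type = "huge"), seed = 1),
               class = "mr_config_error")
  cfg <- sim_config(seed = 5)
  expect_s3_class(cfg, "sim_config")
})

test_that("the same seed reproduces the simulation bit for bit", {
  cfg <- sim_config(n_snps = 30, palindromic_fraction = 0.3,
                    flip_fraction = 0.5, n_null_snps = 10, seed = 123)
  a <- simulate_pair(cfg)
  b <- simulate_pair(cfg)
  expect_identical(as.data.frame(a$exposure), as.data.frame(b$exposure))
  expect_identical(as.data.frame(a$outcome), as.data.frame(b$outcome))
  expect_identical(a$truth$per_snp, b$truth$per_snp)
})

test_that("generator structure matches its configuration", {
  cfg <- sim_config(n_snps = 40, n_null_snps = 20,
                    palindromic_fraction = 0.5, flip_fraction = 0.5,
                    pleiotropy = list(type = "directional", mu = 0.05,
                                      tau = 0.01),
                    seed = 77)
  sim <- simulate_pair(cfg)
  expect_equal(nrow(sim$exposure), 60)
  expect_equal(nrow(sim$outcome), 60)
  truth <- sim$truth$per_snp
  expect_equal(sum(truth$is_instrument), 40)
  expect_true(all(truth$true_gamma[!truth$is_instrument] == 0))
  expect_true(all(truth$true_alpha[!truth$is_instrument] == 0))
  # sigma follows the standardized-trait formula
  e <- as.data.frame(sim$exposure)
  maf <- pmin(e$eaf, 1 - e$eaf)
  expect_equal(e$se, 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exposure))
  # flips are visible as swapped alleles with negated beta
  flipped <- sim$outcome$effect_allele != sim$exposure$effect_allele
  pal <- is_palindromic(sim$exposure$effect_allele,
                        sim$exposure$other_allele)
  expect_gt(sum(flipped & !pal), 0)
  # pleiotropy regime: none => all alpha zero
  sim0 <- simulate_pair(sim_config(n_snps = 10, seed = 3))
  expect_true(all(sim0$truth$per_snp$true_alpha == 0))
})

test_that("exposure sampling noise is calibrated to sigma_x", {
  # replicate the same SNP set many times, varying only the noise draws
  base <- sim_config(n_snps = 200, seed = 50)
  sim <- simulate_pair(base)
  z <- (sim$exposure$beta - sim$truth$per_snp$true_gamma) / sim$exposure$se
  expect_lt(abs(sd(z) - 1), 0.12)
  expect_lt(abs(mean(z)), 0.15)
})

test_that("a full flip run harmonizes back to the unflipped analysis", {
  cfg0 <- sim_config(n_snps = 25, flip_fraction = 0, seed = 9)
  cfg1 <- sim_config(n_snps = 25, flip_fraction = 1, seed = 9)
  s0 <- harmonize(simulate_pair(cfg0)$exposure, simulate_pair(cfg0)$outcome)
  s1 <- harmonize(simulate_pair(cfg1)$exposure, simulate_pair(cfg1)$outcome)
  expect_identical(s0$gamma_hat, s1$gamma_hat)
  expect_identical(s0$Gamma_hat, s1$Gamma_hat)
  expect_identical(ivw(s0)$beta, ivw(s1)$beta)
})

test_that("the generator is unbiased under the null", {
  betas <- vapply(1:300, function(r) {
    set <- sim_harmonized(sim_config(n_snps = 50, beta_causal = 0,
                                     seed = 9000 + r))
    ivw(set)$beta
  }, numeric(1))
  expect_lt(abs(mean(betas)), 0.01)
})

test_that("presets encode their documented regimes", {
  expect_equal(scenario_preset("null", seed = 1)$beta_causal, 0)
  expect_equal(scenario_preset("causal", seed = 1)$beta_causal, 0.3)
  mi <- scenario_preset("majority_invalid", seed = 1)
  expect_equal(mi$invalid_fraction, 0.4)
  truth <- simulate_pair(mi)$truth$per_snp
  expect_equal(mean(truth$true_alpha != 0), 0.4)
  expect_error(scenario_preset("nope", seed = 1),
               class = "mr_config_error")
})

test_that("weak-instrument preset lands in the intended F range", {
  fs <- vapply(1:40, function(r) {
    sim <- simulate_pair(scenario_preset("weak_instruments",
                                         seed = 400 + r))
    mean((sim$exposure$beta / sim$exposure$se)^2)
  }, numeric(1))
  expect_gte(mean(fs), 3)
  expect_lte(mean(fs), 8)
})

test_that("directional pleiotropy shifts the Egger intercept to mu", {
  ints <- vapply(1:500, function(r) {
    set <- sim_harmonized(scenario_preset("directional_pleiotropy",
                                          seed = 20000 + r))
    mr_egger(set)$extra$egger_intercept
  }, numeric(1))
  mc_se <- sd(ints) / sqrt(length(ints))
  expect_lt(abs(mean(ints) - 0.05), 2 * mc_se + 1e-4)
})

test_that("IVW holds its nominal type-I error under the null", {
  rejections <- vapply(1:1000, function(r) {
    set <- sim_harmonized(sim_config(n_snps = 30, beta_causal = 0,
                                     palindromic_fraction = 0,
                                     flip_fraction = 0, seed = 30000 + r))
    ivw(set)$pval < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("weighted median resists 40% invalid instruments where IVW fails", {
  wm <- numeric(200)
  iv <- numeric(200)
  for (r in 1:200) {
    set <- sim_harmonized(scenario_preset("majority_invalid",
                                          seed = 40000 + r))
    wm[r] <- weighted_median(set, n_boot = 0, seed = 1)$beta
    iv[r] <- ivw(set)$beta
  }
  expect_lt(abs(median(wm) - 0.3), 0.05)
  expect_gt(abs(mean(iv) - 0.3), 0.1)
})

test_that("estimator coverage is near nominal with strong instruments", {
  n_rep <- 150
  cover <- matrix(NA, n_rep, 3,
                  dimnames = list(NULL, c("ivw", "mr_egger",
                                          "weighted_median")))
  for (r in seq_len(n_rep)) {
    set <- sim_harmonized(sim_config(n_snps = 30, beta_causal = 0.3,
                                     f_target = 100, seed = 60000 + r))
    est_i <- ivw(set)
    est_e <- mr_egger(set)
    est_m <- weighted_median(set, n_boot = 120, seed = r)
    for (est in list(est_i, est_e, est_m)) {
      cover[r, est$method] <- est$ci_low <= 0.3 && 0.3 <= est$ci_high
    }
  }
  rates <- colMeans(cover)
  expect_true(all(rates >= 0.90 & rates <= 0.99))
})
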