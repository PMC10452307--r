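test_that("Wald ratio matches the delta-method formulas", {
  pair <- harmonized_set(0.05, 0.005, 0.01, 0.004)
  first <- wald_ratio(pair, "first")
  expect_equal(first$beta, 0.2)
  expect_equal(first$se, 0.08)
  second <- wald_ratio(pair, "second")
  expect_equal(second$se, sqrt(0.004^2 / 0.05^2 +
                                 0.01^2 * 0.005^2 / 0.05^4))
  expect_equal(second$se, 0.08246211, tolerance = 1e-6)
  null <- wald_ratio(harmonized_set(0.05, 0.005, 0, 0.004))
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)
  expect_error(wald_ratio(harmonized_set(0, 0.01, 0.01, 0.01)),
               class = "mr_domain_error")
})

test_that("IVW equals the origin-constrained WLS slope and consensus", {
  consensus <- set_from_ratios(c(0.2, 0.2), gamma = c(1, 2))
  expect_equal(ivw(consensus)$beta, 0.2)
  set <- harmonized_set(c(0.1, 0.2, 0.15), rep(0.01, 3),
                        c(0.02, 0.05, 0.03), rep(0.01, 3))
  est <- ivw(set, "fixed")
  oracle <- sum(set$gamma_hat * set$Gamma_hat / set$sigma_y^2) /
    sum(set$gamma_hat^2 / set$sigma_y^2)
  expect_equal(est$beta, oracle)
  lm_fit <- wls_oracle(set$gamma_hat, set$Gamma_hat, 1 / set$sigma_y^2,
                       intercept = FALSE)
  expect_equal(est$beta, unname(lm_fit[1, 1]), tolerance = 1e-12)
  expect_error(ivw(set[1, ]), class = "mr_insufficient_instruments")
  expect_equal(ivw(set[1, ], allow_single = TRUE)$beta,
               wald_ratio(set[1, ])$beta)
})

test_that("random-effects IVW floors the heterogeneity scale at one", {
  homog <- set_from_ratios(c(0.199, 0.2, 0.201), sigma_y = 0.05)
  expect_equal(ivw(homog, "fixed")$se,
               ivw(homog, "multiplicative_random")$se)
  heterog <- set_from_ratios(c(-0.5, 0.2, 0.9), sigma_y = 0.05)
  expect_gt(ivw(heterog, "multiplicative_random")$se,
            ivw(heterog, "fixed")$se)
  q <- cochran_q(heterog)
  expect_equal(ivw(heterog, "multiplicative_random")$se,
               ivw(heterog, "fixed")$se * sqrt(q$q / q$q_df))
})

test_that("MR-Egger recovers exact affine data and matches the WLS oracle", {
  g <- c(0.05, 0.08, 0.12, 0.15, 0.2)
  set <- harmonized_set(g, rep(0.01, 5), 0.1 + 0.5 * g, rep(0.02, 5))
  est <- mr_egger(set)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  expect_equal(est$extra$egger_intercept, 0.1, tolerance = 1e-12)
  # noisy fixture against lm()
  withr::with_seed(5, {
    g2 <- runif(5, 0.02, 0.2)
    G2 <- 0.05 + 0.3 * g2 + rnorm(5, 0, 0.02)
    sy <- runif(5, 0.01, 0.05)
  })
  set2 <- harmonized_set(g2, rep(0.01, 5), G2, sy)
  est2 <- mr_egger(set2)
  lm_fit <- wls_oracle(g2, G2, 1 / sy^2)
  expect_equal(est2$beta, unname(lm_fit["x", "Estimate"]), tolerance = 1e-10)
  expect_equal(est2$se, unname(lm_fit["x", "Std. Error"]), tolerance = 1e-10)
  expect_equal(est2$extra$egger_intercept,
               unname(lm_fit["(Intercept)", "Estimate"]), tolerance = 1e-10)
  expect_equal(est2$extra$intercept_p,
               unname(lm_fit["(Intercept)", "Pr(>|t|)"]), tolerance = 1e-10)
  expect_error(mr_egger(set2[1:2, ]), class = "mr_insufficient_instruments")
})

test_that("Egger orientation makes the fit invariant to allele relabeling", {
  withr::with_seed(8, {
    g <- rnorm(10, 0.05, 0.05)  # mixed signs
    G <- 0.02 + 0.4 * g + rnorm(10, 0, 0.01)
  })
  set <- harmonized_set(g, rep(0.01, 10), G, rep(0.02, 10))
  flip <- rep(c(1, -1), 5)
  set2 <- harmonized_set(g * flip, rep(0.01, 10), G * flip, rep(0.02, 10))
  expect_equal(mr_egger(set)$beta, mr_egger(set2)$beta)
  expect_equal(mr_egger(set)$extra$egger_intercept,
               mr_egger(set2)$extra$egger_intercept)
})

test_that("Egger intercept p is near-uniform when no pleiotropy exists", {
  ps <- vapply(1:500, function(r) {
    set <- sim_harmonized(sim_config(n_snps = 30, beta_causal = 0.2,
                                     flip_fraction = 0,
                                     palindromic_fraction = 0,
                                     seed = 1000 + r))
    mr_egger(set)$extra$intercept_p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("weighted median interpolates the cumulative-weight midpoints", {
  expect_equal(weighted_median(set_from_ratios(c(0.1, 0.2, 0.3)),
                               n_boot = 0, seed = 1)$beta, 0.2)
  # all ratios equal: point estimate is the common ratio, SE shrinks with
  # the noise scale
  same <- set_from_ratios(c(0.25, 0.25, 0.25), sigma_y = 1e-6,
                          sigma_x = 1e-6)
  wm <- weighted_median(same, n_boot = 200, seed = 2)
  expect_equal(wm$beta, 0.25)
  expect_lt(wm$se, 1e-4)
  # exhaustive-interpolation oracle on random small fixtures
  withr::with_seed(99, {
    for (rep in 1:25) {
      j <- sample(3:6, 1)
      theta <- rnorm(j)
      gamma <- runif(j, 0.5, 2)
      sy <- runif(j, 0.1, 1)
      set <- harmonized_set(gamma, rep(0.01, j), theta * gamma, sy)
      w <- gamma^2 / sy^2
      expect_equal(weighted_median(set, n_boot = 0, seed = 1)$beta,
                   weighted_median_oracle(theta, w), tolerance = 1e-12)
    }
  })
  expect_error(weighted_median(set_from_ratios(c(1, 2, 3)), n_boot = 10),
               class = "mr_config_error")  # seed required
})

test_that("mode estimates find the majority cluster", {
  set <- set_from_ratios(c(0.2, 0.2, 0.2, 0.9), sigma_y = 0.05)
  simple <- mode_estimate(set, weighted = FALSE, n_boot = 0, seed = 1)
  expect_lt(abs(simple$beta - 0.2), 0.05)
  # grid-search oracle at much finer resolution (fixture with non-zero mad)
  theta <- c(0.18, 0.2, 0.22, 0.9)
  set_j <- set_from_ratios(theta, sigma_y = 0.05)
  est_j <- mode_estimate(set_j, weighted = FALSE, n_boot = 0, seed = 1)
  h <- 0.9 * min(sd(theta), mad(theta)) * 4^(-1 / 5)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 20000)
  dens <- vapply(grid, function(x) sum(dnorm((x - theta) / h)), numeric(1))
  expect_lt(abs(est_j$beta - grid[which.max(dens)]), 1e-2)
  # point mass and equal-weight agreement
  expect_equal(mode_estimate(set_from_ratios(c(0.3, 0.3, 0.3)),
                             n_boot = 0, seed = 1)$beta, 0.3)
  eq <- set_from_ratios(c(0.1, 0.15, 0.2, 0.6), sigma_y = 0.1)
  expect_equal(mode_estimate(eq, weighted = TRUE, n_boot = 0, seed = 1)$beta,
               mode_estimate(eq, weighted = FALSE, n_boot = 0,
                             seed = 1)$beta)
})

test_that("p_from_beta_ci inverts the normal CI construction", {
  se <- 0.37
  b <- qnorm(0.975) * se
  expect_equal(p_from_beta_ci(b, b - qnorm(0.975) * se,
                              b + qnorm(0.975) * se),
               0.05, tolerance = 1e-10)
  expect_equal(p_from_beta_ci(0, -1, 1), 1)
  expect_error(p_from_beta_ci(1, 2, 2), class = "mr_domain_error")
  # round-trip from an estimate's own CI
  est <- ivw(set_from_ratios(c(0.1, 0.3, 0.25), sigma_y = 0.1))
  expect_equal(p_from_beta_ci(est$beta, est$ci_low, est$ci_high), est$pval,
               tolerance = 1e-12)
})

test_that("estimator battery dispatch follows the set size", {
  one <- set_from_ratios(0.2)
  expect_equal(run_all_estimators(one)$method, "wald_ratio")
  two <- set_from_ratios(c(0.2, 0.3))
  res2 <- run_all_estimators(two)
  expect_equal(res2$method, c("wald_ratio", "wald_ratio", "ivw"))
  five <- set_from_ratios(seq(0.1, 0.5, by = 0.1))
  res5 <- run_all_estimators(five, list(seed = 4, n_boot = 50))
  expect_setequal(res5$method, c("ivw", "mr_egger", "weighted_median",
                                 "simple_mode", "weighted_mode"))
  expect_true(all(res5$n_snp == 5))
  expect_error(run_all_estimators(five), class = "mr_config_error")
  expect_error(run_all_estimators(five[0, ]),
               class = "mr_insufficient_instruments")
  sub <- run_all_estimators(five, list(methods = "ivw"))
  expect_equal(sub$method, "ivw")
})

test_that("estimators are sign- and scale-equivariant", {
  set <- sim_harmonized(scenario_preset("causal", seed = 21))
  cfg <- list(seed = 31, n_boot = 50)
  base <- run_all_estimators(set, cfg)
  neg <- harmonized_set(set$gamma_hat, set$sigma_x, -set$Gamma_hat,
                        set$sigma_y)
  flipped <- run_all_estimators(neg, cfg)
  expect_equal(flipped$beta, -base$beta, tolerance = 1e-10)
  analytic <- base$method %in% c("ivw", "mr_egger")
  expect_equal(flipped$se[analytic], base$se[analytic], tolerance = 1e-10)
  expect_equal(flipped$pval[analytic], base$pval[analytic],
               tolerance = 1e-10)
  # bootstrap SEs mirror only in distribution; same draws, so close
  expect_equal(flipped$se[!analytic], base$se[!analytic], tolerance = 0.5)
  scaled <- harmonized_set(set$gamma_hat, set$sigma_x, 3 * set$Gamma_hat,
                           3 * set$sigma_y)
  res3 <- run_all_estimators(scaled, cfg)
  expect_equal(res3$beta, 3 * base$beta, tolerance = 1e-8)
  expect_equal(res3$se, 3 * base$se, tolerance = 1e-8)
})

test_that("all five estimators recover a strong causal effect", {
  set <- sim_harmonized(scenario_preset("causal", seed = 17))
  res <- run_all_estimators(set, list(seed = 18, n_boot = 200))
  expect_true(all(abs(res$beta - 0.3) < 3 * res$se))
  ivw_row <- res[res$method == "ivw", ]
  expect_lt(abs(ivw_row$beta - 0.3), 0.1)
})
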