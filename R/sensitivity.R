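# Heterogeneity, pleiotropy, influence and outlier diagnostics.

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum_j w_j (theta_j - beta_ivw)^2 with IVW weights
#' `w_j = gamma_hat_j^2 / sigma_y_j^2`, theta_j the per-SNP ratios and
#' beta_ivw the fixed-effect IVW estimate; the p-value is the upper tail of
#' the chi-square distribution with J - 1 degrees of freedom. p < 0.05 is
#' conventionally read as heterogeneity among the instruments.
#'
#' @param set A [harmonized_set()] with at least 2 SNPs.
#' @return List with `q`, `q_df` and `q_pval`.
#' @export
cochran_q <- function(set) {
  check_n_snp(set, 2L, "Cochran's Q")
  w <- ivw_weights(set)
  theta <- ratio_estimates(set)
  beta <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - beta)^2)
  df <- nrow(set) - 1L
  list(q = q, q_df = df, q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimate J times, each time dropping one SNP, to reveal
#' estimates driven by a single instrument. Rows follow the input SNP order.
#'
#' @param set A [harmonized_set()] with at least 3 SNPs.
#' @param config Estimator config passed to [ivw()] (only `ivw_effects` is
#'   used).
#' @return Data frame with one row per dropped SNP: `snp_id`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `n_snp`.
#' @export
leave_one_out <- function(set, config = list()) {
  check_n_snp(set, 3L, "leave-one-out")
  effects <- config$ivw_effects %||% "multiplicative_random"
  rows <- lapply(seq_len(nrow(set)), function(j) {
    est <- ivw(set[-j, , drop = FALSE], effects)
    data.frame(snp_id = set$snp_id[j], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               n_snp = est$n_snp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratio against its precision (inverse first-order SE), the
#' standard visual check for directional pleiotropy: valid instruments
#' scatter symmetrically about the pooled estimate, stored in the
#' `ivw_beta` attribute as the vertical reference line.
#'
#' @param set A [harmonized_set()].
#' @return Data frame `(snp_id, ratio, precision)` with attribute
#'   `ivw_beta`.
#' @export
funnel_data <- function(set) {
  check_n_snp(set, 1L, "funnel data")
  theta <- ratio_estimates(set)
  prec <- abs(set$gamma_hat) / set$sigma_y
  ref <- ivw(set, allow_single = TRUE)$beta
  structure(data.frame(snp_id = set$snp_id, ratio = theta, precision = prec,
                       stringsAsFactors = FALSE),
            ivw_beta = ref)
}

#' Forest-plot data
#'
#' Per-SNP Wald ratio with its 95% CI, plus a final row for the pooled IVW
#' estimate.
#'
#' @param set A [harmonized_set()].
#' @param config Estimator config (only `ivw_effects` is used).
#' @return Data frame `(snp_id, beta, ci_low, ci_high)`.
#' @export
forest_data <- function(set, config = list()) {
  check_n_snp(set, 1L, "forest data")
  theta <- ratio_estimates(set)
  se <- set$sigma_y / abs(set$gamma_hat)
  pooled <- ivw(set, config$ivw_effects %||% "multiplicative_random",
                allow_single = TRUE)
  rbind(
    data.frame(snp_id = set$snp_id, beta = theta,
               ci_low = theta - Z95 * se, ci_high = theta + Z95 * se,
               stringsAsFactors = FALSE),
    data.frame(snp_id = "All (IVW)", beta = pooled$beta,
               ci_low = pooled$ci_low, ci_high = pooled$ci_high,
               stringsAsFactors = FALSE)
  )
}

# Leave-one-out fixed-effect IVW slopes for every SNP, vectorized.
loo_slopes <- function(w, theta) {
  sw <- sum(w)
  swt <- sum(w * theta)
  (swt - w * theta) / (sw - w)
}

#' MR-PRESSO: global heterogeneity, outlier and distortion tests
#'
#' Simulation-based pleiotropy diagnostic. For each SNP j the IVW slope is
#' refit without it, giving the expected outcome effect
#' `theta_(-j) * gamma_hat_j`; the observed residual sum of squares is
#' `RSS_obs = sum_j (Gamma_hat_j - theta_(-j) gamma_hat_j)^2 / sigma_y_j^2`.
#' `n_sim` datasets are simulated under the no-pleiotropy model
#' (`Gamma* ~ N(theta_(-j) gamma_hat_j, sigma_y_j)`, exposure effects held
#' fixed) and the global empirical p is
#' `(1 + #[RSS* >= RSS_obs]) / (n_sim + 1)`. Each SNP's weighted squared
#' residual is compared with its simulated distribution the same way, and
#' SNPs with per-SNP p below `outlier_alpha / J` (Bonferroni over the J
#' SNPs) are flagged as outliers. When outliers exist, the
#' outlier-corrected IVW estimate is computed without them, and a distortion
#' test compares the observed relative slope change against a null
#' distribution built by removing equally many randomly chosen
#' non-outlier SNPs.
#'
#' @param set A [harmonized_set()] with at least 4 SNPs.
#' @param n_sim Number of simulated datasets (study setting 5000).
#' @param outlier_alpha Per-test significance level before the Bonferroni
#'   divisor (default 0.05).
#' @param seed Integer seed (required); results are reproducible given
#'   (`seed`, `n_sim`).
#' @param config Estimator config for the raw/corrected IVW fits.
#' @return Object of class `presso_result`: list with `rss_obs`,
#'   `global_p`, `n_sim`, `outlier_p` (named per-SNP empirical p),
#'   `outliers`, `beta_raw`, `beta_corrected` and `distortion_p` (the last
#'   two `NULL`/`NA` when no outliers are flagged).
#' @export
mr_presso <- function(set, n_sim = 5000, outlier_alpha = 0.05, seed,
                      config = list()) {
  check_n_snp(set, 4L, "MR-PRESSO")
  if (missing(seed)) config_error("mr_presso requires an explicit seed")
  j <- nrow(set)
  w <- ivw_weights(set)
  theta <- ratio_estimates(set)
  effects <- config$ivw_effects %||% "multiplicative_random"

  t_loo <- loo_slopes(w, theta)
  expected <- t_loo * set$gamma_hat
  resid_obs <- (set$Gamma_hat - expected)^2 / set$sigma_y^2
  rss_obs <- sum(resid_obs)

  withr::with_seed(seed, {
    # n_sim x J matrix of simulated outcome effects under no pleiotropy
    g_star <- matrix(stats::rnorm(n_sim * j, mean = rep(expected, each = n_sim),
                                  sd = rep(set$sigma_y, each = n_sim)),
                     nrow = n_sim)
    theta_star <- sweep(g_star, 2, set$gamma_hat, "/")
    # per-simulation leave-one-out slopes (fixed-effect IVW), vectorized
    swt_star <- theta_star %*% w           # n_sim x 1
    t_loo_star <- (matrix(swt_star, n_sim, j) -
                     sweep(theta_star, 2, w, "*")) /
      matrix(sum(w) - w, n_sim, j, byrow = TRUE)
    resid_star <- sweep(g_star - sweep(t_loo_star, 2, set$gamma_hat, "*"),
                        2, set$sigma_y, "/")^2
    rss_star <- rowSums(resid_star)
    global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
    outlier_p <- (1 + colSums(resid_star >=
                                matrix(resid_obs, n_sim, j, byrow = TRUE))) /
      (n_sim + 1)
    names(outlier_p) <- set$snp_id
    outliers <- set$snp_id[outlier_p < outlier_alpha / j]

    beta_raw <- ivw(set, effects)
    beta_corrected <- NULL
    distortion_p <- NA_real_
    if (length(outliers) > 0L && j - length(outliers) >= 2L) {
      keep <- !(set$snp_id %in% outliers)
      beta_corrected <- ivw(set[keep, , drop = FALSE], effects)
      d_obs <- (beta_raw$beta - beta_corrected$beta) /
        abs(beta_corrected$beta)
      non_out <- which(keep)
      k <- length(outliers)
      if (length(non_out) > k) {
        d_null <- vapply(seq_len(n_sim), function(b) {
          drop_idx <- sample(non_out, k)
          bsub <- ivw(set[-drop_idx, , drop = FALSE], "fixed")$beta
          (beta_raw$beta - bsub) / abs(bsub)
        }, numeric(1))
        distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
      }
    }
  })

  structure(list(rss_obs = rss_obs, global_p = global_p, n_sim = n_sim,
                 outlier_p = outlier_p, outliers = outliers,
                 beta_raw = beta_raw, beta_corrected = beta_corrected,
                 distortion_p = distortion_p),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_p, x$n_sim))
  cat(sprintf("Outliers: %s\n",
              if (length(x$outliers)) paste(x$outliers, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Full sensitivity report for a harmonized set
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, the leave-one-out
#' table, and (optionally) MR-PRESSO into one object, the per-cell
#' diagnostic companion to [run_all_estimators()].
#'
#' @param set A [harmonized_set()] with at least 3 SNPs.
#' @param config Named list; honors `ivw_effects`, `run_presso` (default
#'   `FALSE`), `n_sim` (default 5000), `outlier_alpha`, `seed` (required
#'   when `run_presso` is `TRUE`).
#' @return Object of class `sensitivity_report`: list with `q`, `q_df`,
#'   `q_pval`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`, `loo` and `presso` (`NULL` unless requested).
#' @export
sensitivity_report <- function(set, config = list()) {
  check_n_snp(set, 3L, "sensitivity report")
  qres <- cochran_q(set)
  egger <- mr_egger(set)
  loo <- leave_one_out(set, config)
  presso <- NULL
  if (isTRUE(config$run_presso)) {
    if (is.null(config$seed)) {
      config_error("config$seed is required to run MR-PRESSO")
    }
    presso <- mr_presso(set, config$n_sim %||% 5000,
                        config$outlier_alpha %||% 0.05, config$seed, config)
  }
  structure(list(q = qres$q, q_df = qres$q_df, q_pval = qres$q_pval,
                 egger_intercept = egger$extra$egger_intercept,
                 egger_intercept_se = egger$extra$intercept_se,
                 egger_intercept_p = egger$extra$intercept_p,
                 loo = loo, presso = presso),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g (df %d, p = %.3g); Egger intercept = %.4g (p = %.3g)\n",
              x$q, x$q_df, x$q_pval, x$egger_intercept, x$egger_intercept_p))
  if (!is.null(x$presso)) print(x$presso)
  invisible(x)
}
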