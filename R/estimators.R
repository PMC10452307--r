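# Causal-effect estimators on a harmonized SNP set: Wald ratio, IVW,
# MR-Egger, weighted median, and mode-based estimates.

new_mr_estimate <- function(method, beta, se, n_snp, dist = c("z", "t"),
                            df = NULL, extra = list()) {
  dist <- match.arg(dist)
  if (dist == "t") {
    q <- stats::qt(0.975, df)
    pval <- 2 * stats::pt(-abs(beta / se), df)
  } else {
    q <- Z95
    pval <- 2 * stats::pnorm(-abs(beta / se))
  }
  if (is.na(se) || se == 0) pval <- if (is.na(beta) || beta == 0) 1 else NA_real_
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - q * se, ci_high = beta + q * se,
                 pval = pval, n_snp = as.integer(n_snp), extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (95%% CI %.4g to %.4g), se = %.4g, p = %.3g, %d SNP(s)\n",
              x$method, x$beta, x$ci_low, x$ci_high, x$se, x$pval, x$n_snp))
  if (length(x$extra)) utils::str(x$extra)
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             n_snp = x$n_snp,
             egger_intercept = x$extra$egger_intercept %||% NA_real_,
             egger_intercept_se = x$extra$intercept_se %||% NA_real_,
             egger_intercept_p = x$extra$intercept_p %||% NA_real_,
             stringsAsFactors = FALSE)
}

estimates_to_frame <- function(estimates) {
  do.call(rbind, lapply(estimates, as.data.frame))
}

ratio_estimates <- function(set) set$Gamma_hat / set$gamma_hat
ivw_weights <- function(set) set$gamma_hat^2 / set$sigma_y^2

check_n_snp <- function(set, min_n, what) {
  if (nrow(set) < min_n) {
    insufficient_instruments_error(sprintf(
      "%s requires at least %d SNPs, got %d", what, min_n, nrow(set)))
  }
}

#' Wald ratio estimate from a single SNP
#'
#' The per-SNP causal estimate beta = Gamma_hat / gamma_hat with a
#' delta-method standard error: first order `sigma_y / |gamma_hat|`
#' (default), or second order
#' `sqrt(sigma_y^2/gamma_hat^2 + Gamma_hat^2 sigma_x^2 / gamma_hat^4)`,
#' which also propagates the exposure-side uncertainty. Two-sided p from the
#' normal z-score.
#'
#' @param pair A one-row [harmonized_set()] (or list with fields
#'   `gamma_hat`, `sigma_x`, `Gamma_hat`, `sigma_y`).
#' @param se_order `"first"` or `"second"`.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(pair, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  g <- pair$gamma_hat[1]
  sx <- pair$sigma_x[1]
  G <- pair$Gamma_hat[1]
  sy <- pair$sigma_y[1]
  if (is.na(g) || g == 0) {
    domain_error("degenerate instrument: exposure effect is zero")
  }
  beta <- G / g
  se <- if (se_order == "first") sy / abs(g) else
    sqrt(sy^2 / g^2 + G^2 * sx^2 / g^4)
  new_mr_estimate("wald_ratio", beta, se, 1L)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Combines the per-SNP Wald ratios `theta_j = Gamma_hat_j / gamma_hat_j`
#' with weights `w_j = gamma_hat_j^2 / sigma_y_j^2`:
#' `beta = sum(w theta) / sum(w)`, which equals the weighted
#' least-squares slope of the outcome effects on the exposure effects
#' through the origin with weights `1/sigma_y^2`. The fixed-effect standard
#' error is `1/sqrt(sum(w))`; the multiplicative random-effects variant
#' (default) scales it by `max(1, sqrt(Q/(J-1)))` with Q the Cochran
#' heterogeneity statistic, so it never falls below the fixed-effect SE and
#' reduces to it for homogeneous sets. Two-sided p from the normal z-score.
#'
#' @param set A [harmonized_set()] with at least 2 SNPs.
#' @param effects `"multiplicative_random"` (default) or `"fixed"`.
#' @param allow_single Permit the degenerate 1-SNP case, where IVW equals
#'   the first-order Wald ratio.
#' @return An `mr_estimate`.
#' @export
ivw <- function(set, effects = c("multiplicative_random", "fixed"),
                allow_single = FALSE) {
  effects <- match.arg(effects)
  check_n_snp(set, if (allow_single) 1L else 2L, "IVW")
  w <- ivw_weights(set)
  theta <- ratio_estimates(set)
  beta <- sum(w * theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  j <- nrow(set)
  if (effects == "multiplicative_random" && j >= 2L) {
    q <- sum(w * (theta - beta)^2)
    se <- se * max(1, sqrt(q / (j - 1)))
  }
  new_mr_estimate("ivw", beta, se, j)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the outcome effects on the exposure
#' effects with a free intercept, weights `1/sigma_y^2`, after orienting
#' each SNP so its exposure effect is non-negative (both members of a pair
#' are negated together, which leaves the causal slope unchanged). The slope
#' is the pleiotropy-robust causal estimate; a non-zero intercept indicates
#' directional horizontal pleiotropy. Inference for both coefficients uses
#' the t distribution with J - 2 degrees of freedom, the usual WLS
#' convention.
#'
#' @param set A [harmonized_set()] with at least 3 SNPs.
#' @return An `mr_estimate` whose `extra` carries `egger_intercept`,
#'   `intercept_se` and `intercept_p`.
#' @export
mr_egger <- function(set) {
  check_n_snp(set, 3L, "MR-Egger")
  sgn <- ifelse(set$gamma_hat < 0, -1, 1)
  x <- sgn * set$gamma_hat
  y <- sgn * set$Gamma_hat
  w <- 1 / set$sigma_y^2
  j <- length(x)

  xbar <- sum(w * x) / sum(w)
  ybar <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xbar)^2)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  s2 <- sum(w * resid^2) / (j - 2)
  se_slope <- sqrt(s2 / sxx)
  se_int <- sqrt(s2 * (1 / sum(w) + xbar^2 / sxx))
  int_p <- 2 * stats::pt(-abs(intercept / se_int), j - 2)

  new_mr_estimate("mr_egger", slope, se_slope, j, dist = "t", df = j - 2,
                  extra = list(egger_intercept = intercept,
                               intercept_se = se_int,
                               intercept_p = int_p))
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(theta[1])
  jj <- length(theta)
  if (0.5 >= p[jj]) return(theta[jj])
  k <- max(which(p <= 0.5))
  theta[k] + (theta[k + 1] - theta[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

bootstrap_se <- function(set, point_fun, n_boot, seed) {
  if (n_boot <= 0L) return(NA_real_)
  withr::with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      g <- stats::rnorm(nrow(set), set$gamma_hat, set$sigma_x)
      G <- stats::rnorm(nrow(set), set$Gamma_hat, set$sigma_y)
      point_fun(g, G)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted median estimate
#'
#' Orders the per-SNP ratio estimates and takes the weighted median under
#' IVW weights `w_j = gamma_hat_j^2 / sigma_y_j^2`: with normalized weights
#' the cumulative midpoint of SNP j is `p_j = sum_{i<=j} w'_i - w'_j/2`, and
#' the estimate is the linear interpolation of the ordered ratios against
#' `p` evaluated at `p = 0.5`. The estimator is consistent as long as valid
#' instruments carry at least half of the total weight. The standard error
#' is the standard deviation of the estimate over `n_boot` parametric
#' bootstrap replicates that redraw `gamma_hat* ~ N(gamma_hat, sigma_x)` and
#' `Gamma_hat* ~ N(Gamma_hat, sigma_y)`; two-sided p from the normal
#' z-score.
#'
#' @param set A [harmonized_set()] with at least 3 SNPs.
#' @param n_boot Bootstrap replicates for the SE (default 1000); `0` skips
#'   the bootstrap and returns `NA` SE/p (point estimate only).
#' @param seed Integer seed making the bootstrap reproducible (required).
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(set, n_boot = 1000, seed) {
  check_n_snp(set, 3L, "weighted median")
  if (missing(seed)) config_error("weighted_median requires an explicit seed")
  beta <- weighted_median_point(ratio_estimates(set), ivw_weights(set))
  se <- bootstrap_se(set, function(g, G) {
    weighted_median_point(G / g, g^2 / set$sigma_y^2)
  }, n_boot, seed)
  new_mr_estimate("weighted_median", beta, se, nrow(set))
}

mode_point <- function(theta, w, phi, grid_n = 512L) {
  s <- min(stats::sd(theta), stats::mad(theta))
  h <- phi * 0.9 * s * length(theta)^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    # degenerate bandwidth: the kernel limit puts the mode on the atom
    # carrying the most weight
    mass <- tapply(w, theta, sum)
    return(as.numeric(names(mass)[which.max(mass)]))
  }
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = grid_n)
  dens <- colSums(w * stats::dnorm(outer(theta, grid, "-") / h))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' Takes the per-SNP ratio estimates `theta_j` and returns the mode of
#' their normal-kernel density, evaluated on a 512-point grid spanning
#' `[min(theta) - 3h, max(theta) + 3h]`. The bandwidth is
#' `h = phi * 0.9 * min(sd(theta), mad(theta)) * J^(-1/5)` (`mad` with the
#' usual 1/0.6745 consistency constant). The weighted mode scales each
#' kernel by the IVW weight `gamma_hat^2 / sigma_y^2`; the simple mode uses
#' unit weights. Consistent when the largest homogeneous cluster of
#' instruments is valid. When all ratios coincide the bandwidth degenerates
#' and the common ratio is returned. SE via the same parametric bootstrap as
#' [weighted_median()]; two-sided p from the normal z-score.
#'
#' @param set A [harmonized_set()] with at least 3 SNPs.
#' @param weighted Use IVW weights (`TRUE`) or unit weights (`FALSE`).
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates (default 1000); `0` for point only.
#' @param seed Integer seed (required).
#' @return An `mr_estimate` with method `"weighted_mode"` or
#'   `"simple_mode"`.
#' @export
mode_estimate <- function(set, weighted = FALSE, phi = 1, n_boot = 1000,
                          seed) {
  check_n_snp(set, 3L, "mode estimate")
  if (missing(seed)) config_error("mode_estimate requires an explicit seed")
  weight_fun <- if (weighted) {
    function(g) g^2 / set$sigma_y^2
  } else {
    function(g) rep(1, length(g))
  }
  beta <- mode_point(ratio_estimates(set), weight_fun(set$gamma_hat), phi)
  se <- bootstrap_se(set, function(g, G) mode_point(G / g, weight_fun(g), phi),
                     n_boot, seed)
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  beta, se, nrow(set))
}

#' Two-sided p-value from an estimate and its 95% confidence interval
#'
#' Recovers the standard error as `(ci_high - ci_low) / (2 * qnorm(0.975))`
#' and returns the two-sided normal p, `2 * (1 - pnorm(|beta|/se))`. Used to
#' audit published tables that print an estimate, CI and p for internal
#' consistency.
#'
#' @param beta Point estimate.
#' @param ci_low,ci_high 95% confidence bounds, `ci_low < ci_high`.
#' @return Two-sided p-value.
#' @export
p_from_beta_ci <- function(beta, ci_low, ci_high) {
  if (any(ci_low >= ci_high)) domain_error("degenerate CI: ci_low >= ci_high")
  se <- (ci_high - ci_low) / (2 * Z95)
  2 * stats::pnorm(-abs(beta) / se)
}

default_estimator_config <- function() {
  list(wald_se_order = "first", ivw_effects = "multiplicative_random",
       n_boot = 1000, seed = NULL, phi = 1,
       methods = c("ivw", "mr_egger", "weighted_median", "simple_mode",
                   "weighted_mode"))
}

#' Run the estimator battery appropriate to the set size
#'
#' Dispatch follows the number of harmonized SNPs: one SNP gives the Wald
#' ratio alone; two SNPs give a Wald ratio per SNP plus IVW; three or more
#' give IVW, MR-Egger, weighted median, simple mode and weighted mode, all
#' from the same harmonized input. `config$methods` may restrict the
#' three-plus battery to a subset (e.g. `"ivw"` only for large screens).
#'
#' @param set A [harmonized_set()].
#' @param config Named list overriding `wald_se_order`, `ivw_effects`,
#'   `n_boot`, `seed`, `phi`, `methods`. A `seed` is required whenever the
#'   bootstrap-based estimators run with `n_boot > 0`.
#' @return Data frame with one row per estimate: `method`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `n_snp` and the Egger intercept columns.
#' @export
run_all_estimators <- function(set, config = list()) {
  cfg <- utils::modifyList(default_estimator_config(), config)
  j <- nrow(set)
  if (j == 0L) insufficient_instruments_error("empty harmonized set")
  if (j == 1L) {
    return(estimates_to_frame(list(wald_ratio(set, cfg$wald_se_order))))
  }
  if (j == 2L) {
    ests <- c(lapply(1:2, function(i) wald_ratio(set[i, ], cfg$wald_se_order)),
              list(ivw(set, cfg$ivw_effects)))
    return(estimates_to_frame(ests))
  }
  needs_seed <- cfg$n_boot > 0 &&
    any(c("weighted_median", "simple_mode", "weighted_mode") %in% cfg$methods)
  if (needs_seed && is.null(cfg$seed)) {
    config_error("config$seed is required for bootstrap-based estimators")
  }
  runners <- list(
    ivw = function() ivw(set, cfg$ivw_effects),
    mr_egger = function() mr_egger(set),
    weighted_median = function() weighted_median(set, cfg$n_boot, cfg$seed),
    simple_mode = function() mode_estimate(set, FALSE, cfg$phi, cfg$n_boot,
                                           cfg$seed),
    weighted_mode = function() mode_estimate(set, TRUE, cfg$phi, cfg$n_boot,
                                             cfg$seed)
  )
  unknown <- setdiff(cfg$methods, names(runners))
  if (length(unknown) > 0L) {
    config_error(sprintf("unknown estimator method(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  estimates_to_frame(lapply(runners[cfg$methods], function(f) f()))
}
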