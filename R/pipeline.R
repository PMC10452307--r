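# Study-grid orchestration: 5 sleep exposures x 68 cortical outcomes,
# multiple-testing tiers, and the printed-table consistency audit.

#' The five sleep-trait exposure labels
#' @return Character vector of length 5.
#' @export
sleep_exposures <- function() {
  c("morningness", "ease_of_getting_up", "insomnia", "long_sleep",
    "short_sleep")
}

#' The 34 Desikan-Killiany cortical region labels
#' @return Character vector of length 34.
#' @export
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
}

#' The study's analysis grid
#'
#' Five sleep exposures crossed with 68 globally weighted cortical outcomes
#' (34 Desikan-Killiany regions, each measured as surface area `SA` and
#' thickness `TH`), i.e. 340 exposure-outcome cells. Outcome labels take
#' the form `"SA_<region>"` / `"TH_<region>"`.
#'
#' @return List with `exposures`, `regions`, `measures`, `outcomes` (the 68
#'   labels) and `n_cells`.
#' @export
grid_spec <- function() {
  regions <- dk_regions()
  measures <- c("SA", "TH")
  outcomes <- as.vector(outer(measures, regions, paste, sep = "_"))
  list(exposures = sleep_exposures(), regions = regions,
       measures = measures, outcomes = outcomes,
       n_cells = length(sleep_exposures()) * length(outcomes))
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests Number of tests in the family (340 for the full grid).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is_scalar_number(n_tests) || n_tests < 1) {
    config_error("n_tests must be a positive integer")
  }
  alpha / n_tests
}

#' Classify a p-value into the study's evidence tiers
#'
#' `p < threshold` is Bonferroni-significant; `threshold <= p < 0.01` is
#' suggestive of a stronger association; `0.01 <= p < 0.05` is suggestive;
#' anything else is null.
#'
#' @param pval P-value(s) in (0, 1].
#' @param threshold Bonferroni threshold, e.g.
#'   `bonferroni_threshold(340)`.
#' @return Character vector of tier labels.
#' @export
classify_tier <- function(pval, threshold) {
  ifelse(pval < threshold, "bonferroni_significant",
         ifelse(pval < 0.01, "stronger_suggestive",
                ifelse(pval < 0.05, "suggestive", "null")))
}

empty_grid_row <- function(exposure, outcome) {
  data.frame(exposure = exposure, outcome = outcome, status = "failed",
             n_snp = NA_integer_, beta = NA_real_, se = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
             q_pval = NA_real_, egger_intercept_p = NA_real_,
             sign_agreement = NA, tier = NA_character_,
             stringsAsFactors = FALSE)
}

#' Run the full exposure-by-outcome MR grid
#'
#' For each exposure, instruments are selected once (and cached across all
#' of that exposure's outcomes); each cell then harmonizes the selected
#' instruments against the outcome GWAS, runs the estimator battery and the
#' per-cell diagnostics, and is classified into an evidence tier by its IVW
#' p-value — the headline statistic, with the other estimators summarised
#' as a direction-of-effect concordance flag. Cells that fail with too few
#' instruments are reported with `status = "failed"` rather than dropped.
#'
#' @param exposure_tables Named list of exposure [gwas_table()] objects.
#' @param outcome_tables Named list of outcome [gwas_table()] objects.
#' @param ld An [ld_info()] or `NULL`.
#' @param config Named list; honors the [select_instruments()] keys under
#'   `instruments`, the [run_all_estimators()] keys under `estimators`,
#'   `harmonize` keys (`palindrome_mode`, `freq_tolerance`), and `alpha`
#'   (default 0.05) for the Bonferroni threshold over the grid.
#' @return Object of class `grid_result`: data frame with one row per cell
#'   (`exposure`, `outcome`, `status`, IVW estimate columns, `q_pval`,
#'   `egger_intercept_p`, `sign_agreement`, `tier`), with the Bonferroni
#'   threshold in attribute `threshold`.
#' @export
run_grid <- function(exposure_tables, outcome_tables, ld = NULL,
                     config = list()) {
  if (is.null(names(exposure_tables)) || is.null(names(outcome_tables))) {
    config_error("exposure_tables and outcome_tables must be named lists")
  }
  est_cfg <- config$estimators %||% list()
  inst_cfg <- config$instruments %||% list()
  pal_mode <- config$palindrome_mode %||% "drop_all"
  freq_tol <- config$freq_tolerance %||% 0.08
  n_cells <- length(exposure_tables) * length(outcome_tables)
  threshold <- bonferroni_threshold(n_cells, config$alpha %||% 0.05)

  rows <- vector("list", n_cells)
  i <- 0L
  for (ex_name in names(exposure_tables)) {
    instruments <- tryCatch(
      select_instruments(exposure_tables[[ex_name]], ld, inst_cfg),
      mr_insufficient_instruments = function(e) NULL)
    for (out_name in names(outcome_tables)) {
      i <- i + 1L
      if (is.null(instruments)) {
        rows[[i]] <- empty_grid_row(ex_name, out_name)
        next
      }
      cell <- tryCatch({
        set <- harmonize(instruments$table, outcome_tables[[out_name]],
                         palindrome_mode = pal_mode,
                         freq_tolerance = freq_tol)
        ests <- run_all_estimators(set, est_cfg)
        ivw_row <- ests[ests$method %in% c("ivw", "wald_ratio"), ][1, ]
        qp <- if (nrow(set) >= 2L) cochran_q(set)$q_pval else NA_real_
        ip <- if ("mr_egger" %in% ests$method) {
          ests$egger_intercept_p[ests$method == "mr_egger"]
        } else NA_real_
        agree <- if (nrow(ests) > 1L) {
          all(sign(ests$beta) == sign(ivw_row$beta))
        } else NA
        data.frame(exposure = ex_name, outcome = out_name, status = "ok",
                   n_snp = ivw_row$n_snp, beta = ivw_row$beta,
                   se = ivw_row$se, ci_low = ivw_row$ci_low,
                   ci_high = ivw_row$ci_high, pval = ivw_row$pval,
                   q_pval = qp, egger_intercept_p = ip,
                   sign_agreement = agree,
                   tier = classify_tier(ivw_row$pval, threshold),
                   stringsAsFactors = FALSE)
      },
      mr_insufficient_instruments = function(e) empty_grid_row(ex_name,
                                                               out_name),
      mr_data_error = function(e) empty_grid_row(ex_name, out_name))
      rows[[i]] <- cell
    }
  }
  structure(do.call(rbind, rows), threshold = threshold,
            class = c("grid_result", "data.frame"))
}

#' Audit a printed results table for beta/CI/p internal consistency
#'
#' For each row of a published table carrying an estimate, its 95% CI and a
#' printed p-value, recovers the SE from the CI width, recomputes the
#' two-sided normal p via [p_from_beta_ci()], rounds it to the precision at
#' which the p was printed, and reports whether it matches. Rows whose CI
#' is printed too coarsely to reproduce the p are thereby flagged rather
#' than forced.
#'
#' @param rows Data frame with columns `beta`, `ci_low`, `ci_high` and
#'   `printed_p` (character, so that the printed precision is known; a
#'   numeric column is formatted as printed).
#' @return The input with `recomputed_p` (exact), `recomputed_p_rounded`
#'   (at printed precision) and logical `match` appended.
#' @export
check_printed_consistency <- function(rows) {
  printed_chr <- as.character(rows$printed_p)
  printed_num <- as.numeric(printed_chr)
  decimals <- vapply(printed_chr, function(s) {
    if (grepl("\\.", s)) nchar(sub("^[^.]*\\.", "", s)) else 0L
  }, integer(1))
  p_exact <- p_from_beta_ci(rows$beta, rows$ci_low, rows$ci_high)
  p_round <- round(p_exact, decimals)
  out <- rows
  out$recomputed_p <- p_exact
  out$recomputed_p_rounded <- p_round
  out$match <- p_round == printed_num
  out
}

#' Path to the bundled transcription of the study's headline IVW table
#'
#' A 16-row TSV transcribed from the published results table (exposure,
#' outcome, printed IVW p, beta with 95% CI, heterogeneity and Egger
#' intercept p), for use with [check_printed_consistency()].
#'
#' @return File path.
#' @export
table1_path <- function() {
  system.file("extdata", "table1_ivw.tsv", package = "cortexmr",
              mustWork = TRUE)
}
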