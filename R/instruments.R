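# Instrument selection: significance, MAF, LD clumping, confounder
# exclusion and F-statistic gating.

#' Container for pairwise LD and SNP positions
#'
#' @param pairs Data frame with columns `snp_a`, `snp_b`, `r2` (r-squared in
#'   [0, 1]); queried symmetrically.
#' @param positions Data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based base pairs).
#' @return Object of class `ld_info`.
#' @export
ld_info <- function(pairs = NULL, positions = NULL) {
  pairs <- pairs %||% data.frame(snp_a = character(), snp_b = character(),
                                 r2 = numeric(), stringsAsFactors = FALSE)
  positions <- positions %||% data.frame(snp_id = character(),
                                         chrom = character(), pos = numeric(),
                                         stringsAsFactors = FALSE)
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)),
            all(c("snp_id", "chrom", "pos") %in% names(positions)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1, na.rm = TRUE)) {
    domain_error("r2 values must lie in [0, 1]")
  }
  positions$snp_id <- as.character(positions$snp_id)
  positions$chrom <- as.character(positions$chrom)
  # symmetric lookup key
  key <- paste(pmin(pairs$snp_a, pairs$snp_b),
               pmax(pairs$snp_a, pairs$snp_b), sep = "\r")
  r2_map <- stats::setNames(pairs$r2, key)
  structure(list(pairs = pairs, positions = positions, r2_map = r2_map),
            class = "ld_info")
}

ld_r2 <- function(ld, a, b) {
  v <- ld$r2_map[paste(pmin(a, b), pmax(a, b), sep = "\r")]
  unname(v)
}

#' Filter a GWAS table on genome-wide significance
#'
#' Retains records with `pval` strictly below `p_threshold` (study default
#' 5e-8), logging the rest.
#'
#' @param table A [gwas_table()].
#' @param p_threshold Significance threshold in (0, 1).
#' @return Filtered [gwas_table()] whose drop log gains stage
#'   `"significance"` rows.
#' @export
filter_significance <- function(table, p_threshold = 5e-8) {
  if (!is_scalar_number(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    config_error("p_threshold must lie in (0, 1)")
  }
  keep <- table$pval < p_threshold
  subset_gwas(table, keep, "significance",
              sprintf("pval >= %g", p_threshold))
}

#' Filter a GWAS table on minor-allele frequency
#'
#' Retains records whose minor-allele frequency `min(eaf, 1 - eaf)` is
#' strictly above `maf_threshold` (study default 1%). Records with missing
#' `eaf` are retained but noted in the drop log with stage `"maf_warning"`,
#' since their frequency cannot be checked.
#'
#' @param table A [gwas_table()].
#' @param maf_threshold Threshold in (0, 0.5).
#' @return Filtered [gwas_table()].
#' @export
filter_maf <- function(table, maf_threshold = 0.01) {
  if (!is_scalar_number(maf_threshold) ||
      maf_threshold <= 0 || maf_threshold >= 0.5) {
    config_error("maf_threshold must lie in (0, 0.5)")
  }
  maf <- pmin(table$eaf, 1 - table$eaf)
  keep <- is.na(maf) | maf > maf_threshold
  out <- subset_gwas(table, keep, "maf",
                     sprintf("minor allele frequency <= %g", maf_threshold))
  if (any(is.na(maf))) {
    attr(out, "drop_log") <- log_exclusions(
      attr(out, "drop_log"), table$snp_id[is.na(maf)], "maf_warning",
      "missing eaf; retained unchecked")
  }
  out
}

subset_gwas <- function(table, keep, stage, reason) {
  keep[is.na(keep)] <- FALSE
  log <- attr(table, "drop_log")
  if (any(!keep)) {
    log <- log_exclusions(log, table$snp_id[!keep], stage, reason)
  }
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_label = attr(table, "trait_label"),
            source_label = attr(table, "source_label"),
            drop_log = log,
            class = c("gwas_table", "data.frame"))
}

#' Greedy LD clumping by ascending p-value
#'
#' Iterates SNPs in ascending p-value order (ties broken by chromosome,
#' position, then `snp_id`, making the result independent of input row
#' order) and keeps a SNP only if no already-kept SNP lies on the same
#' chromosome within `window_kb` kilobases with pairwise r-squared at or
#' above `r2_threshold`. An in-window pair with no recorded r-squared is
#' resolved by `missing_ld_policy`: `"assume_independent"` treats it as
#' r² = 0 (both kept), `"assume_linked"` treats it as correlated (the
#' higher-p SNP is dropped).
#'
#' @param table A [gwas_table()] whose SNPs all appear in `ld$positions`.
#' @param ld An [ld_info()].
#' @param r2_threshold r-squared threshold (study default 0.001).
#' @param window_kb Window in kilobases (study default 10000).
#' @param missing_ld_policy `"assume_independent"` (default) or
#'   `"assume_linked"`.
#' @return Filtered [gwas_table()] of index SNPs.
#' @export
ld_clump <- function(table, ld, r2_threshold = 0.001, window_kb = 10000,
                     missing_ld_policy = c("assume_independent",
                                           "assume_linked")) {
  missing_ld_policy <- match.arg(missing_ld_policy)
  if (nrow(table) == 0L) return(table)
  pos_idx <- match(table$snp_id, ld$positions$snp_id)
  if (anyNA(pos_idx)) {
    data_error(sprintf("SNP(s) missing from LD positions: %s",
                       paste(table$snp_id[is.na(pos_idx)], collapse = ", ")))
  }
  chrom <- ld$positions$chrom[pos_idx]
  pos <- ld$positions$pos[pos_idx]
  ord <- order(table$pval, chrom, pos, table$snp_id)
  window_bp <- window_kb * 1000

  kept <- integer()
  for (i in ord) {
    in_window <- kept[chrom[kept] == chrom[i] &
                        abs(pos[kept] - pos[i]) <= window_bp]
    linked <- FALSE
    for (k in in_window) {
      r2 <- ld_r2(ld, table$snp_id[i], table$snp_id[k])
      if (is.na(r2)) r2 <- if (missing_ld_policy == "assume_linked") 1 else 0
      if (r2 >= r2_threshold) {
        linked <- TRUE
        break
      }
    }
    if (!linked) kept <- c(kept, i)
  }
  keep <- logical(nrow(table))
  keep[kept] <- TRUE
  subset_gwas(table, keep, "ld_clump",
              sprintf("in LD (r2 >= %g within %d kb) with a lower-p SNP",
                      r2_threshold, window_kb))
}

#' Remove SNPs named on a confounder exclusion list
#'
#' Stands in for an interactive phenotype-lookup step: SNPs known to
#' associate with confounders of the exposure-outcome relation (education,
#' smoking, alcohol, cardiovascular disease, brain disease, psychosis, ...)
#' are supplied as a static list and removed with their reasons logged.
#' Listed SNPs absent from the table are logged as `"not present"` and
#' otherwise ignored.
#'
#' @param table A [gwas_table()].
#' @param exclusion_list Data frame with columns `snp_id` and `reason`
#'   (missing reasons become `"confounder"`), or `NULL` for a no-op.
#' @return Filtered [gwas_table()].
#' @export
exclude_confounder_snps <- function(table, exclusion_list = NULL) {
  if (is.null(exclusion_list) || nrow(exclusion_list) == 0L) return(table)
  reason <- as.character(exclusion_list$reason %||%
                           rep("confounder", nrow(exclusion_list)))
  reason[is.na(reason) | reason == ""] <- "confounder"
  hit <- table$snp_id %in% exclusion_list$snp_id
  log <- attr(table, "drop_log")
  absent <- setdiff(exclusion_list$snp_id, table$snp_id)
  if (length(absent) > 0L) {
    log <- log_exclusions(log, absent, "confounder", "not present")
  }
  attr(table, "drop_log") <- log
  idx <- match(table$snp_id[hit], exclusion_list$snp_id)
  subset_gwas(table, !hit, "confounder",
              if (any(hit)) reason[idx] else character())
}

#' Per-SNP instrument-strength F-statistic
#'
#' Two standard formulas are available. `"wald"` (default) is the squared
#' z-score, F = (beta/se)^2. `"variance_explained"` first computes the
#' variance explained by the SNP,
#' R² = 2 beta² p(1-p) / (2 beta² p(1-p) + 2 se² n p(1-p)) with p the
#' effect-allele frequency, then F = R² (n - 2) / (1 - R²); it requires
#' `eaf` and `n`. The two agree closely for large n. F > 10 is the
#' conventional weak-instrument cutoff.
#'
#' @param record A data frame of GWAS records (rows of a [gwas_table()]).
#' @param method `"wald"` or `"variance_explained"`.
#' @return Numeric vector of F-statistics, one per row.
#' @export
f_statistic <- function(record, method = c("wald", "variance_explained")) {
  method <- match.arg(method)
  if (any(is.na(record$se)) || any(record$se <= 0)) {
    domain_error("se must be positive to compute an F-statistic")
  }
  if (method == "wald") {
    return((record$beta / record$se)^2)
  }
  if (any(is.na(record$eaf)) || any(is.na(record$n))) {
    config_error("variance_explained F requires eaf and n for every SNP")
  }
  pq2 <- 2 * record$eaf * (1 - record$eaf)
  r2 <- record$beta^2 * pq2 /
    (record$beta^2 * pq2 + record$se^2 * record$n * pq2)
  r2 * (record$n - 2) / (1 - r2)
}

default_instrument_config <- function() {
  list(p_threshold = 5e-8, maf_threshold = 0.01, r2_threshold = 0.001,
       window_kb = 10000, f_threshold = 10, f_method = "wald",
       missing_ld_policy = "assume_independent", exclusion_list = NULL)
}

#' Full instrument-selection cascade
#'
#' Applies, in order: genome-wide significance filter, minor-allele
#' frequency filter, greedy LD clumping, confounder exclusion-list removal,
#' and the F-statistic gate (SNPs with F <= `f_threshold` dropped). Defaults
#' follow the study design: p < 5e-8, MAF > 1%, r² < 0.001 within 10,000 kb,
#' F > 10.
#'
#' @param table Exposure [gwas_table()].
#' @param ld An [ld_info()], or `NULL` to skip clumping (degenerate LD).
#' @param config Named list overriding any of `p_threshold`,
#'   `maf_threshold`, `r2_threshold`, `window_kb`, `f_threshold`,
#'   `f_method`, `missing_ld_policy`, `exclusion_list`.
#' @return Object of class `instrument_report`: list with `selected`
#'   (snp_id vector), `table` (the surviving [gwas_table()]), `per_snp_f`,
#'   `mean_f`, `stage_counts` and `exclusions` (the cumulative drop log).
#' @export
select_instruments <- function(table, ld = NULL, config = list()) {
  cfg <- utils::modifyList(default_instrument_config(), config)
  counts <- c(input = nrow(table))

  tab <- filter_significance(table, cfg$p_threshold)
  counts["significance"] <- nrow(tab)
  tab <- filter_maf(tab, cfg$maf_threshold)
  counts["maf"] <- nrow(tab)
  if (!is.null(ld) && nrow(tab) > 0L) {
    tab <- ld_clump(tab, ld, cfg$r2_threshold, cfg$window_kb,
                    cfg$missing_ld_policy)
  }
  counts["ld_clump"] <- nrow(tab)
  tab <- exclude_confounder_snps(tab, cfg$exclusion_list)
  counts["confounder"] <- nrow(tab)

  if (nrow(tab) > 0L) {
    f <- f_statistic(tab, cfg$f_method)
    weak <- f <= cfg$f_threshold
    tab2 <- subset_gwas(tab, !weak, "f_statistic",
                        sprintf("F <= %g", cfg$f_threshold))
    f <- f[!weak]
  } else {
    tab2 <- tab
    f <- numeric()
  }
  counts["f_statistic"] <- nrow(tab2)
  if (nrow(tab2) == 0L) {
    insufficient_instruments_error(sprintf(
      "no instruments survive selection for '%s'",
      attr(table, "trait_label")))
  }
  structure(list(
    selected = tab2$snp_id,
    table = tab2,
    per_snp_f = stats::setNames(f, tab2$snp_id),
    mean_f = mean(f),
    stage_counts = counts,
    exclusions = attr(tab2, "drop_log")
  ), class = "instrument_report")
}

#' @export
print.instrument_report <- function(x, ...) {
  cat(sprintf("Instrument report: %d SNPs selected (mean F = %.1f)\n",
              length(x$selected), x$mean_f))
  print(x$stage_counts)
  invisible(x)
}
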