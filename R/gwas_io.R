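# Reading, validating and writing GWAS summary statistics and result tables.

canonical_gwas_fields <- function() {
  c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pval", "n")
}

required_gwas_fields <- function() {
  c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
}

#' Construct a validated GWAS summary-statistics table
#'
#' Builds the package's canonical per-SNP container from a data frame holding
#' (at least) `snp_id`, `effect_allele`, `other_allele`, `beta`, `se` and
#' `pval`; `chrom`, `pos`, `eaf` and `n` are optional and filled with `NA`
#' when absent. Rows violating the per-record invariants (non-ACGT or
#' identical alleles, `se <= 0`, `pval` outside (0, 1], `eaf` outside [0, 1],
#' non-positive `n`, duplicated `snp_id`) are dropped and recorded in the
#' table's drop log rather than raising an error, so that a partially dirty
#' public summary file still loads. Alleles are uppercased on entry; this
#' makes the analysis SNP-only, since indel alleles are not single ACGT
#' letters and are dropped.
#'
#' @param df Data frame with canonical column names.
#' @param trait_label Human-readable trait name carried through the pipeline.
#' @param source_label Provenance string (typically the file path).
#' @return An object of class `gwas_table`: a data frame with canonical
#'   columns plus attributes `trait_label`, `source_label` and `drop_log`
#'   (a data frame of `snp_id`, `stage`, `reason`).
#' @export
gwas_table <- function(df, trait_label = "", source_label = "") {
  missing_req <- setdiff(required_gwas_fields(), names(df))
  if (length(missing_req) > 0L) {
    config_error(sprintf("missing required column(s): %s",
                         paste(missing_req, collapse = ", ")))
  }
  for (f in setdiff(canonical_gwas_fields(), names(df))) df[[f]] <- NA
  df <- df[, canonical_gwas_fields(), drop = FALSE]

  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (f in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  }

  acgt <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  flag(!(df$effect_allele %in% acgt) | !(df$other_allele %in% acgt),
       "non-ACGT allele")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(is.na(df$beta), "missing beta")
  flag(is.na(df$se) | df$se <= 0, "nonpositive se")
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "invalid pval")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "invalid eaf")
  flag(!is.na(df$n) & df$n <= 0, "nonpositive n")
  flag(duplicated(df$snp_id), "duplicate snp_id")

  dropped <- !is.na(reason)
  drop_log <- new_exclusion_log()
  if (any(dropped)) {
    drop_log <- log_exclusions(drop_log, df$snp_id[dropped], "read",
                               reason[dropped])
  }
  out <- df[!dropped, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_label = trait_label,
            source_label = source_label,
            drop_log = drop_log,
            class = c("gwas_table", "data.frame"))
}

#' Read GWAS summary statistics from a headered TSV
#'
#' Reads a tab-separated summary-statistics file (optionally
#' gzip-compressed), renames columns to the package's canonical field names
#' through `column_map`, and validates the rows via [gwas_table()]. Public
#' GWAS releases use many header dialects, so the mapping is a configuration
#' concern: `column_map` is a named character vector whose names are the
#' canonical fields (`snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) and whose values are
#' the matching file headers. Unmapped canonical fields default to their own
#' name; optional fields absent from the file are tolerated.
#'
#' @param path Path to the TSV (or `.gz`) file.
#' @param column_map Named character vector, canonical field -> file header.
#' @param trait_label,source_label Labels stored on the returned table;
#'   default to the file's base name and path.
#' @return A [gwas_table()].
#' @export
read_gwas <- function(path, column_map = NULL, trait_label = NULL,
                      source_label = NULL) {
  if (!file.exists(path)) data_error(sprintf("GWAS file not found: %s", path))
  con <- path
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(try(close(con), silent = TRUE), add = TRUE)
  }
  raw <- utils::read.delim(con, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) data_error(sprintf("empty GWAS file: %s", path))

  cm <- as.list(column_map %||% character())
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in canonical_gwas_fields()) {
    header <- cm[[f]] %||% f
    mapped_explicitly <- !is.null(cm[[f]])
    if (header %in% names(raw)) {
      df[[f]] <- raw[[header]]
    } else if (mapped_explicitly) {
      config_error(sprintf(
        "column '%s' (mapped from field '%s') not found in %s",
        header, f, path))
    } else if (f %in% required_gwas_fields()) {
      config_error(sprintf(
        "required column '%s' not found in %s (supply a column_map)",
        f, path))
    }
  }
  gwas_table(df,
             trait_label = trait_label %||% sub("\\.tsv(\\.gz)?$", "",
                                                basename(path)),
             source_label = source_label %||% path)
}

#' Write a GWAS table to TSV
#'
#' Writes the canonical columns of a [gwas_table()] as a headered
#' tab-separated file; numeric values keep 10 significant digits so that a
#' write/read round trip is the identity at that precision.
#'
#' @param table A [gwas_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(table, path) {
  write_results(as.data.frame(table), path)
}

format_result_frame <- function(df) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- formatC(out[[j]], digits = 10, format = "g")
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  out
}

#' Write a result table to TSV
#'
#' Serializes any result data frame (MR estimates, sensitivity rows, grid
#' output, exclusion logs) as a headered tab-separated file. Floating-point
#' columns are written with 10 significant digits, so
#' `read_results(write_results(x))` reproduces `x` to that precision.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    data_error(sprintf("output directory does not exist: %s", dir))
  }
  utils::write.table(format_result_frame(df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns typed by `read.delim`'s usual rules.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) data_error(sprintf("file not found: %s", path))
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("GWAS table '%s' (%d SNPs, %d dropped at read)\n",
              attr(x, "trait_label"), nrow(x), nrow(attr(x, "drop_log"))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
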