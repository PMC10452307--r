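# Allele harmonization of exposure and outcome summary statistics.

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic when its two alleles are strand complements of each
#' other ({A,T} or {C,G}), so the reported strand cannot be inferred from the
#' alleles alone and exposure/outcome alignment is ambiguous.
#'
#' @param effect_allele,other_allele Single-letter allele codes (A/C/G/T),
#'   vectorized.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  acgt <- c("A", "C", "G", "T")
  if (any(!(ea %in% acgt)) || any(!(oa %in% acgt))) {
    domain_error("alleles must be one of A/C/G/T")
  }
  unname(ALLELE_COMPLEMENT[ea] == oa)
}

#' Construct a harmonized exposure/outcome SNP set directly
#'
#' Low-level constructor for the container the estimators consume: one row
#' per SNP with the exposure effect `gamma_hat` (SE `sigma_x`) and the
#' outcome effect `Gamma_hat` (SE `sigma_y`) expressed for the same effect
#' allele. [harmonize()] produces these from two GWAS tables; this
#' constructor is for data that is already aligned.
#'
#' @param gamma_hat,sigma_x Exposure per-allele effects and standard errors.
#' @param Gamma_hat,sigma_y Outcome per-allele effects and standard errors.
#' @param snp_id SNP identifiers (defaults to `snp_1`, `snp_2`, ...).
#' @param eaf_exposure Effect-allele frequency in the exposure GWAS, or `NA`.
#' @param flipped,palindromic Per-SNP provenance flags.
#' @param exposure_label,outcome_label Trait labels.
#' @param exclusions Data frame of `(snp_id, reason)` recording SNPs removed
#'   during harmonization.
#' @return An object of class `harmonized_set` (a data frame with one row
#'   per SNP plus label/exclusion attributes).
#' @export
harmonized_set <- function(gamma_hat, sigma_x, Gamma_hat, sigma_y,
                           snp_id = NULL, eaf_exposure = NA_real_,
                           flipped = FALSE, palindromic = FALSE,
                           exposure_label = "exposure",
                           outcome_label = "outcome",
                           exclusions = NULL) {
  j <- length(gamma_hat)
  stopifnot(length(sigma_x) == j, length(Gamma_hat) == j,
            length(sigma_y) == j)
  if (any(!is.finite(sigma_x)) || any(sigma_x <= 0) ||
      any(!is.finite(sigma_y)) || any(sigma_y <= 0)) {
    domain_error("harmonized standard errors must be positive")
  }
  df <- data.frame(
    snp_id = as.character(snp_id %||% paste0("snp_", seq_len(j))),
    gamma_hat = as.numeric(gamma_hat),
    sigma_x = as.numeric(sigma_x),
    Gamma_hat = as.numeric(Gamma_hat),
    sigma_y = as.numeric(sigma_y),
    eaf_exposure = rep_len(as.numeric(eaf_exposure), j),
    flipped = rep_len(as.logical(flipped), j),
    palindromic = rep_len(as.logical(palindromic), j),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$snp_id)) domain_error("snp_id must be unique")
  excl <- exclusions %||%
    data.frame(snp_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(df,
            exposure_label = exposure_label,
            outcome_label = outcome_label,
            exclusions = excl,
            class = c("harmonized_set", "data.frame"))
}

# Classify one outcome allele pair against the exposure pair.
# Returns "aligned", "swapped", "strand_aligned", "strand_swapped" or
# "incompatible".
classify_alleles <- function(exp_ea, exp_oa, out_ea, out_oa) {
  if (out_ea == exp_ea && out_oa == exp_oa) return("aligned")
  if (out_ea == exp_oa && out_oa == exp_ea) return("swapped")
  cea <- ALLELE_COMPLEMENT[[out_ea]]
  coa <- ALLELE_COMPLEMENT[[out_oa]]
  if (cea == exp_ea && coa == exp_oa) return("strand_aligned")
  if (cea == exp_oa && coa == exp_ea) return("strand_swapped")
  "incompatible"
}

#' Harmonize exposure and outcome GWAS tables to a common effect allele
#'
#' Intersects the two tables by `snp_id` and aligns each outcome record to
#' the exposure's effect allele: when the outcome's alleles are swapped
#' relative to the exposure, the outcome beta is negated and its frequency
#' complemented (`flipped = TRUE`); when the alleles match only after strand
#' complementation (A<->T, C<->G), the pair is complemented first and then
#' aligned the same way. Allele pairs that cannot be reconciled are excluded
#' with reason `"incompatible alleles"`.
#'
#' Palindromic SNPs cannot be oriented from alleles alone and are handled by
#' `palindrome_mode`:
#' \describe{
#'   \item{`drop_all`}{(default) every palindromic SNP is excluded — the
#'     conservative choice.}
#'   \item{`drop_intermediate_freq`}{palindromic SNPs whose exposure or
#'     outcome effect-allele frequency lies within `freq_tolerance` of 0.5
#'     (or is missing) are excluded; the remainder are oriented by frequency
#'     agreement: if both frequencies fall on the same side of 0.5 the pair
#'     is taken as aligned, otherwise the outcome is flipped.}
#' }
#'
#' @param exposure,outcome [gwas_table()] objects.
#' @param palindrome_mode `"drop_all"` or `"drop_intermediate_freq"`.
#' @param freq_tolerance Half-width of the ambiguous frequency band around
#'   0.5 used by `drop_intermediate_freq` (default 0.08).
#' @return A [harmonized_set()] whose `exclusions` attribute accounts for
#'   every intersected SNP not present in the output.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_mode = c("drop_all", "drop_intermediate_freq"),
                      freq_tolerance = 0.08) {
  palindrome_mode <- match.arg(palindrome_mode)
  exp_df <- as.data.frame(exposure)
  out_df <- as.data.frame(outcome)
  common <- intersect(exp_df$snp_id, out_df$snp_id)
  if (length(common) == 0L) {
    data_error(sprintf(
      "no SNPs shared between exposure '%s' and outcome '%s'",
      attr(exposure, "trait_label"), attr(outcome, "trait_label")))
  }
  e <- exp_df[match(common, exp_df$snp_id), ]
  o <- out_df[match(common, out_df$snp_id), ]

  keep <- logical(length(common))
  flipped <- logical(length(common))
  Gamma <- o$beta
  eaf_exp <- e$eaf
  excl_id <- character()
  excl_reason <- character()
  palin <- is_palindromic(e$effect_allele, e$other_allele)

  for (i in seq_along(common)) {
    cls <- classify_alleles(e$effect_allele[i], e$other_allele[i],
                            o$effect_allele[i], o$other_allele[i])
    if (cls == "incompatible") {
      excl_id <- c(excl_id, common[i])
      excl_reason <- c(excl_reason, "incompatible alleles")
      next
    }
    if (palin[i]) {
      # For a palindromic pair "aligned" and "strand_swapped" (and "swapped"
      # and "strand_aligned") are indistinguishable; resolve per mode.
      if (palindrome_mode == "drop_all") {
        excl_id <- c(excl_id, common[i])
        excl_reason <- c(excl_reason, "palindromic")
        next
      }
      fe <- e$eaf[i]
      fo <- o$eaf[i]
      if (is.na(fe) || is.na(fo)) {
        excl_id <- c(excl_id, common[i])
        excl_reason <- c(excl_reason, "palindromic, missing eaf")
        next
      }
      lo <- 0.5 - freq_tolerance
      hi <- 0.5 + freq_tolerance
      if ((fe >= lo && fe <= hi) || (fo >= lo && fo <= hi)) {
        excl_id <- c(excl_id, common[i])
        excl_reason <- c(excl_reason, "palindromic, intermediate frequency")
        next
      }
      same_side <- (fe < 0.5) == (fo < 0.5)
      keep[i] <- TRUE
      if (!same_side) {
        flipped[i] <- TRUE
        Gamma[i] <- -o$beta[i]
      }
      next
    }
    keep[i] <- TRUE
    if (cls %in% c("swapped", "strand_swapped")) {
      flipped[i] <- TRUE
      Gamma[i] <- -o$beta[i]
    }
  }

  if (!any(keep)) {
    data_error(sprintf(
      "harmonization of '%s' on '%s' left no usable SNPs",
      attr(exposure, "trait_label"), attr(outcome, "trait_label")))
  }
  harmonized_set(
    gamma_hat = e$beta[keep],
    sigma_x = e$se[keep],
    Gamma_hat = Gamma[keep],
    sigma_y = o$se[keep],
    snp_id = common[keep],
    eaf_exposure = eaf_exp[keep],
    flipped = flipped[keep],
    palindromic = palin[keep],
    exposure_label = attr(exposure, "trait_label") %||% "exposure",
    outcome_label = attr(outcome, "trait_label") %||% "outcome",
    exclusions = data.frame(snp_id = excl_id, reason = excl_reason,
                            stringsAsFactors = FALSE)
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s (%d SNPs, %d excluded)\n",
              attr(x, "exposure_label"), attr(x, "outcome_label"),
              nrow(x), nrow(attr(x, "exclusions"))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
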