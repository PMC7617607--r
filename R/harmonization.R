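# Allele harmonization of exposure and outcome summary statistics.
#
# Two GWAS may report the same SNP with effect/other alleles swapped or on
# opposite strands. Harmonization re-expresses the outcome association on the
# exposure's effect allele. Palindromic variants (A/T or C/G) cannot be
# resolved from allele labels; they are oriented by allele-frequency
# concordance when the minor allele frequency is well away from 0.5 and
# excluded (MAF > 0.42 in either data set) otherwise.

ALLELE_COMP <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic?
#'
#' `TRUE` iff the unordered pair is \{A,T\} or \{C,G\}, i.e. the variant reads
#' the same on both strands.
#'
#' @param a1,a2 Allele characters (vectorized).
#' @return Logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

harmonized_row <- function(variant_id, ea, oa, bx, sex, fx, by, sey, fy,
                           action, reason = "") {
  data.frame(variant_id = variant_id, effect_allele = ea, other_allele = oa,
             beta_exposure = bx, se_exposure = sex, eaf_exposure = fx,
             beta_outcome = by, se_outcome = sey, eaf_outcome = fy,
             action = action, reason = reason, stringsAsFactors = FALSE)
}

#' Harmonize one exposure/outcome variant pair
#'
#' Aligns the outcome association to the exposure's effect allele. Possible
#' actions: `none` (labels already agree), `swapped` (outcome beta negated,
#' eaf complemented), `strand_flipped` (outcome alleles relabeled to the
#' opposite strand; non-palindromic only), or `excluded` with a
#' machine-readable reason (`palindromic_ambiguous`,
#' `palindromic_missing_eaf`, `allele_mismatch`). Palindromic variants with
#' MAF <= `maf_ambiguity` in both data sets are oriented by frequency
#' concordance (whichever of `eaf_out` and `1 - eaf_out` is closer to
#' `eaf_exp`); above that threshold the orientation is ambiguous and the
#' variant is excluded.
#'
#' @param exposure,outcome Single records (1-row `data.frame` or list) with
#'   fields `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`; same `variant_id` in both.
#' @param maf_ambiguity Palindromic-exclusion MAF threshold (default 0.42).
#' @return One-row `data.frame` (a harmonized pair), exposure-allele
#'   labeled, with `action` and `reason` columns. Exclusion is a value, not
#'   an error.
#' @export
harmonize <- function(exposure, outcome, maf_ambiguity = 0.42) {
  stopifnot(exposure$variant_id == outcome$variant_id)
  ea_x <- exposure$effect_allele; oa_x <- exposure$other_allele
  ea_y <- outcome$effect_allele;  oa_y <- outcome$other_allele
  out <- function(by, fy, action, reason = "") {
    harmonized_row(exposure$variant_id, ea_x, oa_x,
                   exposure$beta, exposure$se, exposure$eaf,
                   by, outcome$se, fy, action, reason)
  }
  excl <- function(reason) {
    harmonized_row(exposure$variant_id, ea_x, oa_x,
                   exposure$beta, exposure$se, exposure$eaf,
                   NA_real_, outcome$se, outcome$eaf, "excluded", reason)
  }

  if (is_palindromic(ea_x, oa_x)) {
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) return(excl("allele_mismatch"))
    if (is.na(outcome$eaf) || is.na(exposure$eaf)) {
      return(excl("palindromic_missing_eaf"))
    }
    maf_x <- min(exposure$eaf, 1 - exposure$eaf)
    maf_y <- min(outcome$eaf, 1 - outcome$eaf)
    if (maf_x > maf_ambiguity || maf_y > maf_ambiguity) {
      return(excl("palindromic_ambiguous"))
    }
    same <- abs(exposure$eaf - outcome$eaf) <=
      abs(exposure$eaf - (1 - outcome$eaf))
    if (same) out(outcome$beta, outcome$eaf, "none")
    else out(-outcome$beta, 1 - outcome$eaf, "swapped", "palindromic_freq")
  } else if (ea_y == ea_x && oa_y == oa_x) {
    out(outcome$beta, outcome$eaf, "none")
  } else if (ea_y == oa_x && oa_y == ea_x) {
    out(-outcome$beta, 1 - outcome$eaf, "swapped")
  } else if (identical(unname(ALLELE_COMP[ea_y]), ea_x) &&
             identical(unname(ALLELE_COMP[oa_y]), oa_x)) {
    out(outcome$beta, outcome$eaf, "strand_flipped")
  } else if (identical(unname(ALLELE_COMP[ea_y]), oa_x) &&
             identical(unname(ALLELE_COMP[oa_y]), ea_x)) {
    out(-outcome$beta, 1 - outcome$eaf, "swapped", "strand_flipped")
  } else {
    excl("allele_mismatch")
  }
}

#' Harmonize two summary-statistic sets variant by variant
#'
#' Joins on `variant_id` (variants absent from either set are dropped and
#' counted in attribute `"n_unmatched"`) and applies [harmonize()] to each
#' shared variant.
#'
#' @param exposure_ss,outcome_ss [sumstat_set()] objects.
#' @inheritParams harmonize
#' @return `data.frame` of harmonized pairs (one row per shared variant,
#'   including exclusions).
#' @export
harmonize_sets <- function(exposure_ss, outcome_ss, maf_ambiguity = 0.42) {
  xv <- exposure_ss$variants
  yv <- outcome_ss$variants
  shared <- intersect(xv$variant_id, yv$variant_id)
  xi <- match(shared, xv$variant_id)
  yi <- match(shared, yv$variant_id)
  rows <- lapply(seq_along(shared), function(k) {
    harmonize(xv[xi[k], ], yv[yi[k], ], maf_ambiguity)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    harmonized_row(character(), character(), character(), numeric(),
                   numeric(), numeric(), numeric(), numeric(), numeric(),
                   character(), character())
  attr(out, "n_unmatched") <- (nrow(xv) - length(shared)) +
    (nrow(yv) - length(shared))
  out
}

#' Drop excluded rows from a harmonized table
#'
#' @param pairs Output of [harmonize_sets()].
#' @return The retained (analyzable) rows.
#' @export
harmonized_retained <- function(pairs) {
  pairs[pairs$action != "excluded", , drop = FALSE]
}
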