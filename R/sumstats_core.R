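# Domain types, readers/writers and validation for GWAS summary statistics,
# LD correlation matrices and gene annotations.

VALID_ALLELES <- c("A", "C", "G", "T")

SUMSTAT_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")

#' Construct a summary-statistic set
#'
#' A `sumstat_set` bundles one trait's per-variant GWAS associations: the
#' unit passed around by every downstream stage. Effect sizes are per
#' effect-allele copy, on the per-SD scale for quantitative (protein) traits
#' and the log-odds scale for binary (disease) traits.
#'
#' @param trait_id Trait identifier (e.g. the protein or outcome name).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param cohort_label Free-text cohort label (e.g. `"decode"`, `"ukb"`).
#' @param variants `data.frame` with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`.
#' @return An object of class `sumstat_set`.
#' @export
sumstat_set <- function(trait_id, trait_type = c("quantitative", "binary"),
                        cohort_label = "", variants) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(variants))
  missing <- setdiff(SUMSTAT_COLS, names(variants))
  if (length(missing) > 0L) {
    stop("schema error: missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("variant_id must be unique within a summary-statistic set")
  }
  variants <- variants[, SUMSTAT_COLS]
  rownames(variants) <- NULL
  structure(list(trait_id = trait_id, trait_type = trait_type,
                 cohort_label = cohort_label, variants = variants),
            class = "sumstat_set")
}

#' @export
print.sumstat_set <- function(x, ...) {
  cat(sprintf("<sumstat_set> trait '%s' (%s%s): %d variants\n", x$trait_id,
              x$trait_type,
              if (nzchar(x$cohort_label)) paste0(", ", x$cohort_label) else "",
              nrow(x$variants)))
  invisible(x)
}

#' Validate summary-statistic records
#'
#' Checks every record against the field invariants (A/C/G/T alleles, distinct
#' alleles, `eaf` in \[0,1\], `se` > 0, `pval` in (0,1\]) and, optionally, the
#' consistency of `pval` with `2*pnorm(-|beta/se|)` at 10% relative tolerance.
#' Real summary files often carry rounded p-values, so the consistency check
#' warns by default and only rejects in strict mode.
#'
#' @param variants Summary-statistic `data.frame`.
#' @param strict If `TRUE` a p-value inconsistent with beta/se rejects the
#'   record; otherwise it only raises a warning.
#' @param check_pval Disable the p-value consistency check entirely.
#' @param pval_tol Relative tolerance of the consistency check.
#' @return list with elements `ok` (validated rows) and `rejected`
#'   (`data.frame` of row number, variant_id, reason).
#' @export
validate_sumstats <- function(variants, strict = FALSE, check_pval = TRUE,
                              pval_tol = 0.1) {
  n <- nrow(variants)
  reasons <- character(n)
  add <- function(bad, msg) {
    bad[is.na(bad)] <- FALSE
    reasons[bad] <<- ifelse(nzchar(reasons[bad]),
                            paste(reasons[bad], msg, sep = "; "), msg)
  }
  add(!(variants$effect_allele %in% VALID_ALLELES) |
        !(variants$other_allele %in% VALID_ALLELES),
      "non-ACGT allele")
  add(variants$effect_allele == variants$other_allele, "identical alleles")
  add(!is.na(variants$eaf) & (variants$eaf < 0 | variants$eaf > 1),
      "eaf outside [0,1]")
  add(is.na(variants$se) | variants$se <= 0, "se not positive")
  add(is.na(variants$pval) | variants$pval <= 0 | variants$pval > 1,
      "pval outside (0,1]")
  add(is.na(variants$pos) | variants$pos < 1, "pos not positive")

  if (check_pval) {
    expected <- 2 * stats::pnorm(-abs(variants$beta / variants$se))
    # extremely small p-values underflow in text formats; skip them
    comparable <- !is.na(variants$pval) & !is.na(expected) &
      variants$pval > 1e-290 & expected > 1e-290 & !nzchar(reasons)
    off <- comparable &
      abs(variants$pval - expected) / expected > pval_tol
    off[is.na(off)] <- FALSE
    if (any(off)) {
      if (strict) {
        add(off, "pval inconsistent with beta/se")
      } else {
        warning(sum(off), " record(s) have pval inconsistent with |beta/se|",
                call. = FALSE)
      }
    }
  }

  bad <- nzchar(reasons)
  list(ok = variants[!bad, , drop = FALSE],
       rejected = data.frame(row = which(bad),
                             variant_id = variants$variant_id[bad],
                             reason = reasons[bad],
                             stringsAsFactors = FALSE))
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Expects a UTF-8 TSV with header columns `variant_id, chrom, pos,
#' effect_allele, other_allele, eaf, beta, se, pval, n`; missing `eaf` is
#' encoded `NA`. Rows violating record invariants are dropped with a warning;
#' the per-row report is attached as attribute `"rejected"`.
#'
#' @inheritParams sumstat_set
#' @param path File path.
#' @inheritParams validate_sumstats
#' @return A validated [sumstat_set()].
#' @export
read_sumstats <- function(path, trait_id, trait_type = "quantitative",
                          cohort_label = "", strict = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(variant_id = "character",
                                         chrom = "character"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(SUMSTAT_COLS, names(df))
  if (length(missing) > 0L) {
    stop("schema error: missing columns: ", paste(missing, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  for (cn in c("eaf", "beta", "se", "pval", "n")) df[[cn]] <- as.numeric(df[[cn]])
  v <- validate_sumstats(df, strict = strict)
  if (nrow(v$rejected) > 0L) {
    warning(sprintf("%d record(s) rejected reading %s: %s", nrow(v$rejected),
                    path, paste(utils::head(v$rejected$reason, 3L),
                                collapse = " | ")), call. = FALSE)
  }
  out <- sumstat_set(trait_id, trait_type, cohort_label, v$ok)
  attr(out, "rejected") <- v$rejected
  out
}

#' Write a summary-statistic set to a tab-delimited file
#'
#' Numeric fields are serialized with 17 significant digits so that a
#' write/read round trip reproduces every double bit-for-bit.
#'
#' @param ss A [sumstat_set()].
#' @param path Output file path.
#' @export
write_sumstats <- function(ss, path) {
  df <- ss$variants
  fmt <- df
  for (cn in c("eaf", "beta", "se", "pval", "n")) {
    fmt[[cn]] <- ifelse(is.na(df[[cn]]), "NA", sprintf("%.17g", df[[cn]]))
  }
  fmt$pos <- sprintf("%d", df$pos)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an LD correlation matrix
#'
#' An LD matrix is a square numeric matrix of signed allelic correlations r
#' with variant ids as dimnames, unit diagonal, entries in \[-1,1\] and no
#' eigenvalue below -1e-8 (near positive semidefinite). Asymmetry beyond
#' `tol` is an error; smaller asymmetry is symmetrized away.
#'
#' @param R Numeric matrix with variant ids as row/column names.
#' @param tol Largest tolerated absolute asymmetry.
#' @return The validated (symmetrized) matrix.
#' @export
validate_ld <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop("LD format error: matrix is not square")
  }
  if (is.null(rownames(R))) stop("LD matrix must carry variant ids as dimnames")
  if (max(abs(R - t(R))) > tol) stop("LD format error: matrix is asymmetric")
  R <- (R + t(R)) / 2
  if (any(abs(diag(R) - 1) > 1e-12)) {
    stop("LD format error: diagonal entries must equal 1")
  }
  if (max(abs(R)) > 1 + 1e-12) stop("LD format error: |r| > 1")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("LD format error: matrix is not positive semidefinite")
  R
}

#' Read an LD matrix from a plain-text file
#'
#' First line: whitespace-delimited variant ids; following lines: the dense
#' matrix rows in the same order.
#'
#' @param path File path.
#' @return Validated LD matrix (named, symmetric, unit diagonal).
#' @export
read_ld <- function(path) {
  ids <- scan(path, what = character(), nlines = 1L, quiet = TRUE)
  m <- length(ids)
  vals <- scan(path, what = numeric(), skip = 1L, quiet = TRUE)
  if (length(vals) != m * m) {
    stop("LD format error: expected a ", m, "x", m, " matrix")
  }
  R <- matrix(vals, nrow = m, byrow = TRUE, dimnames = list(ids, ids))
  validate_ld(R)
}

#' Write an LD matrix to a plain-text file
#'
#' @param R Named LD matrix.
#' @param path Output file path.
#' @export
write_ld <- function(R, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(R), collapse = " "), con)
  for (i in seq_len(nrow(R))) {
    writeLines(paste(sprintf("%.17g", R[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Define a gene region
#'
#' Gene coordinates follow the BED convention: 0-based, half-open
#' `[start, end)`. Variant positions elsewhere in the package are 1-based.
#' The default cis window is the gene body itself (`flank = 0`); a flank can
#' widen it to capture neighboring regulatory variants. Genes sharing a locus
#' (e.g. the fibrinogen alpha/gamma cluster, treated as a single locus due to
#' strong regional genetic correlation) are recorded via `merged_with`.
#'
#' @param gene_symbol Gene symbol naming the region.
#' @param chrom Chromosome label.
#' @param start,end 0-based half-open interval.
#' @param flank Flank in basepairs added on both sides (default 0).
#' @param merged_with Optional character vector of co-located gene symbols.
#' @return An object of class `gene_region`.
#' @export
gene_region <- function(gene_symbol, chrom, start, end, flank = 0,
                        merged_with = NULL) {
  stopifnot(start < end, flank >= 0)
  structure(list(gene_symbol = gene_symbol, chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 flank = as.numeric(flank), merged_with = merged_with),
            class = "gene_region")
}

#' @export
print.gene_region <- function(x, ...) {
  cat(sprintf("<gene_region> %s %s:[%s,%s) flank %s%s\n", x$gene_symbol,
              x$chrom, format(x$start), format(x$end), format(x$flank),
              if (length(x$merged_with)) {
                paste0(" (merged with ", paste(x$merged_with, collapse = ","), ")")
              } else ""))
  invisible(x)
}

#' Restrict a summary-statistic set to a gene region
#'
#' Keeps exactly the variants whose 0-based coordinate `pos - 1` falls in the
#' half-open flanked interval `[start - flank, end + flank)` on the matching
#' chromosome. An empty result is returned, not raised.
#'
#' @param ss A [sumstat_set()].
#' @param region A [gene_region()].
#' @return A [sumstat_set()] with the retained variants.
#' @export
subset_region <- function(ss, region) {
  v <- ss$variants
  pos0 <- v$pos - 1
  keep <- v$chrom == region$chrom &
    pos0 >= region$start - region$flank &
    pos0 < region$end + region$flank
  out <- ss
  out$variants <- v[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out
}

#' Read gene annotations from a BED3+ table
#'
#' Tab-delimited, headerless: chrom, start, end, name, and optionally a fifth
#' comma-separated column of co-located gene symbols.
#'
#' @param path File path.
#' @return Named list of [gene_region()] objects.
#' @export
read_genes_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED format error: need chrom, start, end, name")
  regions <- lapply(seq_len(nrow(df)), function(i) {
    merged <- if (ncol(df) >= 5L && nzchar(df[i, 5L]) && !is.na(df[i, 5L])) {
      strsplit(df[i, 5L], ",", fixed = TRUE)[[1L]]
    }
    gene_region(df[i, 4L], df[i, 1L], df[i, 2L], df[i, 3L],
                merged_with = merged)
  })
  names(regions) <- df[[4L]]
  regions
}

#' Write gene annotations as a BED4(+1) table
#'
#' @param regions Named list of [gene_region()] objects.
#' @param path Output file path.
#' @export
write_genes_bed <- function(regions, path) {
  rows <- vapply(regions, function(r) {
    paste(r$chrom, format(r$start, scientific = FALSE),
          format(r$end, scientific = FALSE), r$gene_symbol,
          paste(r$merged_with %||% character(), collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
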