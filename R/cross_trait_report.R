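# Cross-trait contextualization and final prioritization:
# the proxy-by-protein association library, the VTE-versus-outcome z-score
# comparison, and the conjunction verdict combining MR and colocalization.

#' Build the proxy-by-protein cross-trait association matrix
#'
#' Looks up every selected proxy variant in every protein GWAS (per cohort).
#' Missing measurements are explicit gaps. The Bonferroni family counts the
#' number of distinct (variant, protein) pairs with at least one measurement
#' — so 46 variants fully crossed with 30 proteins gives 1380 tests — and
#' the significance mask applies the resulting per-test alpha to every cell.
#'
#' @param proxies List (possibly nested) of `proxy_set` objects.
#' @param protein_sets Named list of protein [sumstat_set()] objects (one per
#'   protein x cohort).
#' @return Object of class `cross_trait_matrix`: `beta`, `se`, `pval`,
#'   `mask` matrices (rows = variants, columns = protein x cohort),
#'   `n_tests`, `plan` ([bonferroni()]), column metadata `columns`.
#' @export
build_cross_trait <- function(proxies, protein_sets) {
  sets <- list()
  walk <- function(x) {
    if (inherits(x, "proxy_set")) sets[[length(sets) + 1L]] <<- x
    else if (is.list(x)) lapply(x, walk)
  }
  walk(proxies)
  vdf <- do.call(rbind, lapply(sets, function(p) {
    p$variants[, c("variant_id", "chrom", "pos")]
  }))
  vdf <- unique(vdf)
  vdf <- vdf[order(vdf$chrom, vdf$pos), , drop = FALSE]
  vids <- vdf$variant_id

  cols <- data.frame(
    column = names(protein_sets),
    protein = vapply(protein_sets, function(s) s$trait_id, character(1)),
    cohort = vapply(protein_sets, function(s) s$cohort_label, character(1)),
    stringsAsFactors = FALSE)
  mk <- function() matrix(NA_real_, length(vids), nrow(cols),
                          dimnames = list(vids, cols$column))
  beta <- mk(); se <- mk(); pval <- mk()
  for (j in seq_len(nrow(cols))) {
    sv <- protein_sets[[cols$column[j]]]$variants
    i <- match(vids, sv$variant_id)
    beta[, j] <- sv$beta[i]
    se[, j] <- sv$se[i]
    pval[, j] <- sv$pval[i]
  }
  # family size: distinct (variant, protein) pairs with >= 1 measurement
  measured <- !is.na(pval)
  pair_measured <- vapply(unique(cols$protein), function(pr) {
    rowSums(measured[, cols$protein == pr, drop = FALSE]) > 0
  }, logical(length(vids)))
  n_tests <- sum(pair_measured)
  plan <- bonferroni(n_tests)
  structure(list(beta = beta, se = se, pval = pval,
                 mask = !is.na(pval) & pval < plan$alpha_per_test,
                 n_tests = n_tests, plan = plan, columns = cols,
                 variants = vdf),
            class = "cross_trait_matrix")
}

#' Compare proxy z-scores between VTE and an outcome
#'
#' For each proxy variant, pairs the VTE z-score (x axis) with the outcome
#' z-score (y axis) and classifies it as `both`, `vte_only`, `outcome_only`
#' or `neither` by |z| against the cutoff `qnorm(1 - alpha/2)` implied by
#' the MR significance threshold. Variants missing from either set are
#' dropped with a warning.
#'
#' @param proxies List (possibly nested) of `proxy_set` objects.
#' @param vte_ss,outcome_ss [sumstat_set()] objects.
#' @param alpha Two-sided significance level defining the cutoff (default
#'   the study's 0.05/30).
#' @return Object of class `z_comparison`: per-variant table with `z_vte`,
#'   `z_outcome`, `category`; plus `cutoff` and `alpha`.
#' @export
compare_z <- function(proxies, vte_ss, outcome_ss, alpha = 0.05 / 30) {
  sets <- list()
  walk <- function(x) {
    if (inherits(x, "proxy_set")) sets[[length(sets) + 1L]] <<- x
    else if (is.list(x)) lapply(x, walk)
  }
  walk(proxies)
  lab <- do.call(rbind, lapply(sets, function(p) {
    if (nrow(p$variants) == 0L) return(NULL)
    data.frame(variant_id = p$variants$variant_id, protein = p$protein_id,
               source = p$source, stringsAsFactors = FALSE)
  }))
  lab <- lab[!duplicated(lab$variant_id), , drop = FALSE]
  vi <- match(lab$variant_id, vte_ss$variants$variant_id)
  oi <- match(lab$variant_id, outcome_ss$variants$variant_id)
  drop <- is.na(vi) | is.na(oi)
  if (any(drop)) {
    warning(sum(drop), " proxy variant(s) missing from VTE or outcome set",
            call. = FALSE)
  }
  lab <- lab[!drop, , drop = FALSE]; vi <- vi[!drop]; oi <- oi[!drop]
  z_vte <- vte_ss$variants$beta[vi] / vte_ss$variants$se[vi]
  z_out <- outcome_ss$variants$beta[oi] / outcome_ss$variants$se[oi]
  cutoff <- stats::qnorm(1 - alpha / 2)
  category <- ifelse(abs(z_vte) >= cutoff & abs(z_out) >= cutoff, "both",
              ifelse(abs(z_vte) >= cutoff, "vte_only",
              ifelse(abs(z_out) >= cutoff, "outcome_only", "neither")))
  structure(list(table = data.frame(lab, z_vte = z_vte, z_outcome = z_out,
                                    category = category,
                                    stringsAsFactors = FALSE),
                 cutoff = cutoff, alpha = alpha),
            class = "z_comparison")
}

#' Conjunction prioritization of proteins
#'
#' A protein/outcome pair is `prioritized` iff its MR p-value beats the
#' family-wise per-test alpha AND the colocalization posterior for a shared
#' causal variant reaches `pp_min`; pairs with MR evidence but no
#' colocalization result are `incomplete`, never prioritized. The report is
#' sorted by verdict, then MR p-value.
#'
#' @param mr_results `data.frame` with columns `protein`, `source`,
#'   `outcome`, `pval` (plus any estimate columns, carried through).
#' @param coloc_results `data.frame` with columns `protein`, `outcome`,
#'   `pp_h4`.
#' @param plan A [bonferroni()] multiplicity plan.
#' @param pp_min Minimum shared-variant posterior (default 0.7).
#' @return `data.frame` of class `prioritization` with `verdict` column
#'   (`prioritized`, `not_prioritized`, `incomplete`).
#' @export
prioritize <- function(mr_results, coloc_results, plan, pp_min = 0.7) {
  key <- paste(mr_results$protein, mr_results$outcome, sep = "\r")
  ckey <- paste(coloc_results$protein, coloc_results$outcome, sep = "\r")
  pp <- coloc_results$pp_h4[match(key, ckey)]
  mr_sig <- mr_results$pval < plan$alpha_per_test
  verdict <- ifelse(is.na(pp), ifelse(mr_sig, "incomplete", "not_prioritized"),
                    ifelse(mr_sig & pp >= pp_min, "prioritized",
                           "not_prioritized"))
  out <- cbind(mr_results, pp_h4 = pp, mr_alpha = plan$alpha_per_test,
               pp_min = pp_min, verdict = verdict)
  out <- out[order(factor(verdict, c("prioritized", "incomplete",
                                     "not_prioritized")), out$pval), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("prioritization", class(out))
  out
}
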