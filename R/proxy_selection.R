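# Instrument (genetic proxy) selection: the filter cascade and LD clumping.
#
# Three proxy sources mirror the study design: pQTLs from each proteomics
# cohort and disease-liability proxies taken directly from the VTE GWAS.
# The cascade applied per source is
#   cis window -> genome-wide significance -> MAF floor -> outcome overlap
#   -> nominal VTE support -> greedy LD clumping,
# and an audit trail records in/out counts at each stage.

filter_log <- function(ss) {
  attr(ss, "filter_log") %||%
    data.frame(stage = character(), n_in = integer(), n_out = integer(),
               note = character(), stringsAsFactors = FALSE)
}

log_stage <- function(ss, stage, n_in, n_out, note = "") {
  lg <- rbind(filter_log(ss),
              data.frame(stage = stage, n_in = n_in, n_out = n_out,
                         note = note, stringsAsFactors = FALSE))
  attr(ss, "filter_log") <- lg
  ss
}

keep_rows <- function(ss, keep, stage, note = "") {
  out <- ss
  out$variants <- ss$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  attr(out, "filter_log") <- filter_log(ss)
  log_stage(out, stage, nrow(ss$variants), nrow(out$variants), note)
}

#' Filter on association p-value
#'
#' Retains records with `pval < threshold` (the genome-wide significance
#' convention, default threshold 5e-8).
#'
#' @param ss A [sumstat_set()].
#' @param threshold P-value threshold in (0, 1\].
#' @return Filtered [sumstat_set()] with the stage appended to its audit log.
#' @export
filter_significance <- function(ss, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold <= 1)
  keep_rows(ss, ss$variants$pval < threshold, "significance",
            sprintf("p < %g", threshold))
}

#' Filter on minor allele frequency
#'
#' Retains records with `min(eaf, 1 - eaf) >= floor`. Records with missing
#' `eaf` are excluded with a warning, since their MAF cannot be checked.
#'
#' @param ss A [sumstat_set()].
#' @param floor MAF floor in \[0, 0.5\].
#' @return Filtered [sumstat_set()].
#' @export
filter_maf <- function(ss, floor = 0.01) {
  stopifnot(floor >= 0, floor <= 0.5)
  eaf <- ss$variants$eaf
  miss <- is.na(eaf)
  if (any(miss)) {
    warning(sum(miss), " record(s) with missing eaf excluded by MAF filter",
            call. = FALSE)
  }
  keep <- !miss & pmin(eaf, 1 - eaf) >= floor
  keep_rows(ss, keep, "maf", sprintf("MAF >= %g", floor))
}

#' Filter exposure variants on nominal liability (VTE) support
#'
#' Retains exposure records whose variant shows at least nominal association
#' (`pval < alpha`) with the disease-liability trait, enhancing functional
#' relevance to coagulation. Variants absent from the liability set are
#' excluded and counted separately. `enabled = FALSE` reproduces the
#' sensitivity analysis that omits this step (the filter becomes the
#' identity).
#'
#' @param exposure_ss Exposure [sumstat_set()].
#' @param liability_ss Liability-trait [sumstat_set()].
#' @param alpha Nominal p-value threshold (default 0.05).
#' @param enabled Set `FALSE` to disable the filter.
#' @return Filtered exposure [sumstat_set()].
#' @export
filter_liability_support <- function(exposure_ss, liability_ss, alpha = 0.05,
                                     enabled = TRUE) {
  if (!enabled) {
    return(log_stage(exposure_ss, "liability_support",
                     nrow(exposure_ss$variants), nrow(exposure_ss$variants),
                     "disabled"))
  }
  stopifnot(alpha > 0, alpha < 1)
  idx <- match(exposure_ss$variants$variant_id, liability_ss$variants$variant_id)
  present <- !is.na(idx)
  supported <- present & liability_ss$variants$pval[idx] < alpha
  out <- keep_rows(exposure_ss, supported, "liability_support",
                   sprintf("liability p < %g; %d absent from liability set",
                           alpha, sum(!present)))
  out
}

#' Greedy LD clumping
#'
#' Orders candidates by ascending p-value (ties by position, then variant
#' id), repeatedly takes the best remaining variant as an index and discards
#' every remaining variant with `r^2 >= r2_max` against it (r squared from
#' the signed LD correlation). The retained set is pairwise approximately
#' independent: every pair has `r^2 < r2_max`.
#'
#' @param ss A [sumstat_set()]; every variant must appear in `ld`.
#' @param ld Named LD matrix.
#' @param r2_max Clumping threshold (default 0.001).
#' @param protein_id,source Labels carried into the resulting proxy set.
#' @return A `proxy_set`: list with `protein_id`, `source`, `variants`
#'   (retained exposure records), `clump_r2`, `filters_applied` (audit trail)
#'   and `no_proxy` flag.
#' @export
clump <- function(ss, ld, r2_max = 0.001, protein_id = ss$trait_id,
                  source = ss$cohort_label) {
  v <- ss$variants
  absent <- setdiff(v$variant_id, rownames(ld))
  if (length(absent) > 0L) {
    stop("variant(s) missing from LD matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  }
  # ascending p; exact ties (e.g. p-values saturated at the text-format
  # floor) are refined by descending |z| so the strongest peak still leads,
  # then position and id for determinism
  ord <- order(v$pval, -abs(v$beta / v$se), v$pos, v$variant_id)
  remaining <- ord
  kept <- integer()
  while (length(remaining) > 0L) {
    i <- remaining[1L]
    kept <- c(kept, i)
    r <- ld[v$variant_id[remaining], v$variant_id[i]]
    remaining <- remaining[r^2 < r2_max & remaining != i]
  }
  kept <- sort(kept)
  out <- keep_rows(ss, kept, "clump", sprintf("r2 < %g", r2_max))
  proxy_set(protein_id, source, out$variants, clump_r2 = r2_max,
            filters_applied = filter_log(out))
}

#' @rdname clump
#' @param variants Retained exposure records.
#' @param clump_r2 Threshold used.
#' @param filters_applied Audit trail `data.frame`.
#' @param liability Optional matching liability-trait records.
#' @export
proxy_set <- function(protein_id, source, variants, clump_r2,
                      filters_applied = NULL, liability = NULL) {
  structure(list(protein_id = protein_id, source = source,
                 variants = variants, liability = liability,
                 clump_r2 = clump_r2,
                 filters_applied = filters_applied,
                 no_proxy = nrow(variants) == 0L),
            class = "proxy_set")
}

#' @export
print.proxy_set <- function(x, ...) {
  cat(sprintf("<proxy_set> %s [%s]: %d proxies%s\n", x$protein_id, x$source,
              nrow(x$variants), if (x$no_proxy) " (no proxy)" else ""))
  invisible(x)
}

#' Bundle the proxy-selection thresholds
#'
#' Defaults are the study's analytic choices: genome-wide significance 5e-8,
#' MAF floor 0.01, nominal VTE support at 0.05, clumping at r^2 < 0.001.
#'
#' @param pthresh Significance threshold.
#' @param maf_floor MAF floor.
#' @param liability_alpha Nominal liability-support threshold.
#' @param clump_r2 Clumping r^2 threshold.
#' @param use_liability_filter Disable for the sensitivity analysis.
#' @return list of parameters.
#' @export
proxy_params <- function(pthresh = 5e-8, maf_floor = 0.01,
                         liability_alpha = 0.05, clump_r2 = 0.001,
                         use_liability_filter = TRUE) {
  list(pthresh = pthresh, maf_floor = maf_floor,
       liability_alpha = liability_alpha, clump_r2 = clump_r2,
       use_liability_filter = use_liability_filter)
}

#' Select genetic proxies for one protein from every source
#'
#' Applies, per source and in order: cis-region subsetting, genome-wide
#' significance, MAF floor, intersection with the outcome data set (variants
#' absent from the outcome GWAS cannot be analyzed), nominal liability
#' support, and greedy LD clumping. An empty final set is returned flagged
#' `no_proxy`, not raised — proteins without a proxy simply drop out of MR,
#' which is how partial proteome coverage arises.
#'
#' @param protein_id Protein identifier.
#' @param sources Named list of exposure [sumstat_set()] objects (pQTL
#'   cohorts and/or the liability GWAS itself as source `"liability"`).
#' @param liability_ss Liability-trait [sumstat_set()] used by the support
#'   filter.
#' @param outcome_ss Outcome [sumstat_set()] defining the available variant
#'   universe.
#' @param region The protein's cis [gene_region()].
#' @param ld Named LD matrix covering the region's variants.
#' @param params A [proxy_params()] bundle.
#' @return Named list of `proxy_set` objects, one per source.
#' @export
select_proxies <- function(protein_id, sources, liability_ss, outcome_ss,
                           region, ld, params = proxy_params()) {
  stopifnot(length(sources) >= 1L, !is.null(names(sources)))
  lapply(stats::setNames(names(sources), names(sources)), function(src) {
    cur <- subset_region(sources[[src]], region)
    cur <- log_stage(cur, "cis_region", nrow(sources[[src]]$variants),
                     nrow(cur$variants), region$gene_symbol)
    cur <- filter_significance(cur, params$pthresh)
    cur <- filter_maf(cur, params$maf_floor)
    cur <- keep_rows(cur,
                     cur$variants$variant_id %in% outcome_ss$variants$variant_id,
                     "outcome_overlap", outcome_ss$trait_id)
    cur <- filter_liability_support(cur, liability_ss,
                                    alpha = params$liability_alpha,
                                    enabled = params$use_liability_filter)
    ps <- clump(cur, ld, params$clump_r2, protein_id = protein_id,
                source = src)
    li <- match(ps$variants$variant_id, liability_ss$variants$variant_id)
    ps$liability <- liability_ss$variants[li[!is.na(li)], , drop = FALSE]
    ps
  })
}

#' Export a proxy-selection audit trail as JSON
#'
#' @param proxies Named list (or list of named lists) of `proxy_set` objects.
#' @param path Output JSON path.
#' @export
write_proxy_audit <- function(proxies, path) {
  flat <- list()
  walk <- function(x) {
    if (inherits(x, "proxy_set")) {
      flat[[length(flat) + 1L]] <<- list(
        protein = x$protein_id, source = x$source, no_proxy = x$no_proxy,
        n_proxies = nrow(x$variants), clump_r2 = x$clump_r2,
        proxies = x$variants$variant_id, filters = x$filters_applied)
    } else if (is.list(x)) lapply(x, walk)
  }
  walk(proxies)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
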