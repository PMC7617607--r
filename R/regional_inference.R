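# Regional analyses used to disambiguate causal genes: pairwise Bayesian
# colocalization by enumeration over single-causal-variant configurations,
# summary-statistic conditional analysis, single-signal fine-mapping, and
# stepwise signal counting.

#' Assemble a regional dataset
#'
#' Restricts two or more traits to a shared, identically ordered variant list
#' covered by one LD matrix — the unit of colocalization, conditioning and
#' fine-mapping. Variants absent from any trait or from the LD matrix are
#' dropped; the retained order follows the LD matrix.
#'
#' @param region A [gene_region()].
#' @param traits Named list of [sumstat_set()] objects (>= 2 for
#'   colocalization; 1 suffices for fine-mapping/conditioning).
#' @param ld Named LD matrix.
#' @return Object of class `regional_dataset` with aligned `traits` and `ld`.
#' @export
regional_dataset <- function(region, traits, ld) {
  stopifnot(length(traits) >= 1L, !is.null(names(traits)))
  traits <- lapply(traits, subset_region, region = region)
  shared <- Reduce(intersect, lapply(traits, function(s) s$variants$variant_id))
  shared <- rownames(ld)[rownames(ld) %in% shared]
  if (length(shared) == 0L) stop("no shared variants in region")
  traits <- lapply(traits, function(s) {
    s$variants <- s$variants[match(shared, s$variants$variant_id), ,
                             drop = FALSE]
    rownames(s$variants) <- NULL
    if (anyNA(s$variants$beta)) stop("missing betas in regional dataset")
    s
  })
  structure(list(region = region, traits = traits,
                 ld = ld[shared, shared, drop = FALSE]),
            class = "regional_dataset")
}

#' Wakefield log approximate Bayes factor
#'
#' Evidence for association versus the null for one variant, from its
#' z-score and standard error under a `N(0, prior_sd^2)` effect prior:
#' with `V = se^2`, `W = prior_sd^2` and shrinkage `r = W/(V+W)`,
#' `log BF = 0.5 log(1 - r) + 0.5 r z^2`.
#'
#' @param z Z-score(s).
#' @param se Standard error(s) (> 0).
#' @param prior_sd Prior effect SD (> 0).
#' @return log Bayes factor(s), vectorized.
#' @export
log_abf <- function(z, se, prior_sd) {
  stopifnot(all(se > 0), prior_sd > 0)
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * log1p(-r) + 0.5 * r * z^2
}

#' Default effect-scale priors by trait type
#'
#' 0.15 SD for quantitative traits and 0.2 log-odds for binary traits —
#' field-standard colocalization defaults.
#'
#' @param trait_type `"quantitative"` or `"binary"`.
#' @return Prior effect SD.
#' @export
default_prior_sd <- function(trait_type) {
  ifelse(trait_type == "binary", 0.2, 0.15)
}

#' Pairwise Bayesian colocalization by enumeration
#'
#' Under the assumption of at most one causal variant per trait, enumerates
#' all single-variant configurations: per-variant Wakefield log ABFs feed the
#' five hypothesis sums — H0 (neither trait associated), H1/H2 (one trait
#' only), H3 (both, distinct causal variants), H4 (both, one shared causal
#' variant) — weighted by per-variant prior probabilities `p1`, `p2` (single
#' trait) and `p12` (shared). Posteriors are normalized on the log scale
#' with log-sum-exp.
#'
#' @param data A [regional_dataset()] with exactly two traits.
#' @param p1,p2,p12 Per-variant prior probabilities (defaults 1e-4, 1e-4,
#'   1e-5).
#' @param prior_sd Length-2 effect-prior SDs; defaults from
#'   [default_prior_sd()] of each trait's type.
#' @return Object of class `coloc_result`: posterior vector `pp`
#'   (`PP.H0..PP.H4`, sums to 1), priors, prior SDs, variant count.
#' @export
coloc_pair <- function(data, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       prior_sd = NULL) {
  if (length(data$traits) != 2L) {
    stop("coloc_pair takes exactly 2 traits; call it per pair")
  }
  if (is.null(prior_sd)) {
    prior_sd <- vapply(data$traits, function(s) default_prior_sd(s$trait_type),
                       numeric(1))
  }
  l1 <- with(data$traits[[1L]]$variants, log_abf(beta / se, se, prior_sd[1L]))
  l2 <- with(data$traits[[2L]]$variants, log_abf(beta / se, se, prior_sd[2L]))
  L1 <- logsumexp(l1)
  L2 <- logsumexp(l2)
  L12 <- logsumexp(l1 + l2)
  lh <- c(H0 = 0,
          H1 = log(p1) + L1,
          H2 = log(p2) + L2,
          H3 = log(p1) + log(p2) + {
            # sum over j != k equals S1*S2 - S12; keep it on the log scale
            d <- L12 - (L1 + L2)
            if (d >= 0) -Inf else L1 + L2 + log1p(-exp(d))
          },
          H4 = log(p12) + L12)
  pp <- exp(lh - logsumexp(lh))
  structure(list(pp = stats::setNames(pp, paste0("PP.", names(lh))),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = prior_sd,
                 n_variants = length(l1),
                 traits = names(data$traits)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %s vs %s (m=%d): %s\n", x$traits[1L],
              x$traits[2L], x$n_variants,
              paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " ")))
  invisible(x)
}

# core conditional-z projection given marginal z and the correlations r with
# the index variant; index's own conditional z is 0 by construction
cond_z_core <- function(z, r, index) {
  estimable <- abs(r) < 1 - 1e-10
  zc <- rep(NA_real_, length(z))
  zc[estimable] <- (z[estimable] - r[estimable] * z[index]) /
    sqrt(1 - r[estimable]^2)
  zc[index] <- 0
  list(z = zc, estimable = estimable | seq_along(z) == index)
}

#' Conditional z-scores given an index variant
#'
#' Approximate summary-statistic conditional analysis assuming standardized
#' genotypes: `z_cond_j = (z_j - r_j,idx z_idx) / sqrt(1 - r_j,idx^2)`. The
#' index variant's own conditional z is 0. Variants in perfect LD with the
#' index are flagged inestimable (`NA`), and excluded from any residual
#' significance test.
#'
#' @param data A [regional_dataset()].
#' @param trait Name of the trait to condition.
#' @param index_variant Variant id of the conditioning index.
#' @return `data.frame`: `variant_id`, `z_cond`, `pval_cond` (two-sided
#'   normal), `estimable`.
#' @export
conditional_z <- function(data, trait, index_variant) {
  v <- data$traits[[trait]]$variants
  idx <- match(index_variant, v$variant_id)
  if (is.na(idx)) stop("index variant ", index_variant, " not in region")
  z <- v$beta / v$se
  r <- data$ld[, idx]
  cc <- cond_z_core(z, r, idx)
  data.frame(variant_id = v$variant_id, z_cond = cc$z,
             pval_cond = 2 * stats::pnorm(-abs(cc$z)),
             estimable = cc$estimable, stringsAsFactors = FALSE)
}

#' Single-signal fine-mapping credible set
#'
#' Under a single-causal-variant assumption with a uniform prior over
#' variants, the posterior inclusion probability is
#' `PIP_j = BF_j / sum_k BF_k`. The credible set is the smallest prefix of
#' the descending-PIP ordering (ties broken by position) whose cumulative
#' mass reaches the coverage target.
#'
#' @param data A [regional_dataset()].
#' @param trait Trait name.
#' @param prior_sd Effect prior SD (default by trait type).
#' @param coverage Credible-set coverage target (default 0.95).
#' @return Object of class `credible_set`: per-variant `pip` table (in
#'   credible-set order), `credible_set` ids, achieved `mass`, `coverage`.
#' @export
finemap_single <- function(data, trait, prior_sd = NULL, coverage = 0.95) {
  s <- data$traits[[trait]]
  if (is.null(prior_sd)) prior_sd <- default_prior_sd(s$trait_type)
  v <- s$variants
  l <- log_abf(v$beta / v$se, v$se, prior_sd)
  pip <- exp(l - logsumexp(l))
  ord <- order(-pip, v$pos)
  cum <- cumsum(pip[ord])
  k <- which(cum >= coverage)[1L]
  if (is.na(k)) k <- length(pip)
  tab <- data.frame(variant_id = v$variant_id[ord], pos = v$pos[ord],
                    pip = pip[ord], cumulative = cum,
                    in_credible_set = seq_along(ord) <= k,
                    stringsAsFactors = FALSE)
  structure(list(pip = tab, credible_set = tab$variant_id[seq_len(k)],
                 mass = cum[k], coverage = coverage, trait = trait),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("<credible_set> %s: %d variant(s), mass %.3f (target %.2f)\n",
              x$trait, length(x$credible_set), x$mass, x$coverage))
  invisible(x)
}

#' Count independent association signals by stepwise conditioning
#'
#' Repeatedly finds the minimum-p variant; if its p-value is below `stop_p`
#' a signal is recorded and the z-scores (and LD) are replaced by their
#' conditional counterparts given that index, until no variant remains below
#' the threshold. `stop_p` defaults to the regional Bonferroni `0.05 / m`.
#'
#' @param data A [regional_dataset()].
#' @param trait Trait name.
#' @param prior_sd Effect prior SD recorded per signal (annotation only; the
#'   stepwise search itself is p-value driven).
#' @param stop_p Stopping threshold in (0, 1).
#' @return list: `n_signals`, `signals` (`data.frame` of index variants with
#'   the z/p at selection and log ABF), `stop_p`.
#' @export
count_signals <- function(data, trait, prior_sd = NULL, stop_p = NULL) {
  s <- data$traits[[trait]]
  v <- s$variants
  m <- nrow(v)
  if (is.null(stop_p)) stop_p <- 0.05 / m
  stopifnot(stop_p > 0, stop_p < 1)
  if (is.null(prior_sd)) prior_sd <- default_prior_sd(s$trait_type)
  z <- v$beta / v$se
  R <- data$ld
  active <- rep(TRUE, m)
  sig <- list()
  for (step in seq_len(m)) {
    p <- 2 * stats::pnorm(-abs(z))
    p[!active] <- 1
    # rank on |z|: equivalent to min p but immune to p-value underflow
    za <- abs(z)
    za[!active] <- 0
    i <- which.max(za)
    if (p[i] >= stop_p) break
    sig[[step]] <- data.frame(
      variant_id = v$variant_id[i], step = step, z = z[i], pval = p[i],
      log_abf = log_abf(z[i], v$se[i], prior_sd), stringsAsFactors = FALSE)
    r <- R[, i]
    cc <- cond_z_core(z, r, i)
    z <- cc$z
    active <- active & cc$estimable
    active[i] <- FALSE
    z[!active] <- 0
    # partial correlations given the index, for subsequent steps
    den <- sqrt(pmax(1 - r^2, 1e-12))
    R <- (R - outer(r, r)) / outer(den, den)
    diag(R) <- 1
  }
  signals <- if (length(sig)) do.call(rbind, sig) else
    data.frame(variant_id = character(), step = integer(), z = numeric(),
               pval = numeric(), log_abf = numeric(), stringsAsFactors = FALSE)
  list(n_signals = nrow(signals), signals = signals, stop_p = stop_p)
}

#' Condition a whole regional dataset on an index variant
#'
#' Returns a new [regional_dataset()] in which every trait's z-scores are
#' replaced by their conditional counterparts given the index (betas are
#' rebuilt as `z_cond * se`) and the LD matrix is replaced by the partial
#' correlations given the index. Conditioning the result on the same index
#' again is a no-op (the projection is idempotent). Variants in perfect LD
#' with the index are dropped as inestimable.
#'
#' @param data A [regional_dataset()].
#' @param index_variant Variant id of the conditioning index.
#' @return A conditioned [regional_dataset()].
#' @export
condition_dataset <- function(data, index_variant) {
  v1 <- data$traits[[1L]]$variants
  idx <- match(index_variant, v1$variant_id)
  if (is.na(idx)) stop("index variant ", index_variant, " not in region")
  r <- data$ld[, idx]
  estimable <- abs(r) < 1 - 1e-10
  estimable[idx] <- TRUE
  out <- data
  out$traits <- lapply(data$traits, function(s) {
    z <- s$variants$beta / s$variants$se
    cc <- cond_z_core(z, r, idx)
    s$variants$beta <- cc$z * s$variants$se
    s$variants$pval <- pmax(2 * stats::pnorm(-abs(cc$z)), 1e-300)
    s$variants <- s$variants[estimable, , drop = FALSE]
    rownames(s$variants) <- NULL
    s
  })
  den <- sqrt(pmax(1 - r^2, 1e-12))
  Rp <- (data$ld - outer(r, r)) / outer(den, den)
  diag(Rp) <- 1
  Rp[idx, ] <- 0
  Rp[, idx] <- 0
  diag(Rp) <- 1
  out$ld <- Rp[estimable, estimable, drop = FALSE]
  out
}

#' Per-variant regional association table for plotting
#'
#' (position, -log10 p, r^2 to a lead variant) — the data behind a regional
#' association ("LocusZoom-style") plot.
#'
#' @param data A [regional_dataset()].
#' @param trait Trait name.
#' @param lead Variant id to compute r^2 against (default: min-p variant).
#' @return `data.frame` with `variant_id`, `pos`, `neglog10p`, `r2_lead`.
#' @export
regional_plot_table <- function(data, trait, lead = NULL) {
  v <- data$traits[[trait]]$variants
  if (is.null(lead)) lead <- v$variant_id[which.min(v$pval)]
  li <- match(lead, v$variant_id)
  data.frame(variant_id = v$variant_id, pos = v$pos,
             neglog10p = -log10(v$pval), r2_lead = data$ld[, li]^2,
             lead = v$variant_id == lead, stringsAsFactors = FALSE)
}
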