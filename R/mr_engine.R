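# Causal-effect estimation from harmonized summary statistics.
#
# Single instrument: Wald ratio with first-order delta-method SE. Multiple
# instruments: inverse-variance weighted (IVW) regression of the SNP-outcome
# log-odds on the SNP-exposure association, constrained through the origin
# and weighted by 1/se_outcome^2, with multiplicative random effects — the
# SE is inflated by sqrt(max(1, Q/(J-1))) so over-dispersion widens the
# interval but can never shrink it below the fixed-effect SE. Multivariable
# MR generalizes the same weighted regression to K exposure columns.

new_mr_estimate <- function(theta, se, method, n_variants, Q = NA_real_,
                            phi = 1, exposure_scale = "per_sd") {
  z <- theta / se
  structure(list(theta = theta, se = se,
                 ci_low = theta - stats::qnorm(0.975) * se,
                 ci_high = theta + stats::qnorm(0.975) * se,
                 pval = 2 * stats::pnorm(-abs(z)),
                 or = exp(theta),
                 or_ci_low = exp(theta - stats::qnorm(0.975) * se),
                 or_ci_high = exp(theta + stats::qnorm(0.975) * se),
                 method = method, n_variants = as.integer(n_variants),
                 Q = Q, phi = phi, exposure_scale = exposure_scale),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s (J=%d, %s): OR %.2f [%.2f, %.2f], p = %.3g%s\n",
    x$method, x$n_variants, x$exposure_scale, x$or, x$or_ci_low, x$or_ci_high,
    x$pval,
    if (!is.na(x$Q)) sprintf(", Q = %.2f, phi = %.2f", x$Q, x$phi) else ""))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(theta = x$theta, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, pval = x$pval, or = x$or,
             or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
             method = x$method, n_variants = x$n_variants, Q = x$Q,
             phi = x$phi, exposure_scale = x$exposure_scale,
             stringsAsFactors = FALSE)
}

#' Wald ratio estimate from a single harmonized variant
#'
#' `theta = beta_outcome / beta_exposure` with the first-order delta-method
#' standard error `se = se_outcome / |beta_exposure|`; 95% Wald CI and
#' two-sided normal p-value.
#'
#' @param pair One harmonized pair (1-row `data.frame` with `beta_exposure`,
#'   `beta_outcome`, `se_outcome`).
#' @param exposure_scale Scale annotation carried into the estimate.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(pair, exposure_scale = "per_sd") {
  if (nrow(as.data.frame(pair)) != 1L) stop("wald_ratio takes a single pair")
  bx <- pair$beta_exposure
  if (bx == 0) stop("undefined ratio: beta_exposure is 0")
  new_mr_estimate(theta = pair$beta_outcome / bx,
                  se = pair$se_outcome / abs(bx),
                  method = "wald", n_variants = 1L,
                  exposure_scale = exposure_scale)
}

#' Random-effects inverse-variance weighted estimate
#'
#' Origin-constrained weighted regression of outcome on exposure betas with
#' weights `1/se_outcome^2`:
#' `theta = sum(w bx by) / sum(w bx^2)`, fixed-effect
#' `se = sqrt(1 / sum(w bx^2))`, Cochran's
#' `Q = sum(w (by - theta bx)^2)`, multiplicative inflation
#' `phi = max(1, Q/(J-1))`, final `se = fixed se * sqrt(phi)`. A single pair
#' reduces exactly to the Wald ratio.
#'
#' @param pairs Harmonized pairs (`data.frame`, one row per variant; excluded
#'   rows should already be dropped).
#' @inheritParams wald_ratio
#' @return An `mr_estimate`.
#' @export
ivw <- function(pairs, exposure_scale = "per_sd") {
  pairs <- as.data.frame(pairs)
  J <- nrow(pairs)
  if (J == 0L) stop("ivw requires at least one harmonized pair")
  if (J == 1L) return(wald_ratio(pairs, exposure_scale))
  bx <- pairs$beta_exposure
  by <- pairs$beta_outcome
  if (all(bx == 0)) stop("undefined ratio: all exposure betas are 0")
  w <- 1 / pairs$se_outcome^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  se_fe <- sqrt(1 / sum(w * bx^2))
  Q <- sum(w * (by - theta * bx)^2)
  phi <- max(1, Q / (J - 1))
  new_mr_estimate(theta = theta, se = se_fe * sqrt(phi), method = "ivw",
                  n_variants = J, Q = Q, phi = phi,
                  exposure_scale = exposure_scale)
}

#' Multivariable MR by origin-constrained weighted least squares
#'
#' Regresses the outcome betas jointly on K exposure-beta columns with
#' weights `1/se_outcome^2` and no intercept, isolating each exposure's
#' direct effect. SEs come from the weighted information matrix, inflated by
#' the multiplicative rule `phi = max(1, Q/(J-K))`.
#'
#' @param beta_exposures J x K numeric matrix (one column per exposure;
#'   column names name the exposures).
#' @param beta_outcome,se_outcome Length-J outcome association and SE.
#' @return Named list of `mr_estimate` objects, one per exposure column.
#' @export
mvmr <- function(beta_exposures, beta_outcome, se_outcome) {
  BX <- as.matrix(beta_exposures)
  J <- nrow(BX); K <- ncol(BX)
  if (J < K) stop("mvmr needs at least as many variants as exposures")
  if (is.null(colnames(BX))) colnames(BX) <- paste0("exposure", seq_len(K))
  w <- 1 / se_outcome^2
  Xw <- BX * sqrt(w)
  qx <- qr(Xw)
  if (qx$rank < K) {
    stop("collinear exposures: ",
         paste(colnames(BX)[qx$pivot[(qx$rank + 1L):K]], collapse = ", "))
  }
  A <- crossprod(Xw)                       # weighted information matrix
  theta <- unname(solve(A, crossprod(BX * w, beta_outcome))[, 1L])
  cov_fe <- solve(A)
  Q <- sum(w * (beta_outcome - BX %*% theta)^2)
  phi <- if (J > K) max(1, Q / (J - K)) else 1
  ses <- unname(sqrt(diag(cov_fe) * phi))
  out <- lapply(seq_len(K), function(k) {
    new_mr_estimate(theta = theta[k], se = ses[k], method = "mvmr",
                    n_variants = J, Q = Q, phi = phi)
  })
  names(out) <- colnames(BX)
  out
}

#' Rescale an estimate to the per-doubling-of-VTE-odds scale
#'
#' For proxies defined by disease (VTE) liability rather than protein level,
#' the natural exposure unit is not an SD of protein. The reported effect is
#' instead the outcome log-odds change accompanying a doubling of VTE odds
#' acting through the locus: the per-allele outcome effect is divided by the
#' per-allele VTE log-odds and multiplied by ln 2, i.e.
#' `theta_per_doubling = (theta / liability_beta) * ln 2`. The SE scales by
#' `ln 2 / |liability_beta|`.
#'
#' @param estimate An `mr_estimate` whose `theta` is on the per-allele
#'   outcome (numerator) scale.
#' @param liability_beta Per-allele VTE log-odds (nonzero).
#' @return The rescaled `mr_estimate` with
#'   `exposure_scale = "per_doubling_liability"`.
#' @export
rescale_per_doubling <- function(estimate, liability_beta) {
  if (liability_beta == 0) stop("liability_beta must be nonzero")
  est <- new_mr_estimate(
    theta = estimate$theta * log(2) / liability_beta,
    se = estimate$se * log(2) / abs(liability_beta),
    method = estimate$method, n_variants = estimate$n_variants,
    Q = estimate$Q, phi = estimate$phi,
    exposure_scale = "per_doubling_liability")
  est
}

#' Bonferroni multiplicity plan
#'
#' `alpha_per_test = 0.05 / n_tests`, with the matching two-sided normal
#' z cutoff. With the study's 30 proteins this gives 0.0017; with the
#' 1380-cell cross-trait library, 3.6e-5.
#'
#' @param n_tests Number of tests in the family.
#' @param alpha_family Family-wise alpha (default 0.05).
#' @return list with `n_tests`, `alpha_family`, `alpha_per_test`, `z_cutoff`.
#' @export
bonferroni <- function(n_tests, alpha_family = 0.05) {
  stopifnot(n_tests >= 1)
  alpha <- alpha_family / n_tests
  list(n_tests = as.integer(n_tests), alpha_family = alpha_family,
       alpha_per_test = alpha,
       z_cutoff = stats::qnorm(1 - alpha / 2))
}
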