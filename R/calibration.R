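# Simulation studies that characterize the pipeline's statistical operating
# points: estimator recovery, type-I error, colocalization calibration,
# conditional-analysis clearance, and end-to-end prioritization recovery.
# These power the acceptance checks and the analysis drivers alike.

ivw_study_config <- function(seed, J, lambda, theta, n_exposure, n_case,
                             n_control) {
  region <- sim_region("GENE", "1", 1e6, 1e6 + 6e4, m = J, rho = 0,
                       freq_range = c(0.1, 0.9))
  sim_config(
    regions = list(GENE = region),
    proteins = list(GENE = sim_protein("GENE", "GENE", seq_len(J), lambda,
                                       cohorts = "expo")),
    cohorts = list(expo = list(n = n_exposure)),
    outcomes = list(out = sim_outcome("out", n_case, n_control,
                                      theta = c(GENE = theta))),
    seed = seed)
}

#' IVW estimator recovery study
#'
#' Repeatedly simulates a protein with `J` independent valid instruments and
#' a binary outcome with causal effect `theta` (log-odds per SD), runs the
#' harmonization-free IVW estimator on the causal variants, and summarizes
#' recovery: mean estimate, Monte-Carlo SE, and empirical 95% CI coverage.
#'
#' @param n_reps Number of replicates.
#' @param J Instruments per replicate.
#' @param theta True log-odds per SD (default `log(1.31)`, a cardioembolic
#'   stroke-sized effect).
#' @param n_exposure Exposure GWAS sample size.
#' @param n_case,n_control Outcome GWAS case/control counts.
#' @param lambda Per-variant instrument strengths (recycled to `J`).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return list: `theta`, `mean_theta`, `mc_se`, `coverage`, `n_reps`,
#'   `estimates`.
#' @export
ivw_recovery_study <- function(n_reps = 500L, J = 20L, theta = log(1.31),
                               n_exposure = 4e4, n_case = 6e3,
                               n_control = 1.2e5,
                               lambda = seq(0.12, 0.3, length.out = J),
                               seed = 1L) {
  lambda <- rep_len(lambda, J) * rep_len(c(1, -1), J)
  est <- matrix(NA_real_, n_reps, 3L,
                dimnames = list(NULL, c("theta", "lo", "hi")))
  for (r in seq_len(n_reps)) {
    cfg <- ivw_study_config(seed + r, J, lambda, theta, n_exposure, n_case,
                            n_control)
    sim <- simulate_sumstats(cfg)
    vx <- sim$sumstats$GENE.expo$variants
    vy <- sim$sumstats$out$variants
    e <- ivw(data.frame(beta_exposure = vx$beta, beta_outcome = vy$beta,
                        se_outcome = vy$se))
    est[r, ] <- c(e$theta, e$ci_low, e$ci_high)
  }
  list(theta = theta, mean_theta = mean(est[, 1L]),
       mc_se = stats::sd(est[, 1L]) / sqrt(n_reps),
       coverage = mean(est[, 2L] <= theta & theta <= est[, 3L]),
       n_reps = n_reps, estimates = est[, 1L])
}

#' IVW type-I error study under the null
#'
#' Valid, strong instruments but `theta = 0`; reports the rejection rate of
#' the two-sided IVW test at `alpha` together with the exact binomial 95%
#' interval for a calibrated test.
#'
#' @inheritParams ivw_recovery_study
#' @param n Outcome (and exposure) scale: exposure n, cases `0.05 n`,
#'   controls `0.95 n` by default.
#' @param alpha Test level (default the study's 0.05/30).
#' @return list: `rate`, `n_rejections`, `binom_low`, `binom_high`, `alpha`,
#'   `n_reps`.
#' @export
ivw_type1_study <- function(n_reps = 1e4, J = 15L, n = 5e4,
                            alpha = 0.05 / 30, seed = 1L) {
  lambda <- rep_len(c(0.2, -0.25, 0.15), J)
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- ivw_study_config(seed + r, J, lambda, theta = 0,
                            n_exposure = n, n_case = round(0.05 * n),
                            n_control = round(0.95 * n))
    sim <- simulate_sumstats(cfg)
    vx <- sim$sumstats$GENE.expo$variants
    vy <- sim$sumstats$out$variants
    e <- ivw(data.frame(beta_exposure = vx$beta, beta_outcome = vy$beta,
                        se_outcome = vy$se))
    rej[r] <- e$pval < alpha
  }
  k <- sum(rej)
  list(rate = k / n_reps, n_rejections = k,
       binom_low = stats::qbinom(0.025, n_reps, alpha),
       binom_high = stats::qbinom(0.975, n_reps, alpha),
       alpha = alpha, n_reps = n_reps)
}

#' Colocalization calibration study
#'
#' `scenario = "shared"`: protein and outcome share one causal variant, both
#' powered to a noncentrality of about 8; reports how often PP(H4) > 0.9.
#' `scenario = "distinct"`: causal variants in linkage equilibrium
#' (separate LD blocks), equal power; reports how often PP(H3) > 0.9.
#'
#' @param n_seeds Number of simulation seeds.
#' @param scenario `"shared"` or `"distinct"`.
#' @param m Variants per region.
#' @param rho AR(1) LD decay within blocks.
#' @param ncp Target noncentrality of the causal z-scores.
#' @param seed Base seed.
#' @return list: `rate` (fraction of seeds with the target posterior > 0.9),
#'   `pp` (the posteriors), `scenario`, `n_seeds`.
#' @export
coloc_calibration_study <- function(n_seeds = 200L,
                                    scenario = c("shared", "distinct"),
                                    m = 30L, rho = 0.9, ncp = 8, seed = 1L) {
  scenario <- match.arg(scenario)
  n_prot <- 35559
  n_case <- 62100; n_control <- 1234808
  f <- 0.5  # frequency range is degenerate so power is exactly controlled
  se_x <- 1 / sqrt(2 * n_prot * f * (1 - f))
  phi <- n_case / (n_case + n_control)
  se_y <- 1 / sqrt(2 * (n_case + n_control) * phi * (1 - phi) * f * (1 - f))
  lambda <- ncp * se_x
  pp <- vapply(seq_len(n_seeds), function(s) {
    region <- sim_region("G", "1", 1e6, 1e6 + 6e4, m = m,
                         blocks = c(ceiling(m / 2), floor(m / 2)), rho = rho,
                         freq_range = c(f, f))
    i1 <- m %/% 4L
    outcome <- if (scenario == "shared") {
      sim_outcome("out", n_case, n_control,
                  theta = c(G = ncp * se_y / lambda))
    } else {
      sim_outcome("out", n_case, n_control,
                  pleiotropy = list(list(region = "G",
                                         idx = m %/% 2L + m %/% 4L,
                                         effect = ncp * se_y)))
    }
    cfg <- sim_config(
      list(G = region),
      list(G = sim_protein("G", "G", i1, lambda, cohorts = "expo")),
      list(expo = list(n = n_prot)), list(out = outcome), seed = seed + s)
    sim <- simulate_sumstats(cfg)
    rd <- regional_dataset(region, sim$sumstats[c("G.expo", "out")],
                           sim$ld$G)
    cr <- coloc_pair(rd)
    if (scenario == "shared") cr$pp[["PP.H4"]] else cr$pp[["PP.H3"]]
  }, numeric(1))
  list(rate = mean(pp > 0.9), pp = pp, scenario = scenario,
       n_seeds = n_seeds)
}

#' Conditional-analysis clearance study
#'
#' High-power single-signal regions: after conditioning the outcome trait on
#' the true causal variant, does any other (estimable) variant remain below
#' the regional Bonferroni threshold `0.05/m`? Reports the fraction of seeds
#' with a clean residual region — the operating characteristic behind
#' "conditioning on the lead pQTL leaves no significant residual
#' association".
#'
#' @inheritParams coloc_calibration_study
#' @return list: `rate` (fraction of clean seeds), `threshold`, `n_seeds`.
#' @export
conditional_clearance_study <- function(n_seeds = 200L, m = 30L, rho = 0.9,
                                        seed = 1L) {
  clean <- vapply(seq_len(n_seeds), function(s) {
    region <- sim_region("G", "1", 1e6, 1e6 + 6e4, m = m, rho = rho,
                         freq_range = c(0.2, 0.8))
    cfg <- sim_config(
      list(G = region),
      list(G = sim_protein("G", "G", m %/% 2L, 0.35, cohorts = "expo")),
      list(expo = list(n = 35559)),
      list(out = sim_outcome("out", 62100, 1234808, theta = c(G = 0.25))),
      seed = seed + s)
    sim <- simulate_sumstats(cfg)
    rd <- regional_dataset(region, sim$sumstats[c("G.expo", "out")],
                           sim$ld$G)
    cz <- conditional_z(rd, "out", sim$truth$proteins$G$causal_ids)
    resid <- cz$pval_cond[cz$estimable &
                            cz$variant_id != sim$truth$proteins$G$causal_ids]
    all(resid >= 0.05 / m)
  }, logical(1))
  list(rate = mean(clean), threshold = 0.05 / m, n_seeds = n_seeds)
}

#' Conditional z versus individual-level regression oracle
#'
#' Simulates genotypes at two linked variants with joint effects on a
#' quantitative phenotype, computes marginal z-scores, projects one on the
#' other with the summary-statistic conditional formula, and compares
#' against the joint two-variant regression's t-statistic.
#'
#' @param n_seeds Number of replicates.
#' @param n Individuals per replicate.
#' @param r_max Largest |haplotype correlation| examined.
#' @param seed Base seed.
#' @return list: `max_rel_err`, `rel_err` vector, `n_seeds`.
#' @export
conditional_oracle_study <- function(n_seeds = 100L, n = 2e4, r_max = 0.95,
                                     seed = 1L) {
  rel <- rep(NA_real_, n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(seed + s)
    r <- stats::runif(1, -r_max, r_max)
    f1 <- stats::runif(1, 0.2, 0.8); f2 <- stats::runif(1, 0.2, 0.8)
    g <- tryCatch(simulate_genotype_pair(n, f1, f2, r),
                  error = function(e) NULL)
    if (is.null(g)) next
    y <- 0.08 * g$g1 + 0.06 * g$g2 + stats::rnorm(n)
    z1 <- summary(stats::lm(y ~ g$g1))$coefficients[2L, 3L]
    z2 <- summary(stats::lm(y ~ g$g2))$coefficients[2L, 3L]
    zj <- summary(stats::lm(y ~ g$g1 + g$g2))$coefficients[3L, 3L]
    rhat <- stats::cor(g$g1, g$g2)
    z2c <- (z2 - rhat * z1) / sqrt(1 - rhat^2)
    rel[s] <- abs(z2c - zj) / abs(zj)
  }
  list(max_rel_err = max(rel, na.rm = TRUE), rel_err = rel,
       n_seeds = n_seeds)
}

#' End-to-end prioritization recovery study
#'
#' Runs the full pipeline on replicated demonstration panels (5
#' stroke-causal and 15 VTE-only proteins by default) and scores the
#' prioritization verdict against the generative truth: sensitivity for the
#' causal proteins and the count of VTE-only proteins falsely prioritized.
#'
#' @param n_seeds Number of replicate panels.
#' @param n_causal,n_vte_only Panel composition.
#' @param seed Base seed.
#' @return list: `sensitivity` (mean over seeds), `false_positives` (total
#'   over seeds), per-seed vectors, `n_seeds`.
#' @export
end_to_end_recovery_study <- function(n_seeds = 50L, n_causal = 5L,
                                      n_vte_only = 15L, seed = 1L) {
  sens <- numeric(n_seeds); fp <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- demo_config(seed = seed + s, n_causal = n_causal,
                       n_vte_only = n_vte_only)
    rep <- run_pipeline(cfg)
    pri <- rep$prioritization
    stroke <- pri[pri$outcome == "stroke", , drop = FALSE]
    found <- unique(stroke$protein[stroke$verdict == "prioritized"])
    causal <- names(cfg$outcomes$stroke$theta)
    sens[s] <- length(intersect(found, causal)) / length(causal)
    fp[s] <- length(setdiff(found, causal))
  }
  list(sensitivity = mean(sens), false_positives = sum(fp),
       per_seed_sensitivity = sens, per_seed_fp = fp, n_seeds = n_seeds)
}
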