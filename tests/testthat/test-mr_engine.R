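make_pairs <- function(bx, by, sey, sex = rep(0.01, length(bx))) {
  data.frame(variant_id = paste0("rs", seq_along(bx)),
             effect_allele = "A", other_allele = "G",
             beta_exposure = bx, se_exposure = sex, eaf_exposure = 0.3,
             beta_outcome = by, se_outcome = sey, eaf_outcome = 0.3,
             action = "none", reason = "", stringsAsFactors = FALSE)
}

test_that("Wald ratio implements the first-order delta method", {
  est <- wald_ratio(make_pairs(0.5, 0.1, 0.02))
  expect_equal(est$theta, 0.2)
  expect_equal(est$se, 0.04)
  expect_equal(est$ci_low, 0.2 - qnorm(0.975) * 0.04)
  expect_equal(est$pval, 2 * pnorm(-5))
  # zero numerator: null estimate with the same se
  est0 <- wald_ratio(make_pairs(-0.5, 0, 0.02))
  expect_equal(est0$theta, 0)
  expect_equal(est0$se, 0.04)
  expect_error(wald_ratio(make_pairs(0, 0.1, 0.02)), "undefined ratio")
})

test_that("first-order delta se matches the second-order correction for strong instruments", {
  set.seed(10)
  for (i in 1:100) {
    bx <- runif(1, 0.2, 0.8) * sample(c(-1, 1), 1)
    sex <- abs(bx) / runif(1, 10.5, 40)   # |bx|/sex > 10
    by <- 0.2 * bx
    sey <- abs(by) * runif(1, 0.5, 2)     # outcome z of order 1
    first <- wald_ratio(make_pairs(bx, by, sey, sex))$se
    second <- sqrt(sey^2 / bx^2 + by^2 * sex^2 / bx^4)
    expect_lt(abs(first - second) / second, 0.05)
  }
})

test_that("IVW reduces to the Wald ratio for one variant and is exact when homogeneous", {
  p1 <- make_pairs(0.5, 0.1, 0.02)
  expect_equal(as.data.frame(ivw(p1)),
               as.data.frame(wald_ratio(p1)))
  # equal weights, equal ratios: theta recovered, Q = 0
  p2 <- make_pairs(c(0.5, 0.3), c(0.1, 0.06), c(0.02, 0.02))
  est <- ivw(p2)
  expect_equal(est$theta, 0.2)
  expect_equal(est$Q, 0, tolerance = 1e-24)
  expect_equal(est$phi, 1)  # inflation floored at 1
  expect_error(ivw(make_pairs(1, 1, 1)[0L, ]), "at least one")
})

test_that("IVW equals an independent no-intercept WLS fit (lm oracle)", {
  set.seed(11)
  for (i in 1:100) {
    J <- sample(2:25, 1L)
    bx <- rnorm(J, 0, 0.3)
    sey <- runif(J, 0.005, 0.05)
    by <- rnorm(J, 0.2 * bx, sey)
    est <- ivw(make_pairs(bx, by, sey))
    fit <- lm(by ~ 0 + bx, weights = 1 / sey^2)
    sm <- summary(fit)
    expect_equal(est$theta, unname(coef(fit)[1L]), tolerance = 1e-10)
    # lm scales its se by the residual sd; undo to get the fixed-effect se
    se_fe_lm <- sm$coefficients[1L, 2L] / sm$sigma
    se_fe <- est$se / sqrt(est$phi)
    expect_equal(se_fe, se_fe_lm, tolerance = 1e-10)
    expect_equal(est$Q, sm$sigma^2 * (J - 1), tolerance = 1e-8)
  }
})

test_that("multivariable MR equals the lm oracle and reduces to IVW", {
  set.seed(12)
  for (i in 1:100) {
    J <- sample(4:25, 1L)
    K <- sample(2:3, 1L)
    BX <- matrix(rnorm(J * K, 0, 0.3), J, K,
                 dimnames = list(NULL, paste0("E", seq_len(K))))
    sey <- runif(J, 0.005, 0.05)
    theta_true <- c(0.2, -0.1, 0.3)[seq_len(K)]
    by <- rnorm(J, BX %*% theta_true, sey)
    ests <- mvmr(BX, by, sey)
    fit <- lm(by ~ 0 + BX, weights = 1 / sey^2)
    sm <- summary(fit)
    for (k in seq_len(K)) {
      expect_equal(ests[[k]]$theta, unname(coef(fit)[k]), tolerance = 1e-10)
      se_fe <- ests[[k]]$se / sqrt(ests[[k]]$phi)
      expect_equal(se_fe, sm$coefficients[k, 2L] / sm$sigma,
                   tolerance = 1e-10)
    }
  }
  # K = 1 is exactly IVW
  bx <- rnorm(8, 0, 0.3); sey <- runif(8, 0.01, 0.03)
  by <- rnorm(8, 0.2 * bx, sey)
  m1 <- mvmr(matrix(bx, ncol = 1), by, sey)[[1L]]
  i1 <- ivw(make_pairs(bx, by, sey))
  expect_equal(m1$theta, i1$theta, tolerance = 1e-12)
  expect_equal(m1$se, i1$se, tolerance = 1e-12)
})

test_that("orthogonal exposures give their univariable estimates; collinearity errors", {
  # block-orthogonal design: each exposure acts on its own variants
  bx1 <- c(0.5, 0.4, 0, 0); bx2 <- c(0, 0, 0.3, 0.6)
  sey <- rep(0.02, 4)
  by <- 0.2 * bx1 - 0.1 * bx2
  ests <- mvmr(cbind(A = bx1, B = bx2), by, sey)
  expect_equal(ests$A$theta, ivw(make_pairs(bx1[1:2], by[1:2],
                                            sey[1:2]))$theta)
  expect_equal(ests$B$theta, ivw(make_pairs(bx2[3:4], by[3:4],
                                            sey[3:4]))$theta)
  expect_error(mvmr(cbind(A = bx1, B = 2 * bx1), by, sey), "collinear")
})

test_that("multivariable MR separates neighboring-gene exposures", {
  # two correlated exposures, only the first causal (theta 0.11)
  theta1 <- 0.11
  t1 <- numeric(300); t2 <- numeric(300); se1 <- numeric(300)
  for (s in 1:300) {
    cfg <- f11_klkb1_config(seed = s, theta_stroke = theta1)
    sim <- simulate_sumstats(cfg)
    ids <- c(sim$truth$proteins$F11$causal_ids,
             sim$truth$proteins$KLKB1$causal_ids)
    vX1 <- sim$sumstats$F11.decode$variants
    vX2 <- sim$sumstats$KLKB1.decode$variants
    vY <- sim$sumstats$stroke$variants
    i <- match(ids, vY$variant_id)
    BX <- cbind(F11 = vX1$beta[match(ids, vX1$variant_id)],
                KLKB1 = vX2$beta[match(ids, vX2$variant_id)])
    ests <- mvmr(BX, vY$beta[i], vY$se[i])
    t1[s] <- ests$F11$theta; t2[s] <- ests$KLKB1$theta
    se1[s] <- ests$F11$se
  }
  mc_se2 <- sd(t2) / sqrt(300)
  expect_lt(abs(mean(t2)), 2 * mc_se2)          # no residual KLKB1 effect
  expect_lt(abs(mean(t1) - theta1), 2 * sd(t1) / sqrt(300) + 0.01)
})

test_that("per-doubling rescaling is linear in the liability effect", {
  est <- wald_ratio(make_pairs(1, 0.1, 0.02))  # theta on the numerator scale
  same <- rescale_per_doubling(est, log(2))
  expect_equal(same$theta, est$theta)
  expect_equal(same$se, est$se)
  expect_identical(same$exposure_scale, "per_doubling_liability")
  half <- rescale_per_doubling(est, 2 * log(2))
  expect_equal(half$theta, est$theta / 2)
  neg <- rescale_per_doubling(est, -log(2))
  expect_equal(neg$theta, -est$theta)
  expect_equal(neg$se, est$se)
  expect_error(rescale_per_doubling(est, 0), "nonzero")
})

test_that("per-doubling simulation recovery", {
  # liability-mediated design: variant -> protein -> VTE and stroke; the
  # per-doubling stroke effect implied by theta_stroke/theta_vte * ln 2
  ratios <- vapply(1:200, function(s) {
    cfg <- single_signal_config(s, lambda = 0.5, theta_vte = 0.4,
                                theta_stroke = 0.2)
    sim <- simulate_sumstats(cfg)
    cid <- sim$truth$proteins$GENE1$causal_ids
    vv <- sim$sumstats$vte$variants
    vs <- sim$sumstats$stroke$variants
    i <- match(cid, vv$variant_id)
    est <- wald_ratio(make_pairs(vv$beta[i], vs$beta[match(cid, vs$variant_id)],
                                 vs$se[match(cid, vs$variant_id)]))
    rescale_per_doubling(est, 1)$theta / log(2)  # back to per-VTE-log-odds
  }, numeric(1))
  expect_equal(mean(ratios), 0.2 / 0.4, tolerance = 3 * sd(ratios) / sqrt(200))
})

test_that("Bonferroni plans reproduce the study thresholds", {
  expect_equal(signif(bonferroni(30)$alpha_per_test, 2), 0.0017)
  expect_equal(signif(bonferroni(1380)$alpha_per_test, 2), 3.6e-5)
  expect_equal(bonferroni(1)$alpha_per_test, 0.05)
  plan <- bonferroni(30)
  expect_equal(plan$z_cutoff, qnorm(1 - plan$alpha_per_test / 2))
  expect_lte(plan$alpha_per_test, plan$alpha_family)
})

test_that("IVW is invariant under per-variant allele-relabeling sign flips", {
  set.seed(13)
  bx <- rnorm(10, 0, 0.3); sey <- runif(10, 0.01, 0.03)
  by <- rnorm(10, 0.2 * bx, sey)
  base <- ivw(make_pairs(bx, by, sey))
  for (i in 1:20) {
    flip <- sample(c(-1, 1), 10, replace = TRUE)
    est <- ivw(make_pairs(flip * bx, flip * by, sey))
    expect_equal(est$theta, base$theta, tolerance = 1e-12)
    expect_equal(est$se, base$se, tolerance = 1e-12)
  }
})

test_that("multiplicative random effects never deflate the se", {
  set.seed(14)
  for (i in 1:50) {
    J <- sample(2:20, 1L)
    bx <- rnorm(J, 0, 0.3); sey <- runif(J, 0.01, 0.05)
    by <- rnorm(J, 0.1 * bx, sey * sample(c(1, 3), 1L))
    est <- ivw(make_pairs(bx, by, sey))
    expect_gte(est$phi, 1)
    expect_gte(est$se, sqrt(1 / sum(bx^2 / sey^2)) * (1 - 1e-12))
  }
})
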