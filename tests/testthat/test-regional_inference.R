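# numerical-integration oracle for the Wakefield approximate Bayes factor:
# BF = p(betahat | H1) / p(betahat | H0) with a N(0, W) effect prior
abf_quadrature <- function(z, V, W) {
  betahat <- z * sqrt(V)
  num <- integrate(function(b) {
    dnorm(betahat, b, sqrt(V)) * dnorm(b, 0, sqrt(W))
  }, -Inf, Inf, rel.tol = 1e-12)$value
  log(num) - dnorm(betahat, 0, sqrt(V), log = TRUE)
}

regional_from_sim <- function(cfg, traits) {
  sim <- simulate_sumstats(cfg)
  rd <- regional_dataset(cfg$regions[[1L]], sim$sumstats[traits],
                         sim$ld[[1L]])
  list(rd = rd, sim = sim)
}

test_that("log ABF matches numerical integration and its limits", {
  set.seed(20)
  for (i in 1:50) {
    z <- rnorm(1, 0, 4)
    V <- runif(1, 0.005, 0.05)^2
    W <- runif(1, 0.05, 0.4)^2
    expect_equal(log_abf(z, sqrt(V), sqrt(W)), abf_quadrature(z, V, W),
                 tolerance = 1e-6)
  }
  # null z: pure shrinkage, always negative
  expect_lt(log_abf(0, 0.02, 0.15), 0)
  # vanishing prior: no evidence either way
  expect_equal(log_abf(3, 0.02, 1e-8), 0, tolerance = 1e-3)
})

test_that("colocalization posteriors are a proper distribution and H0 wins on flat data", {
  m <- 100L
  v <- make_variants(m)
  v$variant_id <- paste0("v", seq_len(m))
  v$beta <- 0; v$pval <- 1
  mk <- function(type) sumstat_set("t", type, "", v)
  ld <- make_ld(m, rho = 0.3, ids = v$variant_id)
  rd <- regional_dataset(gene_region("G", "4", 0, 1e6),
                         list(a = mk("quantitative"), b = mk("binary")), ld)
  cr <- coloc_pair(rd)
  expect_equal(sum(cr$pp), 1, tolerance = 1e-9)
  expect_true(all(cr$pp >= 0 & cr$pp <= 1))
  expect_gt(cr$pp[["PP.H0"]], 0.99)
  expect_error(coloc_pair(structure(list(traits = list(1, 2, 3)),
                                    class = "regional_dataset")),
               "exactly 2")
})

test_that("a shared causal variant is recognized as H4", {
  hits <- vapply(1:200, function(s) {
    cfg <- single_signal_config(s, m = 30L, rho = 0.9, lambda = 0.3,
                                theta_stroke = 0.5)
    r <- regional_from_sim(cfg, c("GENE1.decode", "stroke"))
    coloc_pair(r$rd)$pp[["PP.H4"]] > 0.9
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("distinct causal variants in linkage equilibrium are recognized as H3", {
  hits <- vapply(1:200, function(s) {
    m <- 30L
    region <- sim_region("G", "1", 1e6, 1e6 + 6e4, m = m,
                         blocks = c(15L, 15L), rho = 0.9,
                         freq_range = c(0.2, 0.8))
    # protein causal in block 1; outcome signal from block 2 only
    cfg <- sim_config(
      list(G = region),
      list(G = sim_protein("G", "G", 8L, 0.3, cohorts = "decode")),
      list(decode = list(n = 35559)),
      list(stroke = sim_outcome("stroke", 62100, 1234808,
                                pleiotropy = list(list(region = "G",
                                                       idx = 23L,
                                                       effect = 0.06)))),
      seed = s)
    r <- regional_from_sim(cfg, c("G.decode", "stroke"))
    coloc_pair(r$rd)$pp[["PP.H3"]] > 0.9
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("PP(H4) vanishes monotonically as the shared prior p12 shrinks", {
  # deterministic moderate-evidence data: shared peak with z ~ 6 in both
  m <- 20L
  ld <- make_ld(m, rho = 0.5, ids = paste0("v", 1:m))
  z <- as.vector(ld[, 10L] * 6)  # marginal expectation of one causal at v10
  v <- make_variants(m)
  v$variant_id <- paste0("v", 1:m)
  v$se <- 0.02; v$beta <- z * v$se; v$pval <- 2 * pnorm(-abs(z))
  rd <- regional_dataset(gene_region("G", "4", 0, 1e6),
                         list(a = sumstat_set("a", "quantitative", "", v),
                              b = sumstat_set("b", "binary", "", v)), ld)
  p12s <- c(1e-5, 1e-7, 1e-9, 1e-11, 1e-13)
  pp4 <- vapply(p12s, function(p12) {
    coloc_pair(rd, p12 = p12)$pp[["PP.H4"]]
  }, numeric(1))
  expect_gt(pp4[1L], 0.9)
  expect_true(all(diff(pp4) < 0))
  expect_lt(pp4[length(pp4)], 0.01)
})

test_that("coloc output is invariant to variant order", {
  cfg <- single_signal_config(32L)
  sim <- simulate_sumstats(cfg)
  rd <- regional_dataset(cfg$regions[[1L]],
                         sim$sumstats[c("GENE1.decode", "stroke")],
                         sim$ld[[1L]])
  set.seed(1)
  perm <- sample(nrow(rd$traits[[1L]]$variants))
  rd2 <- rd
  rd2$traits <- lapply(rd$traits, function(s) {
    s$variants <- s$variants[perm, ]; s
  })
  rd2$ld <- rd$ld[perm, perm]
  expect_equal(coloc_pair(rd2)$pp, coloc_pair(rd)$pp, tolerance = 1e-12)
  expect_equal(finemap_single(rd2, "stroke")$credible_set,
               finemap_single(rd, "stroke")$credible_set)
})

test_that("conditional z-scores behave at the index and under independence", {
  m <- 10L
  v <- make_variants(m)
  ld <- make_ld(m, blocks = c(5L, 5L), rho = c(0.9, 0),
                ids = v$variant_id)
  ss <- sumstat_set("stroke", "binary", "", v)
  rd <- regional_dataset(gene_region("G", "4", 0, 1e6), list(stroke = ss), ld)
  cz <- conditional_z(rd, "stroke", "rs3")
  z <- v$beta / v$se
  expect_equal(cz$z_cond[3L], 0)
  # variants in the uncorrelated block are untouched
  expect_equal(cz$z_cond[6:10], z[6:10])
  # correlated neighbor follows the projection formula
  r <- ld[1L, 3L]
  expect_equal(cz$z_cond[1L], (z[1L] - r * z[3L]) / sqrt(1 - r^2))
  expect_error(conditional_z(rd, "stroke", "nope"), "not in region")
})

test_that("conditioning a dataset twice on the same index changes nothing", {
  cfg <- single_signal_config(33L)
  sim <- simulate_sumstats(cfg)
  rd <- regional_dataset(cfg$regions[[1L]],
                         sim$sumstats[c("GENE1.decode", "stroke")],
                         sim$ld[[1L]])
  idx <- sim$truth$proteins$GENE1$causal_ids
  once <- condition_dataset(rd, idx)
  twice <- condition_dataset(once, idx)
  expect_equal(twice$traits$stroke$variants$beta,
               once$traits$stroke$variants$beta, tolerance = 1e-10)
  expect_equal(twice$ld, once$ld, tolerance = 1e-8)
})

test_that("summary conditional z agrees with the individual-level regression oracle", {
  set.seed(40)
  n <- 2e4
  worst <- 0
  for (s in 1:100) {
    r <- runif(1, -0.95, 0.95)
    f1 <- runif(1, 0.2, 0.8); f2 <- runif(1, 0.2, 0.8)
    g <- tryCatch(simulate_genotype_pair(n, f1, f2, r),
                  error = function(e) NULL)
    if (is.null(g)) next
    b1 <- 0.08; b2 <- 0.06
    y <- b1 * g$g1 + b2 * g$g2 + rnorm(n)
    zm <- c(summary(lm(y ~ g$g1))$coefficients[2L, 3L],
            summary(lm(y ~ g$g2))$coefficients[2L, 3L])
    joint <- summary(lm(y ~ g$g1 + g$g2))$coefficients
    rhat <- cor(g$g1, g$g2)
    z2_cond <- (zm[2L] - rhat * zm[1L]) / sqrt(1 - rhat^2)
    rel <- abs(z2_cond - joint[3L, 3L]) / abs(joint[3L, 3L])
    worst <- max(worst, rel)
    expect_lt(rel, 0.10)
  }
})

test_that("fine-mapping PIPs are symmetric, normalized, and concentrate correctly", {
  # identical z on 4 variants: uniform PIP, full credible set
  v <- make_variants(4L)
  v$beta <- 0.1; v$se <- 0.02
  v$pval <- 2 * pnorm(-5)
  rd <- regional_dataset(gene_region("G", "4", 0, 1e6),
                         list(t = sumstat_set("t", "binary", "", v)),
                         make_ld(4L, rho = 0.5, ids = v$variant_id))
  cs <- finemap_single(rd, "t")
  expect_equal(unname(cs$pip$pip), rep(0.25, 4L))
  expect_equal(length(cs$credible_set), 4L)
  expect_equal(sum(cs$pip$pip), 1, tolerance = 1e-9)
  # one dominant z in weak LD: singleton credible set containing the causal
  singleton <- vapply(1:200, function(s) {
    cfg <- single_signal_config(s, m = 20L, rho = 0.2, lambda = 0.4)
    sim <- simulate_sumstats(cfg)
    rd <- regional_dataset(cfg$regions[[1L]],
                           sim$sumstats["GENE1.decode"], sim$ld[[1L]])
    cs <- finemap_single(rd, "GENE1.decode")
    length(cs$credible_set) == 1L &&
      cs$credible_set == sim$truth$proteins$GENE1$causal_ids
  }, logical(1))
  expect_gte(mean(singleton), 0.95)
})

test_that("causal-variant PIP grows with sample size", {
  pip_at_n <- function(n) {
    mean(vapply(1:100, function(s) {
      region <- sim_region("G", "1", 1e6, 1e6 + 6e4, m = 20L, rho = 0.9,
                           freq_range = c(0.2, 0.8))
      cfg <- sim_config(
        list(G = region),
        list(G = sim_protein("G", "G", 10L, 0.05, cohorts = "decode")),
        list(decode = list(n = n)),
        list(stroke = sim_outcome("stroke", 6e4, 1.2e6)),
        seed = s)
      sim <- simulate_sumstats(cfg)
      rd <- regional_dataset(region, sim$sumstats["G.decode"], sim$ld$G)
      tab <- finemap_single(rd, "G.decode")$pip
      tab$pip[tab$variant_id == sim$truth$proteins$G$causal_ids]
    }, numeric(1)))
  }
  pips <- c(pip_at_n(1e4), pip_at_n(5e4), pip_at_n(2e5))
  expect_true(all(diff(pips) > 0))
})

test_that("stepwise signal counting finds none, one, or two as configured", {
  # null region
  cfg0 <- single_signal_config(50L, lambda = 0, theta_stroke = 0,
                               theta_vte = 0)
  sim0 <- simulate_sumstats(cfg0)
  rd0 <- regional_dataset(cfg0$regions[[1L]], sim0$sumstats["GENE1.decode"],
                          sim0$ld[[1L]])
  expect_equal(count_signals(rd0, "GENE1.decode")$n_signals, 0L)

  # one strong signal at the study's reporting threshold
  one <- vapply(1:200, function(s) {
    cfg <- single_signal_config(s, lambda = 0.35)
    sim <- simulate_sumstats(cfg)
    rd <- regional_dataset(cfg$regions[[1L]], sim$sumstats["GENE1.decode"],
                           sim$ld[[1L]])
    count_signals(rd, "GENE1.decode", stop_p = 1.3e-4)$n_signals
  }, numeric(1))
  expect_gte(mean(one == 1L), 0.95)

  # two independent causal variants in separate blocks
  two <- vapply(1:100, function(s) {
    m <- 30L
    region <- sim_region("G", "1", 1e6, 1e6 + 6e4, m = m,
                         blocks = c(15L, 15L), rho = 0.9,
                         freq_range = c(0.2, 0.8))
    cfg <- sim_config(
      list(G = region),
      list(G = sim_protein("G", "G", c(8L, 23L), c(0.35, 0.35),
                           cohorts = "decode")),
      list(decode = list(n = 35559)),
      list(stroke = sim_outcome("stroke", 6e4, 1.2e6)),
      seed = s)
    sim <- simulate_sumstats(cfg)
    rd <- regional_dataset(region, sim$sumstats["G.decode"], sim$ld$G)
    count_signals(rd, "G.decode", stop_p = 1.3e-4)$n_signals
  }, numeric(1))
  expect_gte(mean(two == 2L), 0.9)
})

test_that("regional plot tables expose position, -log10 p and r2 to the lead", {
  cfg <- single_signal_config(60L)
  sim <- simulate_sumstats(cfg)
  rd <- regional_dataset(cfg$regions[[1L]], sim$sumstats["GENE1.decode"],
                         sim$ld[[1L]])
  tab <- regional_plot_table(rd, "GENE1.decode")
  expect_equal(nrow(tab), 30L)
  expect_equal(sum(tab$lead), 1L)
  expect_equal(tab$r2_lead[tab$lead], 1)
  expect_true(all(tab$neglog10p >= 0))
})
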