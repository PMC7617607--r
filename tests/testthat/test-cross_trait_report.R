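make_proxy <- function(ids, protein = "P1", source = "decode", seed = 1L) {
  v <- make_variants(length(ids), seed = seed)
  v$variant_id <- ids
  proxy_set(protein, source, v, clump_r2 = 0.001)
}

test_that("cross-trait family size counts tested variant-protein pairs", {
  # 46 variants fully measured across 30 proteins: the study's 1380 tests
  ids <- paste0("rs", 1:46)
  proxies <- list(make_proxy(ids))
  protein_sets <- list()
  for (p in 1:30) {
    v <- make_variants(46L, seed = p)
    v$variant_id <- ids
    protein_sets[[paste0("P", p, ".decode")]] <-
      sumstat_set(paste0("P", p), "quantitative", "decode", v)
  }
  ct <- build_cross_trait(proxies, protein_sets)
  expect_equal(ct$n_tests, 1380L)
  expect_equal(signif(ct$plan$alpha_per_test, 2), 3.6e-5)
  # a single variant and protein: family of one, alpha 0.05
  expect_equal(build_cross_trait(
    list(make_proxy("rs1")),
    list(P1.decode = sumstat_set("P1", "quantitative", "decode",
                                 make_variants(1L))))$plan$alpha_per_test,
    0.05)
})

test_that("gaps are excluded from the family and the mask matches brute force", {
  set.seed(30)
  ids <- paste0("rs", 1:12)
  proxies <- list(make_proxy(ids))
  protein_sets <- list()
  for (p in 1:4) {
    keep <- sort(sample(12L, 8L))  # each protein measures 8 of 12 variants
    v <- make_variants(12L, seed = p + 40L)
    v$variant_id <- ids
    v <- v[keep, ]
    v$pval <- 10^runif(8L, -8, 0)
    protein_sets[[paste0("P", p, ".decode")]] <-
      sumstat_set(paste0("P", p), "quantitative", "decode", v)
  }
  ct <- build_cross_trait(proxies, protein_sets)
  measured <- !is.na(ct$pval)
  expect_equal(ct$n_tests, sum(measured))  # one cohort: pairs == cells
  expect_identical(ct$mask,
                   !is.na(ct$pval) & ct$pval < 0.05 / ct$n_tests)
  expect_true(all(is.na(ct$pval) | measured))
  # bookkeeping: per-cohort duplicates of a protein do not double the family
  dup <- protein_sets
  dup[["P1.ukb"]] <- protein_sets[["P1.decode"]]
  dup[["P1.ukb"]]$cohort_label <- "ukb"
  ct2 <- build_cross_trait(proxies, dup)
  expect_equal(ct2$n_tests, ct$n_tests)
})

test_that("z comparison classifies proxies against the MR cutoff", {
  ids <- c("rs1", "rs2", "rs3", "rs4")
  mk_out <- function(z, trait) {
    v <- make_variants(4L)
    v$variant_id <- ids
    v$se <- 0.02
    v$beta <- z * v$se
    v$pval <- 2 * pnorm(-abs(z))
    sumstat_set(trait, "binary", "", v)
  }
  zc <- compare_z(list(make_proxy(ids)),
                  mk_out(c(5, 0.5, 4, 1), "vte"),
                  mk_out(c(0.5, 6, 4.2, -1), "stroke"), alpha = 0.0017)
  expect_equal(zc$cutoff, qnorm(1 - 0.0017 / 2))
  expect_identical(zc$table$category,
                   c("vte_only", "outcome_only", "both", "neither"))
  # sign-flip invariance of the classification
  zc2 <- compare_z(list(make_proxy(ids)),
                   mk_out(-c(5, 0.5, 4, 1), "vte"),
                   mk_out(-c(0.5, 6, 4.2, -1), "stroke"), alpha = 0.0017)
  expect_identical(zc2$table$category, zc$table$category)
  # a proxy missing from one set is dropped with a warning
  expect_warning(
    zc3 <- compare_z(list(make_proxy(c(ids, "rs9"))),
                     mk_out(c(5, 0.5, 4, 1), "vte"),
                     mk_out(c(0.5, 6, 4.2, -1), "stroke")),
    "missing")
  expect_equal(nrow(zc3$table), 4L)
})

test_that("VTE-only proteins are rarely classified as associated with both", {
  # theta_stroke = 0: the stroke z at the proxy is null, so 'both' should
  # occur at roughly the alpha level
  both <- vapply(1:200, function(s) {
    cfg <- single_signal_config(s, theta_stroke = 0, theta_vte = 0.5,
                                lambda = 0.5)
    sim <- simulate_sumstats(cfg)
    prox <- select_proxies(
      "GENE1", list(decode = sim$sumstats$GENE1.decode),
      liability_ss = sim$sumstats$vte, outcome_ss = sim$sumstats$stroke,
      region = cfg$regions$GENE1, ld = sim$ld$GENE1)
    if (prox$decode$no_proxy) return(NA)
    zc <- compare_z(prox, sim$sumstats$vte, sim$sumstats$stroke,
                    alpha = 0.0017)
    any(zc$table$category == "both")
  }, logical(1))
  expect_lte(mean(both, na.rm = TRUE), 0.02)
})

test_that("prioritization is a strict conjunction of MR and colocalization", {
  mr <- data.frame(protein = c("F11", "TFPI", "PLAU"), source = "decode",
                   outcome = "stroke", pval = c(1e-8, 1e-8, 1e-8),
                   stringsAsFactors = FALSE)
  coloc <- data.frame(protein = c("F11", "TFPI"), outcome = "stroke",
                      pp_h4 = c(0.96, 0.22), stringsAsFactors = FALSE)
  plan <- bonferroni(30)
  out <- prioritize(mr, coloc, plan)
  expect_identical(out$verdict[out$protein == "F11"], "prioritized")
  expect_identical(out$verdict[out$protein == "TFPI"], "not_prioritized")
  # MR evidence without a coloc result can never be prioritized
  expect_identical(out$verdict[out$protein == "PLAU"], "incomplete")
  # weak MR with strong coloc is not prioritized either
  mr2 <- transform(mr, pval = c(0.01, 1e-8, 1e-8))
  out2 <- prioritize(mr2, coloc, plan)
  expect_identical(out2$verdict[out2$protein == "F11"], "not_prioritized")
})

test_that("prioritization verdicts are monotone in the thresholds", {
  set.seed(31)
  mr <- data.frame(protein = paste0("P", 1:40), source = "decode",
                   outcome = "stroke", pval = 10^runif(40, -9, 0),
                   stringsAsFactors = FALSE)
  coloc <- data.frame(protein = paste0("P", 1:40), outcome = "stroke",
                      pp_h4 = runif(40), stringsAsFactors = FALSE)
  base <- prioritize(mr, coloc, bonferroni(30), pp_min = 0.7)
  hit0 <- base$protein[base$verdict == "prioritized"]
  looser_pp <- prioritize(mr, coloc, bonferroni(30), pp_min = 0.5)
  looser_alpha <- prioritize(mr, coloc, bonferroni(10), pp_min = 0.7)
  expect_true(all(hit0 %in%
                    looser_pp$protein[looser_pp$verdict == "prioritized"]))
  expect_true(all(hit0 %in%
                    looser_alpha$protein[looser_alpha$verdict == "prioritized"]))
})

test_that("the full pipeline is complete, deterministic, and writes a report", {
  cfg <- demo_config(seed = 5L, n_causal = 2L, n_vte_only = 3L)
  rep1 <- run_pipeline(cfg)
  # every protein x primary outcome appears exactly once per available source
  pri <- rep1$prioritization
  expect_setequal(unique(pri$protein), names(cfg$proteins))
  counts <- table(pri$protein, pri$source)
  expect_true(all(counts <= 1L))
  # re-running the same configuration reproduces the report byte for byte
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep1, d1)
  write_report(run_pipeline(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_true(file.exists(file.path(d1, "mr_estimates.tsv")))
  expect_true(file.exists(file.path(d1, "proxies_audit.json")))
})

test_that("pipeline recovery: causal proteins found, VTE-only proteins clean", {
  hits <- matrix(0, 10L, 2L)
  for (s in 1:10) {
    cfg <- demo_config(seed = 100L + s)
    rep <- run_pipeline(cfg)
    pri <- rep$prioritization
    stroke <- pri[pri$outcome == "stroke", ]
    found <- unique(stroke$protein[stroke$verdict == "prioritized"])
    causal <- names(cfg$outcomes$stroke$theta)
    hits[s, 1L] <- length(intersect(found, causal)) / length(causal)
    hits[s, 2L] <- length(setdiff(found, causal))
  }
  expect_gte(mean(hits[, 1L]), 0.8)  # sensitivity
  expect_equal(sum(hits[, 2L]), 0)   # no VTE-only false positives
})
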