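# shared in-code fixtures for the test suite

# a small, well-formed summary-statistic table
make_variants <- function(n = 5L, chrom = "4", start_pos = 101L, seed = 1L) {
  set.seed(seed)
  beta <- rnorm(n, 0, 0.05)
  se <- runif(n, 0.005, 0.02)
  data.frame(
    variant_id = paste0("rs", seq_len(n)),
    chrom = chrom,
    pos = start_pos + 10L * (seq_len(n) - 1L),
    effect_allele = rep_len(c("A", "C", "G"), n),
    other_allele = rep_len(c("G", "T", "A"), n),
    eaf = runif(n, 0.05, 0.95),
    beta = beta,
    se = se,
    pval = 2 * pnorm(-abs(beta / se)),
    n = 35559,
    stringsAsFactors = FALSE)
}

make_ss <- function(n = 5L, trait_id = "PROT", trait_type = "quantitative",
                    cohort = "decode", ...) {
  sumstat_set(trait_id, trait_type, cohort, make_variants(n, ...))
}

# single-region config: one causal cis pQTL, VTE and stroke outcomes
single_signal_config <- function(seed, m = 30L, rho = 0.9, lambda = 0.35,
                                 theta_stroke = 0.25, theta_vte = 0.35,
                                 causal = NULL, blocks = NULL) {
  if (is.null(causal)) causal <- max(1L, m %/% 2L)
  region <- sim_region("GENE1", "1", 1e6, 1e6 + 6e4, m = m, blocks = blocks,
                       rho = rho, freq_range = c(0.2, 0.8))
  sim_config(
    regions = list(GENE1 = region),
    proteins = list(GENE1 = sim_protein("GENE1", "GENE1", causal, lambda)),
    cohorts = list(decode = list(n = 35559), ukb = list(n = 46218)),
    outcomes = list(
      vte = sim_outcome("vte", 81190, 1419671,
                        theta = c(GENE1 = theta_vte)),
      stroke = sim_outcome("stroke", 62100, 1234808,
                           theta = c(GENE1 = theta_stroke))),
    seed = seed)
}

# an exposure/outcome record pair for harmonization tests
make_record <- function(variant_id = "rs1", ea = "A", oa = "G", eaf = 0.3,
                        beta = 0.1, se = 0.02) {
  data.frame(variant_id = variant_id, chrom = "1", pos = 100L,
             effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
             se = se, pval = 2 * pnorm(-abs(beta / se)), n = 1e4,
             stringsAsFactors = FALSE)
}

ALLELES <- c("A", "C", "G", "T")
COMP <- c(A = "T", T = "A", C = "G", G = "C")
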