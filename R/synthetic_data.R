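# Summary-statistic simulator with known causal structure.
#
# Summary statistics are drawn directly from the multivariate-normal model for
# GWAS z-scores under LD (the RSS likelihood): within a region with LD matrix
# R and joint-model noncentrality eta_j = beta_joint_j / SE_j,
#   z ~ MVN(R %*% eta, R),  beta = z * SE,
# with SE_j = 1/sqrt(2 n f_j (1-f_j)) on the per-SD scale for quantitative
# traits and SE_j = 1/sqrt(2 n phi (1-phi) f_j (1-f_j)) on the log-odds scale
# for binary traits (phi = case fraction). Outcome joint effects are
# theta * lambda (protein-mediated) plus any direct pleiotropy. This is exact
# under the assumed model and orders of magnitude faster than individual-level
# simulation; a small individual-level generator is provided separately as an
# oracle for conditional-analysis checks.

#' Build a block AR(1) LD matrix
#'
#' Within each block entry (i, j) equals `rho^|i-j|`; across blocks the
#' correlation is exactly zero. This mimics the block structure of reference
#' panel LD at a typical gene locus.
#'
#' @param m Number of variants.
#' @param blocks Integer vector of block sizes summing to `m` (default: one
#'   block).
#' @param rho AR(1) decay in `[0, 1)`, scalar or one value per block.
#' @param ids Variant ids for the dimnames (default `v1..vm`).
#' @return Validated LD matrix.
#' @export
make_ld <- function(m, blocks = NULL, rho = 0, ids = NULL) {
  stopifnot(m >= 1)
  if (is.null(blocks)) blocks <- m
  if (sum(blocks) != m) stop("block sizes must sum to m")
  if (any(rho < 0) || any(rho >= 1)) stop("rho must satisfy 0 <= rho < 1")
  rho <- rep_len(rho, length(blocks))
  if (is.null(ids)) ids <- paste0("v", seq_len(m))
  R <- matrix(0, m, m, dimnames = list(ids, ids))
  off <- 0L
  for (b in seq_along(blocks)) {
    idx <- off + seq_len(blocks[b])
    R[idx, idx] <- rho[b]^abs(outer(idx, idx, "-"))
    off <- off + blocks[b]
  }
  validate_ld(R)
}

#' Declare a simulated gene region
#'
#' A `sim_region` is a [gene_region()] augmented with the simulation
#' parameters for its variants: how many, their LD blocks and AR(1) decay,
#' and the allele-frequency range (kept inside \[0.01, 0.99\], mirroring the
#' minor-allele-frequency floor of the real outcome data).
#'
#' @inheritParams gene_region
#' @param m Number of variants in the region.
#' @param blocks LD block sizes (default one block).
#' @param rho AR(1) decay per block.
#' @param freq_range Length-2 range for effect-allele frequencies.
#' @return Object of classes `sim_region` and `gene_region`.
#' @export
sim_region <- function(gene_symbol, chrom, start, end, m, blocks = NULL,
                       rho = 0.9, freq_range = c(0.05, 0.95), flank = 0,
                       merged_with = NULL) {
  rg <- gene_region(gene_symbol, chrom, start, end, flank, merged_with)
  stopifnot(m >= 1, end - start >= m,
            length(freq_range) == 2L, freq_range[1] <= freq_range[2],
            freq_range[1] >= 0.01, freq_range[2] <= 0.99)
  rg$m <- as.integer(m)
  rg$blocks <- as.integer(blocks %||% m)
  rg$rho <- rho
  rg$freq_range <- freq_range
  class(rg) <- c("sim_region", class(rg))
  rg
}

#' Declare a simulated protein trait
#'
#' @param id Protein identifier (its trait id in the output).
#' @param region Name of the [sim_region()] containing its gene.
#' @param causal Integer indices (within the region) of its causal cis pQTLs.
#' @param lambda Per-allele effects on protein level, SD units, one per
#'   causal index.
#' @param cohorts Cohort labels in which the protein is measured.
#' @param sign_flip Optional cohort label whose reported betas for this
#'   protein are negated, emulating an assay/epitope artifact that reverses
#'   the apparent direction of association in one platform.
#' @return Object of class `sim_protein`.
#' @export
sim_protein <- function(id, region, causal, lambda,
                        cohorts = c("decode", "ukb"), sign_flip = NULL) {
  stopifnot(length(causal) == length(lambda), length(causal) >= 1L)
  structure(list(id = id, region = region, causal = as.integer(causal),
                 lambda = as.numeric(lambda), cohorts = cohorts,
                 sign_flip = sign_flip), class = "sim_protein")
}

#' Declare a simulated binary outcome
#'
#' @param id Outcome identifier.
#' @param n_case,n_control Case and control counts.
#' @param theta Named numeric: causal log-odds per SD of each protein
#'   (proteins not named have no effect).
#' @param pleiotropy Optional list of direct (non-protein-mediated) variant
#'   effects, each `list(region =, idx =, effect =)` on the log-odds scale —
#'   violations of the exclusion-restriction assumption, e.g. a confounding
#'   signal from a neighboring gene.
#' @return Object of class `sim_outcome`.
#' @export
sim_outcome <- function(id, n_case, n_control, theta = numeric(),
                        pleiotropy = NULL) {
  stopifnot(n_case + n_control > 0, n_case >= 0, n_control >= 0)
  structure(list(id = id, n_case = n_case, n_control = n_control,
                 theta = theta, pleiotropy = pleiotropy),
            class = "sim_outcome")
}

#' Assemble and validate a simulation configuration
#'
#' @param regions Named list of [sim_region()] objects.
#' @param proteins List of [sim_protein()] objects.
#' @param cohorts Named list, each `list(n = sample size)` for a proteomics
#'   cohort.
#' @param outcomes Named list of [sim_outcome()] objects.
#' @param overlap_fraction Correlation of association noise across traits
#'   induced by shared samples (0 = independent cohorts).
#' @param seed Master seed; all randomness derives from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(regions, proteins, cohorts, outcomes,
                       overlap_fraction = 0, seed = 1L) {
  stopifnot(length(regions) >= 1L, !is.null(names(regions)),
            overlap_fraction >= 0, overlap_fraction < 1)
  if (is.null(names(outcomes))) {
    names(outcomes) <- vapply(outcomes, `[[`, "", "id")
  }
  for (p in proteins) {
    if (!p$region %in% names(regions)) {
      stop("protein ", p$id, " references unknown region ", p$region)
    }
    if (max(p$causal) > regions[[p$region]]$m) {
      stop("protein ", p$id, " causal index beyond region size")
    }
    if (!all(p$cohorts %in% names(cohorts))) {
      stop("protein ", p$id, " references unknown cohort")
    }
  }
  pid <- vapply(proteins, `[[`, "", "id")
  if (anyDuplicated(pid)) stop("duplicate protein ids")
  names(proteins) <- pid
  for (o in outcomes) {
    if (!all(names(o$theta) %in% pid)) {
      stop("outcome ", o$id, " has theta for unknown protein")
    }
    for (pl in o$pleiotropy %||% list()) {
      if (!pl$region %in% names(regions)) {
        stop("pleiotropy references unknown region ", pl$region)
      }
    }
  }
  structure(list(regions = regions, proteins = proteins, cohorts = cohorts,
                 outcomes = outcomes, overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-region variant metadata (ids, positions, alleles, freqs)
region_meta <- function(config, i) {
  rg <- config$regions[[i]]
  set.seed(derive_seed(config$seed, 1L, i))
  pos0 <- rg$start + sort(sample.int(rg$end - rg$start, rg$m)) - 1
  f <- stats::runif(rg$m, rg$freq_range[1], rg$freq_range[2])
  alle <- t(vapply(seq_len(rg$m), function(j) sample(VALID_ALLELES, 2L),
                   character(2)))
  ids <- sprintf("rs%s_%.0f", rg$chrom, pos0 + 1)
  data.frame(variant_id = ids, chrom = rg$chrom, pos = as.integer(pos0 + 1),
             effect_allele = alle[, 1L], other_allele = alle[, 2L],
             eaf = f, region = names(config$regions)[i],
             stringsAsFactors = FALSE)
}

trait_table <- function(config) {
  traits <- list()
  for (p in config$proteins) {
    for (ch in p$cohorts) {
      traits[[paste(p$id, ch, sep = ".")]] <-
        list(kind = "protein", protein = p, cohort = ch,
             n = config$cohorts[[ch]]$n)
    }
  }
  for (onm in names(config$outcomes)) {
    traits[[onm]] <- list(kind = "outcome", outcome = config$outcomes[[onm]])
  }
  traits
}

# per-variant standard errors for a trait over one region's frequencies
trait_se <- function(spec, f) {
  if (spec$kind == "protein") {
    1 / sqrt(2 * spec$n * f * (1 - f))
  } else {
    n <- spec$outcome$n_case + spec$outcome$n_control
    phi <- spec$outcome$n_case / n
    1 / sqrt(2 * n * phi * (1 - phi) * f * (1 - f))
  }
}

# joint (conditional) per-allele effect vector for a trait over one region
trait_joint_effects <- function(config, spec, region_name, m) {
  b <- numeric(m)
  if (spec$kind == "protein") {
    if (spec$protein$region == region_name) {
      b[spec$protein$causal] <- b[spec$protein$causal] + spec$protein$lambda
    }
  } else {
    for (pid in names(spec$outcome$theta)) {
      p <- config$proteins[[pid]]
      if (p$region == region_name) {
        b[p$causal] <- b[p$causal] + spec$outcome$theta[[pid]] * p$lambda
      }
    }
    for (pl in spec$outcome$pleiotropy %||% list()) {
      if (pl$region == region_name) b[pl$idx] <- b[pl$idx] + pl$effect
    }
  }
  b
}

#' Simulate multi-trait GWAS summary statistics with known truth
#'
#' Draws, for every protein-by-cohort trait and every binary outcome in the
#' configuration, region-wise z-scores from `MVN(R %*% eta, R)` and converts
#' them to betas, SEs and two-sided normal p-values (floored at 1e-300 to
#' stay inside (0,1\] in text formats). Cohort overlap `o` mixes a shared
#' noise stream into every trait so that association noise correlates at `o`
#' across traits. Proteins flagged with a sign-flip cohort have that cohort's
#' betas negated. Fully reproducible from `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @return list with `sumstats` (named list of [sumstat_set()]; proteins keyed
#'   `"<protein>.<cohort>"`, outcomes by their id) and `truth` (`sim_truth`:
#'   variant metadata, causal ids, lambda, theta, expected z per trait and
#'   region, artifact flags).
#' @export
simulate_sumstats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nr <- length(config$regions)
  meta <- lapply(seq_len(nr), function(i) region_meta(config, i))
  names(meta) <- names(config$regions)
  Rs <- lapply(seq_len(nr), function(i) {
    rg <- config$regions[[i]]
    make_ld(rg$m, rg$blocks, rg$rho, ids = meta[[i]]$variant_id)
  })
  Ls <- lapply(Rs, function(R) t(chol(R)))
  names(Rs) <- names(Ls) <- names(config$regions)

  o <- config$overlap_fraction
  shared <- NULL
  if (o > 0) {
    shared <- lapply(seq_len(nr), function(i) {
      set.seed(derive_seed(config$seed, 2L, i))
      stats::rnorm(config$regions[[i]]$m)
    })
  }

  traits <- trait_table(config)
  sumstats <- list()
  expected_z <- list()
  for (k in seq_along(traits)) {
    tn <- names(traits)[k]
    spec <- traits[[k]]
    set.seed(derive_seed(config$seed, 3L, k))
    rows <- vector("list", nr)
    ez <- vector("list", nr)
    for (i in seq_len(nr)) {
      mt <- meta[[i]]
      m <- nrow(mt)
      se <- trait_se(spec, mt$eaf)
      bj <- trait_joint_effects(config, spec, names(config$regions)[i], m)
      eta <- bj / se
      mu <- as.vector(Rs[[i]] %*% eta)
      u <- stats::rnorm(m)
      if (o > 0) u <- sqrt(1 - o) * u + sqrt(o) * shared[[i]]
      z <- mu + as.vector(Ls[[i]] %*% u)
      flip <- spec$kind == "protein" &&
        identical(spec$protein$sign_flip, spec$cohort)
      if (flip) z <- -z
      ez[[i]] <- if (flip) -mu else mu
      rows[[i]] <- data.frame(
        variant_id = mt$variant_id, chrom = mt$chrom, pos = mt$pos,
        effect_allele = mt$effect_allele, other_allele = mt$other_allele,
        eaf = mt$eaf, beta = z * se, se = se,
        pval = pmax(2 * stats::pnorm(-abs(z)), 1e-300),
        n = if (spec$kind == "protein") spec$n else {
          spec$outcome$n_case + spec$outcome$n_control
        },
        stringsAsFactors = FALSE)
    }
    names(ez) <- names(config$regions)
    expected_z[[tn]] <- ez
    sumstats[[tn]] <- sumstat_set(
      trait_id = if (spec$kind == "protein") spec$protein$id else spec$outcome$id,
      trait_type = if (spec$kind == "protein") "quantitative" else "binary",
      cohort_label = if (spec$kind == "protein") spec$cohort else "",
      variants = do.call(rbind, rows))
  }

  truth <- structure(list(
    seed = config$seed,
    variants = do.call(rbind, c(meta, list(make.row.names = FALSE))),
    proteins = lapply(config$proteins, function(p) {
      list(region = p$region,
           causal_ids = meta[[p$region]]$variant_id[p$causal],
           causal_idx = p$causal, lambda = p$lambda,
           sign_flip = p$sign_flip)
    }),
    outcomes = lapply(config$outcomes, function(oc) {
      list(theta = as.list(oc$theta), pleiotropy = oc$pleiotropy)
    }),
    expected_z = expected_z), class = "sim_truth")

  list(sumstats = sumstats, ld = Rs, truth = truth)
}

#' Write a simulated fixture bundle to disk
#'
#' Emits `sumstats/<trait>.tsv`, `ld/<region>.ld.txt`, `genes.bed`,
#' `truth.json` and `config.yaml` under `dir`. Deterministic: the same
#' configuration (including its seed) produces byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, the simulation result (as [simulate_sumstats()]).
#' @export
write_fixture <- function(config, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop("output directory ", dir, " is not empty (use force = TRUE)")
  }
  dir.create(file.path(dir, "sumstats"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ld"), recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_sumstats(config)
  for (tn in names(sim$sumstats)) {
    write_sumstats(sim$sumstats[[tn]], file.path(dir, "sumstats",
                                                 paste0(tn, ".tsv")))
  }
  for (rn in names(sim$ld)) {
    write_ld(sim$ld[[rn]], file.path(dir, "ld", paste0(rn, ".ld.txt")))
  }
  write_genes_bed(config$regions, file.path(dir, "genes.bed"))
  truth <- sim$truth
  truth_json <- list(
    seed = truth$seed,
    variants = truth$variants,
    proteins = truth$proteins,
    outcomes = truth$outcomes)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(serialize_config(config), file.path(dir, "config.yaml"))
  invisible(sim)
}

serialize_config <- function(config) {
  list(
    seed = config$seed,
    overlap_fraction = config$overlap_fraction,
    regions = lapply(config$regions, function(r) {
      list(gene_symbol = r$gene_symbol, chrom = r$chrom, start = r$start,
           end = r$end, m = r$m, blocks = as.list(r$blocks), rho = r$rho,
           freq_range = as.list(r$freq_range),
           merged_with = as.list(r$merged_with %||% character()))
    }),
    proteins = lapply(config$proteins, function(p) {
      list(id = p$id, region = p$region, causal = as.list(p$causal),
           lambda = as.list(p$lambda), cohorts = as.list(p$cohorts),
           sign_flip = p$sign_flip)
    }),
    cohorts = lapply(config$cohorts, function(ch) list(n = ch$n)),
    outcomes = lapply(config$outcomes, function(oc) {
      list(id = oc$id, n_case = oc$n_case, n_control = oc$n_control,
           theta = as.list(oc$theta),
           pleiotropy = lapply(oc$pleiotropy %||% list(), function(pl) {
             list(region = pl$region, idx = pl$idx, effect = pl$effect)
           }))
    }))
}

#' Rebuild a simulation configuration from a fixture's config.yaml
#'
#' @param path Path to a `config.yaml` written by [write_fixture()].
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  regions <- lapply(y$regions, function(r) {
    sim_region(r$gene_symbol, r$chrom, r$start, r$end, m = r$m,
               blocks = unlist(r$blocks), rho = r$rho,
               freq_range = unlist(r$freq_range),
               merged_with = if (length(r$merged_with)) unlist(r$merged_with))
  })
  names(regions) <- names(y$regions)
  proteins <- lapply(y$proteins, function(p) {
    sim_protein(p$id, p$region, unlist(p$causal), unlist(p$lambda),
                cohorts = unlist(p$cohorts), sign_flip = p$sign_flip)
  })
  outcomes <- lapply(y$outcomes, function(oc) {
    sim_outcome(oc$id, oc$n_case, oc$n_control,
                theta = unlist(oc$theta) %||% numeric(),
                pleiotropy = if (length(oc$pleiotropy)) oc$pleiotropy)
  })
  names(outcomes) <- names(y$outcomes)
  sim_config(regions, proteins, y$cohorts, outcomes,
             overlap_fraction = y$overlap_fraction, seed = y$seed)
}

#' Simulate individual-level genotypes at two linked variants
#'
#' Small-scale individual-level generator used as an independent oracle for
#' summary-statistic conditional analysis: haplotypes at two biallelic loci
#' with allele frequencies `f1`, `f2` and haplotype (allelic) correlation `r`
#' are drawn from the implied 2x2 haplotype table, and genotypes are the sum
#' of two independent haplotypes (Hardy-Weinberg equilibrium).
#'
#' @param n Number of diploid individuals.
#' @param f1,f2 Allele frequencies.
#' @param r Haplotype correlation; must be compatible with the frequencies
#'   (the implied haplotype table must have non-negative entries).
#' @return list with integer genotype vectors `g1`, `g2` (values 0/1/2).
#' @export
simulate_genotype_pair <- function(n, f1, f2, r) {
  d <- r * sqrt(f1 * (1 - f1) * f2 * (1 - f2))
  p <- c(`11` = f1 * f2 + d, `10` = f1 * (1 - f2) - d,
         `01` = (1 - f1) * f2 - d, `00` = (1 - f1) * (1 - f2) + d)
  if (any(p < -1e-12)) {
    stop("r = ", r, " is infeasible for frequencies ", f1, ", ", f2)
  }
  p <- pmax(p, 0)
  hap <- matrix(sample.int(4L, 2L * n, replace = TRUE, prob = p), ncol = 2L)
  a1 <- hap <= 2L            # haplotypes 1 and 2 carry allele 1 at locus 1
  a2 <- hap %% 2L == 1L      # haplotypes 1 and 3 carry allele 1 at locus 2
  list(g1 = as.integer(rowSums(a1)), g2 = as.integer(rowSums(a2)))
}
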