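---
title: "Methods: cis-pQTL Mendelian randomization for coagulation proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-pQTL Mendelian randomization for coagulation proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coagmr)
```

## Scope and model

`coagmr` estimates causal effects of circulating coagulation cascade
proteins on binary thrombotic outcomes (ischemic stroke and its subtypes,
venous thromboembolism) from GWAS summary statistics, and corroborates them
with regional colocalization evidence. The causal model is the standard
two-sample MR one: a cis variant j in the protein's gene perturbs protein
level X by λ_j SD per allele; the protein shifts outcome liability by θ
log-odds per SD; the variant has no other path to the outcome. Under that
model the per-allele outcome association is β_Yj = θ·λ_j, so θ is estimable
as a ratio (one variant) or a zero-intercept regression slope (several).

Three instrument sources are kept separate throughout, mirroring the study
design this package operationalizes: pQTLs from each of two proteomics
cohorts (SomaScan-style and Olink-style platforms, n ≈ 35.6k and 46.2k),
and VTE-liability variants inside the gene for proteins whose functional
variation is not visible as a concentration change. Liability-derived
estimates are reported per doubling of VTE odds: the Wald numerator is
divided by the variant's VTE log-odds and multiplied by ln 2, so "θ = 0.2"
reads "a doubling of VTE risk through this locus carries e^0.2-fold stroke
odds".

## Instrument selection

The cascade per protein and source is: restrict to the gene body (BED-style
0-based half-open interval; `flank = 0` by default because the cis
definition is the gene itself, configurable since regulatory variants
can sit outside it); keep p < 5×10⁻⁸; keep MAF ≥ 0.01; keep variants
present in the outcome GWAS; keep variants with nominal VTE association
(p < 0.05; a switch disables this for sensitivity analysis, and disabling
it can only enlarge the candidate pool); finally greedy LD clumping at
r² < 0.001. Clumping ranks by ascending p-value; exact p ties — which in
practice arise when p-values underflow the double range (|z| ≳ 37, floored
at 10⁻³⁰⁰ in text output) — are refined by descending |z|, then position,
then variant id, so the association peak still leads and the result is
deterministic. Directional concordance between exposure and liability
effects is *not* required; the support filter is a p-value condition only.

Proteins whose cascade ends empty are flagged `no_proxy` and simply drop
out of MR; the number of *covered* proteins defines the family for the
Bonferroni plan (0.05/30 = 0.0017 at the study's coverage; the
cross-trait library uses 0.05/(tested variant×protein pairs), 3.6×10⁻⁵ at
46×30).

## Harmonization

Outcome betas are aligned to the exposure's effect allele: label swaps
negate beta and complement the frequency; non-palindromic strand flips
relabel silently. Palindromic variants (A/T, C/G) carry no strand
information, so they are oriented by frequency concordance — whichever of
eaf and 1−eaf is closer to the exposure frequency — but only when MAF ≤
0.42 in *both* data sets (the threshold is applied to each side; with MAF
near ½ the concordance signal vanishes, and the variant is excluded as
ambiguous). Missing outcome frequency also excludes a palindromic variant,
since orientation cannot be checked. Exclusion is a value with a
machine-readable reason, not an error, and harmonization is idempotent and
gauge-invariant (relabeling either input's alleles with the matching sign
and frequency changes leaves all downstream estimates unchanged).

## Estimators

*Wald ratio*: θ̂ = β_Y/β_X, SE = se_Y/|β_X| (first-order delta method).
*IVW*: θ̂ = Σw β_X β_Y / Σw β_X² with w = 1/se_Y², the zero-intercept
weighted regression of outcome on exposure betas. Heterogeneity is handled
multiplicatively: Cochran's Q on J−1 degrees of freedom inflates the SE by
√max(1, Q/(J−1)). The floor at 1 means over-dispersion can widen but never
narrow the interval; the cost is mild conservatism of the test in the far
tail (analytically, the rejection rate at α = 0.0017 with J = 15 valid
instruments is ≈ 0.0012). A single pair reduces exactly to the Wald ratio.
*Multivariable MR* generalizes the same weighted regression to K exposure
columns (inflation denominator J−K), isolating each protein's direct
effect when neighboring genes' pQTLs are correlated; rank deficiency is a
named error. CIs use the 1.96 normal quantile and p-values the normal
distribution throughout — the summary-statistic MR convention, J being
small notwithstanding.

## Regional inference

Colocalization enumerates single-causal-variant configurations for two
traits over a shared regional variant list. Per-variant evidence is the
Wakefield log approximate Bayes factor, log BF = ½log(1−r) + ½r z² with
r = W/(V+W); effect priors default to W = 0.15² (per-SD protein traits)
and 0.2² (log-odds outcome traits), and configuration priors to
p1 = p2 = 10⁻⁴, p12 = 10⁻⁵ — field-standard defaults, declared rather than
inferred, since the analysis they stand in for used a multi-trait method
whose exact priors are not public. Hypothesis sums are accumulated on the
log scale (log-sum-exp; the H3 cross term uses log1p(−e^d) with a guard for
the degenerate m = 1 case), so posteriors sum to 1 to machine precision at
any signal strength.

Conditional analysis assumes standardized genotypes:
z_cond = (z_j − r_{j,idx} z_idx)/√(1−r²_{j,idx}), with the index's own
conditional z set to 0 and perfect-LD partners flagged inestimable —
adequate at the MAF floor of 0.01, and verified in the test suite against a
joint regression on simulated individual-level genotypes (agreement within
10% for |r| ≤ 0.95; observed discrepancies are below 1%). Stepwise signal
counting repeats min-p selection (ranked on |z|) and conditioning — also
updating the LD matrix to partial correlations — until no variant remains
below `stop_p`, which defaults to the regional Bonferroni 0.05/m.
Single-signal fine-mapping assigns PIP_j = BF_j/ΣBF_k under a uniform
causal prior and reports the smallest descending-PIP prefix reaching 95%
coverage, ties broken by position.

## The simulator

Summary statistics are drawn directly from the multivariate-normal model
for GWAS z-scores under LD: per region, z ~ MVN(Rη, R), where
η_j = b_j/SE_j is the joint-model noncentrality, with SE_j =
1/√(2n f_j(1−f_j)) for per-SD quantitative traits and
1/√(2n φ(1−φ) f_j(1−f_j)) for log-odds binary traits (φ = case fraction;
the standard logistic approximation, with no rare-disease correction).
Outcome joint effects are θ·λ plus any configured direct pleiotropy. LD is
block AR(1): entry ρ^|i−j| within a block, 0 across blocks — a stylized but
convenient stand-in for reference-panel LD with exact, fast Cholesky
sampling. One master seed drives everything through per-purpose,
per-index derived streams (variant metadata / shared overlap noise /
per-trait draws), so adding a trait to a configuration never perturbs the
draws of existing traits. Cohort sample overlap o mixes a shared noise
stream into every trait, giving cross-trait noise correlation exactly o
(default 0: the real overlap is described only as "small"). Assay/epitope
artifacts are modeled as a pure sign flip of one cohort's betas for a
flagged protein.

Default study conditions follow the real data sets: proteomics cohorts
n = 35 559 and 46 218; VTE 81 190 cases / 1 419 671 controls; stroke
62 100 cases / 1 234 808 controls. The demonstration panel
(`demo_config()`) uses 20 proteins — 5 stroke-causal with θ = log of
(1.31, 1.19, 1.83, 0.88, 1.44), the magnitude spectrum of the effects this
protein family is expected to show, and 15 VTE-only with |θ_VTE| = 0.35 —
each with a single cis pQTL of λ = 0.35 SD per allele in a 30-variant,
two-block ρ = 0.9 region. The λ and region size were chosen once as
typical of strong plasma pQTLs at these sample sizes (causal z ≈ 40); ρ =
0.9 reflects the tight LD of a gene-sized window.

What the simulator does **not** emulate: realistic LD from a reference
panel (no long-range structure, no allele-frequency/LD coupling),
imputation error, population stratification, assay-specific measurement
models beyond the sign flip, overlapping gene annotations, indels, and
allele-frequency mismatch between cohorts beyond noise. Passing tests
therefore demonstrate correctness of the estimators and decision logic
under the assumed sampling model — not robustness to reference-panel
mismatch or cryptic structure in real consortium data.

## Numerical choices and edge cases

P-values are floored at 10⁻³⁰⁰ to stay inside (0,1] in text formats; all
internal ranking that could hit the floor uses |z| instead. Doubles are
serialized with 17 significant digits so fixture round trips are
bit-exact. LD matrices are validated on read (symmetry to 10⁻⁸ then
symmetrized, unit diagonal, |r| ≤ 1, eigenvalues ≥ −10⁻⁸). The
p-value/beta/se consistency check on summary input warns by default and
rejects only in strict mode, because published summary files round
p-values. Variants in perfect LD with a conditioning index are excluded
from residual-significance tests rather than producing infinities.

## Operating points

The acceptance suite (`tests/testthat/test-acceptance.R`, reproduced by
`scripts/acceptance.R`) measures, at the study scale: IVW recovery of
θ = log 1.31 with 20 instruments (mean within 2 Monte-Carlo SE; CI coverage
93–97%); null rejection at α = 0.0017 within the exact binomial band over
10⁴ replicates; exact agreement (10⁻¹⁰) of IVW/MVMR with an independent
weighted-least-squares fit and of clumping with an exhaustively verified
greedy pass; colocalization calling PP(H4) > 0.9 (shared) and PP(H3) > 0.9
(distinct) in ≥ 90% of seeds at noncentrality 8; conditional clearance of
single-signal regions in ≥ 95% of seeds; and end-to-end sensitivity ≥ 0.8
with zero VTE-only false positives on the 5+15 panel. Replicate counts
(500 / 10⁴ / 200 / 50) are the package's chosen design sizes: large enough
that the Monte-Carlo error is a fraction of each tolerance band.

## Limitations

Colocalization here is strictly pairwise two-trait enumeration under a
single-causal-variant assumption; multi-trait clustering and multi-signal
fine-mapping are out of scope, and regions with multiple causal variants
per trait can push posterior mass to H3/H4 in ways the single-signal model
does not represent. Conditional analysis ignores per-variant genotype
variance differences. The per-doubling scale inherits the sign of the
VTE effect (an estimate is "per doubling of VTE odds via this locus", so a
protective locus yields an inverted ratio — read the sign together with
the VTE direction). MR-Egger, weighted-median and Steiger-style filters
are deliberately absent, as is any handling of X-chromosome genes.
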