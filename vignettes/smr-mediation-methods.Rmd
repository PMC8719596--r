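---
title: "Multi-omics SMR and HEIDI: models, calibration and design choices"
author: "smrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics SMR and HEIDI: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrmediate)
```

## The model

Summary-data Mendelian randomization (SMR) asks whether a molecular
phenotype `x` (the expression of a gene, or the methylation level of a CpG
probe) has a pleiotropic — potentially causal — association with a complex
trait `y`, using only summary statistics from separate studies. A single
cis-SNP `z` (the probe's strongest cis-QTL) serves as the instrument. With
marginal effect estimates `b_zx` (SNP on the molecular phenotype, from a
QTL study) and `b_zy` (SNP on the trait, from a GWAS), the ratio estimate
is

    b_xy = b_zy / b_zx .

Writing `z_zx = b_zx / se_zx` and `z_zy = b_zy / se_zy`, the SMR test
statistic is

    T_SMR = z_zx^2 * z_zy^2 / (z_zx^2 + z_zy^2) ,

referred to a 1-df chi-square; the delta-method standard error is
`se_xy = |b_xy| / sqrt(T_SMR)`. `T_SMR` is symmetric in the two
z-statistics and bounded above by both of their squares, so the test can
never be more significant than the weaker of the instrument-exposure and
instrument-outcome associations.

A significant `T_SMR` cannot distinguish a single causal variant affecting
both `x` and `y` (pleiotropy/causality) from two distinct variants in
linkage disequilibrium, each affecting one of them. The HEIDI
(heterogeneity in dependent instruments) test addresses this: every
sufficiently strong cis-SNP `i` yields its own ratio estimate `b_xy(i)`,
and under the single-causal-variant null these all estimate the same
quantity. The contrasts `d_i = b_xy(i) − b_xy(top)` are combined as

    T_HEIDI = sum_i d_i^2 / var(d_i) ,

whose null distribution is a weighted sum of 1-df chi-squares,
`sum_k lambda_k chi2_1`, with `lambda_k` the eigenvalues of the
correlation matrix of the standardized contrasts. Rejection (small
`p_HEIDI`) flags heterogeneity — i.e. linkage — and such probes are
excluded from the pleiotropic candidate list.

The mediation layer combines three SMR analyses: methylation → trait,
expression → trait, and methylation → expression (methylation as exposure,
instrumented by its top cis-mQTL, with the expression probe's cis records
supplying the outcome effects). A (DNAm probe, expression probe) pair on
the same chromosome and within 2 Mb whose three links all pass SMR
significance and HEIDI supports the chain SNP → DNAm → expression → trait.
The consistency verdict is a sign check: the product `b_m2e * b_e2t` must
have the same sign as the direct `b_m2t`; the relative deviation of the
product from the direct estimate is reported but, deliberately, not used
as a hard filter — sampling noise in three ratio estimates makes a product
criterion unstable, while the sign is robust.

## Covariance of dependent ratio estimates

`bxyCovariance()` propagates errors to first order. Within one dataset,
marginal effect estimates at two SNPs in LD have
`cov(b_i, b_j) = r_ij se_i se_j`, where `r_ij` is the allelic correlation
from the reference panel; across the two datasets the estimates are
independent (two-sample design, non-overlapping cohorts). Then

    cov(b_xy_i, b_xy_j) =   r_ij se_zy_i se_zy_j / (b_zx_i b_zx_j)
                          + b_zy_i b_zy_j r_ij se_zx_i se_zx_j /
                            (b_zx_i^2 b_zx_j^2)

and `cov(d_i, d_j)` follows by expanding the contrasts against the top
SNP. Higher-order terms are neglected; the test suite validates the
first-order matrix against a Monte-Carlo propagation oracle (100,000
multivariate-normal resamples) to within 5%. The approximation degrades
when instruments are weak, which is why HEIDI SNPs must individually pass
the chi-square = 10 inclusion threshold (`p < 1.57e-3`) — below that,
ratio estimates are too unstable to compare.

## Quadratic-form p-values

`quadFormPvalue()` evaluates the upper tail of `sum lambda_k chi2_1` by
Imhof's numerical inversion of the characteristic function, integrating
`sin(theta(u)) / (u rho(u))` over `(0, Inf)` with R's adaptive
quadrature (relative tolerance `1e-10`, 10,000 subdivisions). If the
reported integration error exceeds 1% of the value, or the value falls
outside `[0, 1]`, the function falls back to the Satterthwaite
moment-matched scaled chi-square (`g * chi2_h` with `g = s2/s1`,
`h = s1^2/s2`) and flags the method in the result, which the pipeline
carries through to the output tables. In the test suite the Imhof route
agrees with direct Monte-Carlo tails within 10% for p between 0.001 and
0.5.

## Thresholds and defaults

All defaults live in `pipelineConfig()`:

| parameter | default | meaning |
|---|---|---|
| `cis_window` | 2e6 bp | cis records kept within ±2 Mb of the probe (inclusive boundary) |
| `p_top_qtl` | 5e-8 | a probe enters the analysis only if its best cis-QTL passes genome-wide significance |
| `heidi_inclusion_p` | 1.57e-3 | HEIDI SNP inclusion; equals the chi-square = 10 instrument-strength rule |
| `r2_upper` / `r2_lower` | 0.9 / 0.05 | prune SNPs in very strong LD with, or nearly independent of, the top QTL |
| `max_heidi_snps` | 20 | cap, keeping smallest QTL p (ties: position, then id) |
| `min_heidi_snps` | 3 | below this the probe is HEIDI non-testable and excluded from pass lists |
| `heidi_pass_p` | 0.01 | pass when `p_HEIDI >= 0.01` (not rejected at 0.01) |
| `alpha` | 0.05 | family-wise level; per-layer threshold is `alpha / n_eligible` |
| `m2t_max_distance` | 2e6 bp | DNAm-expression pairing distance, strict `<` |

The multiple-testing burden of each layer is the number of probes
*actually analyzed* in that layer (those with a genome-wide-significant
top cis-QTL), not a fixed constant; for the methylation → expression step
it is the number of distance-eligible pairs, which the pipeline logs. The
corrected threshold is Bonferroni `alpha / n`; a Benjamini–Hochberg
alternative is available via `multiple_testing = "bh"` for comparison,
since the two differ once many probes are truly associated.

Boundary conventions, chosen once and fixed: the cis window is inclusive
(`|pos − probe_pos| <= 2 Mb`), the pairing distance is strict
(`< 2 Mb`), coordinates are 1-based, and all tie-breaks (top-QTL
selection, HEIDI capping) are deterministic: smallest p, then smallest
position, then lexicographic SNP id.

## Allele harmonization

Effect alleles are aligned dataset-by-dataset against the QTL exposure
records (and panel dosages are re-oriented to the same coding before LD is
computed, so the sign of r is meaningful). Swapped alleles flip the sign
of `b` and map `freq` to `1 − freq`; strand flips are resolved through
base complementing. Palindromic SNPs (A/T, C/G) are strand-ambiguous:
they are dropped when the effect-allele frequency is missing or in
[0.40, 0.60], and otherwise oriented by frequency agreement when the
reference frequency is informative (falling back to allele labels when it
is not). Duplicate SNP ids keep the first record with a warning.
Harmonization is an involution, and all downstream estimates are
invariant under consistent allele re-coding of any single input — both
properties are asserted in the test suite.

## What the synthetic-data generator emulates

`simulateGenotypes()` draws a latent Gaussian AR(1) vector per sample
(adjacent-SNP correlation `rho`, default 0.8) and thresholds it at each
SNP's Hardy–Weinberg genotype frequencies, giving 0/1/2 dosages whose LD
decays geometrically with distance. This reproduces the one feature HEIDI
actually consumes — a smooth local LD structure — at a tiny fraction of
the cost of coalescent simulation. It does *not* emulate recombination
hotspots, allele-frequency/LD coupling, rare variants, or realistic human
haplotype blocks; passing tests therefore demonstrate the statistics are
computed correctly under a plausible LD regime, not that power estimates
transfer to any particular human locus.

`simulateMediationCohort()` draws a reference panel and three
non-overlapping cohorts (DNAm, expression, trait) sharing the locus's
frequencies and LD, then generates phenotypes under one of four
architectures (mediation, pleiotropy, linkage, null; see
`?simulationScenario`). The trait is continuous: the SMR machinery
consumes only `(b, se)` pairs, so the test mechanics are identical to a
liability-scale analysis while staying tractable; a logistic option is
out of scope. Cohorts are disjoint, matching the two-sample design of
blood QTL studies versus a separate GWAS, which is what justifies the
vanishing cross-dataset covariance in the HEIDI derivation. Multi-locus
studies are concatenations of independent loci, one probe pair per locus,
each on its own chromosome — adequate because the analysis is strictly
cis.

Default study conditions: 20 SNPs per locus, `rho = 0.8`, MAF uniform on
[0.1, 0.5], reference panel n = 500, molecular cohorts n = 2,000, trait
cohort n = 20,000 — the scale of blood eQTL/mQTL resources paired with a
large GWAS. The default effect chain is `b1 = 0.5` (SNP → DNAm),
`b2 = −0.9` (DNAm → expression), `b3 = −0.05` (expression → trait),
mirroring the sign structure and magnitude of a published
methylation–expression–atrial-fibrillation axis; the implied
methylation-to-trait effect is `b2 * b3 = 0.045`.

One consequence of that realistic choice deserves emphasis: at
`b3 = −0.05` the SNP-on-trait effect is `0.5 × 0.9 × 0.05 ≈ 0.023`, a
GWAS z-statistic of about 2 at n = 20,000 — real, but far below any
corrected significance threshold. Parameter-recovery calibration
(unfiltered estimates: mean bias, CI coverage) therefore uses this
default chain, while *detection*-oriented properties (the planted locus
must surface as exactly one consistent triplet after all filters) plant
`b3 = −0.15`, whose trait signal (z ≈ 6) is genome-wide significant by
construction. This separation is deliberate: a recovery property at
`b3 = −0.05` would measure statistical power, not pipeline correctness.

## Numerical choices and degenerate inputs

* Contrast variances below `1e-12` (near-perfect LD that survived
  pruning) drop the SNP before standardization.
* If the standardized-contrast correlation matrix is numerically
  non-PSD, an escalating ridge (from `1e-8`) is added to the diagonal and
  the matrix renormalized; unrecoverable matrices make the probe HEIDI
  non-testable rather than producing a spurious p-value.
* `b_zx = 0` makes the ratio undefined (probe skipped); `b_zy = 0` gives
  `T_SMR = 0`, `p = 1`, and a missing `se_xy`.
* Regression p-values that underflow are floored at the smallest positive
  double so the (0, 1] invariant holds.
* LD is computed pairwise-complete over non-missing dosages;
  monomorphic SNPs and pairs with fewer than 2 overlapping samples are
  hard errors naming the SNP.

## Problem sizes used in validation

The packaged validation runs at sizes a laptop handles in minutes, chosen
to keep Monte-Carlo error well inside each assertion's margin: 500
null-scenario probes for SMR type-I error, 1,000 pleiotropy replicates
for HEIDI calibration (rejection at 0.05 and KS distance from
uniformity), 100 mediation replicates for estimator bias and CI coverage,
100,000-draw Monte-Carlo oracles for the covariance and quadratic-form
approximations, and 50 seeded four-locus studies for planted-pair
recovery through the full pipeline.

## Known limitations

* First-order error propagation understates contrast covariances for
  weak instruments; the chi-square = 10 inclusion rule is the guard, and
  residual miscalibration appears as the mild HEIDI conservatism/
  anti-conservatism the calibration tests bound at 0.08.
* The generator's AR(1) LD cannot produce the pathological LD
  configurations (e.g. long-range haplotypes) where HEIDI is known to be
  least reliable.
* Only biallelic SNVs are handled; indels, multi-allelics and trans-QTL
  analyses are out of scope, as is binary-trait simulation.
* Tissue-specificity enrichment requires a user-supplied gene × tissue
  t-statistic matrix (e.g. derived from GTEx); none is shipped.
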