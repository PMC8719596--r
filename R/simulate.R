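#' Define a simulation scenario
#'
#' Bundles the parameters of the synthetic-data generator: locus size and LD
#' decay, allele-frequency range, cohort sizes, and the causal architecture
#' connecting SNP, DNA methylation (m), expression (e) and trait (t).
#'
#' Architectures:
#' \describe{
#'   \item{mediation}{m = b1 g + eps; e = b2 m + eps; t = b3 e + eps. The
#'     implied molecular effects on the trait are b2*b3 (m -> t) and b3
#'     (e -> t).}
#'   \item{pleiotropy}{m, e and t all depend directly on the same causal
#'     SNP (effects b1, bDirectE, bDirectT); no path through the molecular
#'     phenotypes, so the single-causal-variant HEIDI null holds.}
#'   \item{linkage}{the molecular phenotypes are driven by one SNP and the
#'     trait by a distinct SNP in LD with it (target r-squared
#'     `r2Linkage`); HEIDI should reject.}
#'   \item{null}{molecular phenotypes have cis-QTLs but the trait is pure
#'     noise.}
#' }
#'
#' All phenotype noise terms are standard normal, so effects are on the
#' scale of trait standard deviations per allele (or per unit of the
#' upstream phenotype).
#'
#' @param scenario one of `"mediation"`, `"pleiotropy"`, `"linkage"`,
#'   `"null"`.
#' @param nSnps SNPs in the locus (default 20).
#' @param rho adjacent-SNP latent AR(1) correlation (default 0.8).
#' @param mafRange range of effect-allele frequencies (default 0.1-0.5).
#' @param nRef,nQtl,nGwas reference panel, molecular cohort and trait
#'   cohort sizes (defaults 500, 2000, 20000).
#' @param b1,b2,b3 mediation-path effects (defaults 0.5, -0.9, -0.05).
#' @param bDirectE,bDirectT direct SNP effects on expression and trait in
#'   the pleiotropy/linkage architectures (defaults 0.5, 0.1).
#' @param r2Linkage target r-squared between the molecular- and
#'   trait-causal SNPs in the linkage architecture (default 0.4).
#' @param seed RNG seed.
#' @param chrom,posStart,posStep,idPrefix,probePrefix locus naming/placement.
#' @return a validated scenario list of class `"SimulationScenario"`.
#' @export
simulationScenario <- function(scenario = c("mediation", "pleiotropy",
                                            "linkage", "null"),
        nSnps = 20L, rho = 0.8, mafRange = c(0.1, 0.5),
        nRef = 500L, nQtl = 2000L, nGwas = 20000L,
        b1 = 0.5, b2 = -0.9, b3 = -0.05,
        bDirectE = 0.5, bDirectT = 0.1, r2Linkage = 0.4,
        seed = 1L, chrom = "1", posStart = 1e6, posStep = 1000,
        idPrefix = "rs", probePrefix = "L1") {
    scenario <- match.arg(scenario)
    stopifnot(nSnps >= 1, rho > -1, rho < 1,
              nRef >= 2, nQtl >= 2, nGwas >= 2,
              mafRange[1L] > 0, mafRange[2L] <= 0.5,
              r2Linkage > 0, r2Linkage < 1)
    structure(list(scenario = scenario, nSnps = as.integer(nSnps),
        rho = rho, mafRange = mafRange, nRef = as.integer(nRef),
        nQtl = as.integer(nQtl), nGwas = as.integer(nGwas),
        b1 = b1, b2 = b2, b3 = b3, bDirectE = bDirectE,
        bDirectT = bDirectT, r2Linkage = r2Linkage, seed = seed,
        chrom = as.character(chrom), posStart = posStart,
        posStep = posStep, idPrefix = idPrefix,
        probePrefix = probePrefix), class = "SimulationScenario")
}

#' Simulate genotype dosages with AR(1) linkage disequilibrium
#'
#' Latent Gaussian AR(1) copula: each sample draws a latent vector with
#' adjacent-SNP correlation `rho`, thresholded per SNP at the
#' Hardy-Weinberg genotype frequencies implied by its effect-allele
#' frequency, giving dosages in \{0, 1, 2\}. Deterministic given `seed`.
#'
#' @param nSamples samples to draw.
#' @param nSnps SNPs in the locus.
#' @param rho latent adjacent-SNP correlation in (-1, 1).
#' @param mafRange range effect-allele frequencies are drawn from.
#' @param seed optional seed (omit to use the current RNG stream).
#' @param mafs optional explicit per-SNP frequencies (overrides
#'   `mafRange`).
#' @param chrom,posStart,posStep,idPrefix SNP naming/placement.
#' @return A [GenotypePanel-class]; attribute `mafs` holds the frequencies
#'   used.
#' @export
simulateGenotypes <- function(nSamples, nSnps, rho,
        mafRange = c(0.1, 0.5), seed = NULL, mafs = NULL,
        chrom = "1", posStart = 1e6, posStep = 1000, idPrefix = "rs") {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(nSamples >= 2, nSnps >= 1, rho > -1, rho < 1)
    if (is.null(mafs))
        mafs <- stats::runif(nSnps, mafRange[1L], mafRange[2L])
    if (any(mafs <= 0 | mafs > 0.5 | !is.finite(mafs)))
        stop("degenerate MAF: frequencies must lie in (0, 0.5]")
    Z <- matrix(stats::rnorm(nSamples * nSnps), nSamples, nSnps)
    if (nSnps > 1L && rho != 0) {
        sc <- sqrt(1 - rho^2)
        for (j in 2:nSnps) Z[, j] <- rho * Z[, j - 1L] + sc * Z[, j]
    }
    q0 <- stats::qnorm((1 - mafs)^2)   # below: dosage 0
    q2 <- stats::qnorm(1 - mafs^2)     # above: dosage 2
    D <- t((t(Z) > q0) + (t(Z) > q2)) * 1
    snps <- data.frame(
        snp = paste0(idPrefix, seq_len(nSnps)),
        chrom = chrom,
        pos = posStart + (seq_len(nSnps) - 1L) * posStep,
        a1 = "A", a2 = "G", stringsAsFactors = FALSE)
    panel <- GenotypePanel(sampleIds = paste0("S", seq_len(nSamples)),
                           snps = snps, dosages = D)
    attr(panel, "mafs") <- mafs
    panel
}

#' Per-SNP marginal association summary statistics
#'
#' Simple linear regression of the phenotype on each SNP's dosage: slope,
#' standard error, and two-sided p-value from the t distribution with
#' n - 2 degrees of freedom. Monomorphic SNPs are dropped with a message.
#'
#' @param panel A [GenotypePanel-class] holding the cohort's genotypes.
#' @param phenotype numeric vector aligned with the panel's samples.
#' @return summary-statistic data.frame (`snp`, `chrom`, `pos`, `a1`, `a2`,
#'   `freq`, `b`, `se`, `p`, `n`).
#' @export
makeSummaryStats <- function(panel, phenotype) {
    G <- dosages(panel)
    stopifnot(length(phenotype) == nrow(G))
    info <- snpInfo(panel)
    n <- length(phenotype)
    gc <- sweep(G, 2L, colMeans(G))
    yc <- phenotype - mean(phenotype)
    Sxx <- colSums(gc^2)
    mono <- Sxx == 0
    if (any(mono)) {
        message("makeSummaryStats: dropped ", sum(mono),
                " monomorphic SNP(s)")
        gc <- gc[, !mono, drop = FALSE]
        G <- G[, !mono, drop = FALSE]
        info <- info[!mono, , drop = FALSE]
        Sxx <- Sxx[!mono]
    }
    Sxy <- crossprod(gc, yc)[, 1L]
    Syy <- sum(yc^2)
    b <- Sxy / Sxx
    rss <- Syy - b * Sxy
    rss[rss < 0] <- 0
    sigma2 <- rss / (n - 2L)
    se <- sqrt(sigma2 / Sxx)
    tval <- b / se
    p <- 2 * stats::pt(-abs(tval), df = n - 2L)
    p[p == 0] <- .Machine$double.xmin   # keep p in (0, 1]
    data.frame(snp = info$snp, chrom = info$chrom, pos = info$pos,
               a1 = info$a1, a2 = info$a2, freq = colMeans(G) / 2,
               b = b, se = se, p = p, n = n,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate one locus: panel, molecular cohorts, trait cohort
#'
#' Draws a reference panel and three non-overlapping cohorts (DNAm,
#' expression, trait) sharing the locus's allele frequencies and LD
#' structure, generates phenotypes under the scenario's causal
#' architecture, and summarizes each cohort into QTL/GWAS summary
#' statistics. The two-sample design (disjoint cohorts) makes the
#' exposure and outcome effect estimates independent across datasets.
#'
#' @param scenario a [simulationScenario()] list.
#' @return list with elements `panel` ([GenotypePanel-class]), `mqtlProbe`
#'   and `eqtlProbe` ([QtlProbe-class]), `gwas` (summary-statistic
#'   data.frame), `cohorts` (genotype panels and phenotype vectors of the
#'   three cohorts), and `truth` (causal SNPs, path effects, implied
#'   molecular-to-trait effects).
#' @export
simulateMediationCohort <- function(scenario) {
    stopifnot(inherits(scenario, "SimulationScenario"))
    s <- scenario
    set.seed(s$seed)
    mafs <- stats::runif(s$nSnps, s$mafRange[1L], s$mafRange[2L])
    gen <- function(n) simulateGenotypes(n, s$nSnps, s$rho, mafs = mafs,
        chrom = s$chrom, posStart = s$posStart, posStep = s$posStep,
        idPrefix = paste0(s$probePrefix, "_", s$idPrefix))
    panel <- gen(s$nRef)
    ic <- as.integer(ceiling(s$nSnps / 2))    # molecular causal SNP
    jc <- ic
    if (s$scenario == "linkage") {
        if (s$rho <= 0)
            stop("linkage scenario requires rho > 0")
        lag <- max(1L, as.integer(round(log(s$r2Linkage) /
                                        (2 * log(s$rho)))))
        jc <- min(s$nSnps, ic + lag)
    }
    Gm <- gen(s$nQtl); Ge <- gen(s$nQtl); Gt <- gen(s$nGwas)
    dm <- dosages(Gm); de <- dosages(Ge); dt <- dosages(Gt)

    if (s$scenario == "mediation") {
        m <- s$b1 * dm[, ic] + stats::rnorm(s$nQtl)
        mE <- s$b1 * de[, ic] + stats::rnorm(s$nQtl)
        e <- s$b2 * mE + stats::rnorm(s$nQtl)
        mT <- s$b1 * dt[, ic] + stats::rnorm(s$nGwas)
        eT <- s$b2 * mT + stats::rnorm(s$nGwas)
        t <- s$b3 * eT + stats::rnorm(s$nGwas)
        truth_bxy <- list(m2t = s$b2 * s$b3, e2t = s$b3, m2e = s$b2)
    } else if (s$scenario == "pleiotropy") {
        m <- s$b1 * dm[, ic] + stats::rnorm(s$nQtl)
        e <- s$bDirectE * de[, ic] + stats::rnorm(s$nQtl)
        t <- s$bDirectT * dt[, ic] + stats::rnorm(s$nGwas)
        truth_bxy <- list(m2t = s$bDirectT / s$b1,
                          e2t = s$bDirectT / s$bDirectE, m2e = NA_real_)
    } else if (s$scenario == "linkage") {
        m <- s$b1 * dm[, ic] + stats::rnorm(s$nQtl)
        e <- s$bDirectE * de[, ic] + stats::rnorm(s$nQtl)
        t <- s$bDirectT * dt[, jc] + stats::rnorm(s$nGwas)
        truth_bxy <- list(m2t = NA_real_, e2t = NA_real_, m2e = NA_real_)
    } else {                                   # null
        m <- s$b1 * dm[, ic] + stats::rnorm(s$nQtl)
        e <- s$bDirectE * de[, ic] + stats::rnorm(s$nQtl)
        t <- stats::rnorm(s$nGwas)
        truth_bxy <- list(m2t = 0, e2t = 0, m2e = NA_real_)
    }

    snps <- snpInfo(panel)
    probe_pos <- snps$pos[ic]
    gene <- paste0("GENE_", s$probePrefix)
    mqtlProbe <- QtlProbe(paste0(s$probePrefix, "_cg1"), s$chrom,
        probe_pos, gene, "methylation", makeSummaryStats(Gm, m))
    eqtlProbe <- QtlProbe(paste0(s$probePrefix, "_tx1"), s$chrom,
        probe_pos, gene, "expression", makeSummaryStats(Ge, e))
    gwas <- makeSummaryStats(Gt, t)

    list(panel = panel, mqtlProbe = mqtlProbe, eqtlProbe = eqtlProbe,
         gwas = gwas,
         cohorts = list(dnam = list(genotypes = Gm, phenotype = m),
                        expression = list(genotypes = Ge, phenotype = e),
                        trait = list(genotypes = Gt, phenotype = t)),
         truth = list(scenario = s$scenario,
                      causalSnp = snps$snp[ic],
                      traitCausalSnp = snps$snp[jc],
                      b1 = s$b1, b2 = s$b2, b3 = s$b3,
                      bXy = truth_bxy))
}

#' Simulate a multi-locus study
#'
#' Concatenates independent loci (one probe pair per locus, each on its own
#' chromosome): `plantedLoci` mediation loci followed by null loci. Cohort
#' genotypes are independent across loci, matching the cis-only design in
#' which each probe is analyzed within its own window.
#'
#' @param nLoci total loci (default 10).
#' @param plantedLoci number of leading mediation loci (default 1).
#' @param seed study seed; per-locus seeds are derived from it.
#' @param ... further arguments passed to [simulationScenario()] for every
#'   locus (e.g. cohort sizes, effects).
#' @return list with `gwas` (pooled summary statistics), `mqtlProbes`,
#'   `eqtlProbes` (named lists of [QtlProbe-class]), `panel` (pooled
#'   reference panel), `truth` (per-locus truth records).
#' @export
simulateStudy <- function(nLoci = 10L, plantedLoci = 1L, seed = 1L, ...) {
    stopifnot(nLoci >= 1, plantedLoci >= 0, plantedLoci <= nLoci)
    set.seed(seed)
    locusSeeds <- sample.int(.Machine$integer.max - 1L, nLoci)
    loci <- lapply(seq_len(nLoci), function(k) {
        sc <- simulationScenario(
            scenario = if (k <= plantedLoci) "mediation" else "null",
            seed = locusSeeds[k], chrom = as.character(k),
            probePrefix = paste0("L", k), ...)
        simulateMediationCohort(sc)
    })
    gwas <- do.call(rbind, lapply(loci, `[[`, "gwas"))
    rownames(gwas) <- NULL
    panels <- lapply(loci, `[[`, "panel")
    nRef <- length(sampleIds(panels[[1L]]))
    panel <- GenotypePanel(
        sampleIds = sampleIds(panels[[1L]]),
        snps = do.call(rbind, lapply(panels, snpInfo)),
        dosages = do.call(cbind, lapply(panels, dosages)))
    mqtlProbes <- lapply(loci, `[[`, "mqtlProbe")
    eqtlProbes <- lapply(loci, `[[`, "eqtlProbe")
    names(mqtlProbes) <- vapply(mqtlProbes, probeId, character(1))
    names(eqtlProbes) <- vapply(eqtlProbes, probeId, character(1))
    list(gwas = gwas, mqtlProbes = mqtlProbes, eqtlProbes = eqtlProbes,
         panel = panel, truth = lapply(loci, `[[`, "truth"))
}

#' Write a simulated study to disk in the pipeline's input dialects
#'
#' Emits the COJO .ma GWAS file, the two flat QTL TSVs, and the reference
#' panel as VCF, so a simulated study doubles as a format-conformance
#' fixture for the readers.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return named list of file paths.
#' @export
writeScenarioBundle <- function(study, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(gwas = file.path(dir, "gwas.ma"),
                  eqtl = file.path(dir, "eqtl.tsv"),
                  mqtl = file.path(dir, "mqtl.tsv"),
                  panel = file.path(dir, "panel.vcf"))
    writeGwasMa(study$gwas, paths$gwas)
    writeQtlFlat(study$eqtlProbes, paths$eqtl)
    writeQtlFlat(study$mqtlProbes, paths$mqtl)
    writeVcfPanel(study$panel, paths$panel)
    paths
}
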