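# Shared simulation drivers (these exercise the package; the oracles live
# in helper-oracles.R).

# HEIDI p-values from repeated single-locus simulations of a scenario.
simHeidiPvalues <- function(scenario, nrep, seed, ...) {
    set.seed(seed)
    seeds <- sample.int(2^31 - 2, nrep)
    cfg <- pipelineConfig()
    vapply(seq_len(nrep), function(i) {
        sim <- simulateMediationCohort(
            simulationScenario(scenario, seed = seeds[i], ...))
        r <- runSmrLayer(list(sim$mqtlProbe), sim$gwas, sim$panel, cfg)
        if (nrow(r) == 1L && isTRUE(r$heidiTestable)) r$pHeidi
        else NA_real_
    }, numeric(1))
}

# SMR p-values for eligible probes under the null (no molecular effect on
# the trait), one locus per probe.
simNullSmrPvalues <- function(nProbes, seed, ...) {
    set.seed(seed)
    seeds <- sample.int(2^31 - 2, nProbes)
    cfg <- pipelineConfig()
    vapply(seq_len(nProbes), function(i) {
        sim <- simulateMediationCohort(
            simulationScenario("null", seed = seeds[i], ...))
        r <- runSmrLayer(list(sim$mqtlProbe), sim$gwas, sim$panel, cfg)
        if (nrow(r) == 1L) r$pSmr else NA_real_
    }, numeric(1))
}

# Methylation-to-trait SMR estimates under the planted mediation chain.
simMediationEstimates <- function(nrep, seed, ...) {
    set.seed(seed)
    seeds <- sample.int(2^31 - 2, nrep)
    cfg <- pipelineConfig()
    rows <- lapply(seq_len(nrep), function(i) {
        sim <- simulateMediationCohort(
            simulationScenario("mediation", seed = seeds[i], ...))
        r <- runSmrLayer(list(sim$mqtlProbe), sim$gwas, sim$panel, cfg)
        if (nrow(r) == 1L)
            data.frame(bXy = r$bXy, seXy = r$seXy,
                       truth = sim$truth$bXy$m2t)
        else NULL
    })
    do.call(rbind, rows)
}

# A tiny deterministic panel for LD unit tests.
toyPanel <- function(dosageMatrix, chrom = "1") {
    n <- ncol(dosageMatrix)
    snps <- data.frame(snp = paste0("rs", seq_len(n)), chrom = chrom,
                       pos = 1e6 + seq_len(n) * 1000,
                       a1 = "A", a2 = "G", stringsAsFactors = FALSE)
    GenotypePanel(paste0("S", seq_len(nrow(dosageMatrix))), snps,
                  dosageMatrix)
}

# A QtlProbe with explicit per-SNP p-values/positions for selection tests.
toyProbe <- function(p, pos = NULL, snp = NULL, b = NULL, se = NULL,
                     layer = "methylation", probePos = 1e6) {
    k <- length(p)
    if (is.null(pos)) pos <- 1e6 + seq_len(k) * 1000
    if (is.null(snp)) snp <- paste0("rs", seq_len(k))
    if (is.null(b)) b <- rep(0.5, k)
    if (is.null(se)) se <- rep(0.05, k)
    rec <- data.frame(snp = snp, chrom = "1", pos = pos, a1 = "A",
                      a2 = "G", freq = 0.3, b = b, se = se, p = p,
                      stringsAsFactors = FALSE)
    QtlProbe("cg_test", "1", probePos, "GENE_T", layer, rec)
}
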