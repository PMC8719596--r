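test_that("top cis-QTL selection applies threshold and tie-breaks", {
    expect_equal(selectTopCisQtl(toyProbe(c(1e-9, 1e-7, 0.3))), "rs1")
    expect_true(is.na(selectTopCisQtl(toyProbe(c(1e-7, 1e-6)))))
    # tie at the minimum p: smaller position wins
    pr <- toyProbe(p = c(1e-9, 1e-9, 1e-5), pos = c(300, 100, 200),
                   snp = c("rsA", "rsB", "rsC"))
    expect_equal(selectTopCisQtl(pr), "rsB")
    # empty cis records
    empty <- QtlProbe("cgE", "1", 1e6, "G", "methylation",
                      cisRecords(toyProbe(0.5))[0, ])
    expect_true(is.na(selectTopCisQtl(empty)))
})

test_that("SMR ratio, statistic and p-value match closed forms", {
    # null instrument-outcome effect
    r0 <- smrEffect(0.5, 0.05, 0, 0.01)
    expect_equal(r0$bXy, 0)
    expect_equal(r0$tSmr, 0)
    expect_equal(r0$pSmr, 1)
    expect_true(is.na(r0$seXy))
    # zZx = 10, zZy = 3 -> T = 900/109; chi-square survival via the
    # normal-tail identity for 1 df
    r <- smrEffect(0.5, 0.05, 0.02, 0.02 / 3)
    expect_equal(r$bXy, 0.04)
    expect_equal(r$tSmr, 900 / 109, tolerance = 1e-12)
    expect_equal(r$pSmr, 2 * pnorm(-sqrt(900 / 109)), tolerance = 1e-12)
    expect_equal(r$seXy, 0.04 / sqrt(900 / 109), tolerance = 1e-12)
    # undefined ratio
    expect_true(is.na(smrEffect(0, 0.05, 0.02, 0.01)$bXy))
})

test_that("T_SMR is symmetric and bounded by both instrument chi-squares", {
    set.seed(31)
    for (i in 1:50) {
        bzx <- rnorm(1, sd = 0.5); bzy <- rnorm(1, sd = 0.1)
        if (bzx == 0) next
        r1 <- smrEffect(bzx, 0.04, bzy, 0.01)
        r2 <- smrEffect(bzy, 0.01, bzx, 0.04)
        expect_equal(r1$tSmr, r2$tSmr, tolerance = 1e-12)
        expect_lte(r1$tSmr, min(r1$zZx^2, r1$zZy^2) + 1e-12)
    }
})

test_that("SMR estimate agrees with a 2SLS oracle on shared data", {
    set.seed(32)
    n <- 20000
    g <- rbinom(n, 2, 0.3)
    x <- 0.5 * g + rnorm(n)
    t <- 0.3 * x + rnorm(n)
    panel <- toyPanel(cbind(g, matrix(rbinom(n, 2, 0.3), n, 1)))
    sx <- makeSummaryStats(panel, x)
    st <- makeSummaryStats(panel, t)
    r <- smrEffect(sx$b[1], sx$se[1], st$b[1], st$se[1])
    expect_lt(abs(r$bXy - oracleIv(g, x, t)), 0.01)
    expect_lt(abs(r$bXy - 0.3), 3 * r$seXy)
})

test_that("p_smr is uniform under the null with a strong instrument", {
    set.seed(33)
    nrep <- 2000
    se_zy <- 0.01
    bzy <- rnorm(nrep, 0, se_zy)           # zero true outcome effect
    bzx <- rnorm(nrep, 0.5, 0.02)          # strong instrument
    p <- smrEffect(bzx, 0.02, bzy, se_zy)$pSmr
    expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.001)
})

test_that("layer run keeps eligible probes and logs join failures", {
    set.seed(34)
    st <- simulateStudy(nLoci = 4, plantedLoci = 4, seed = 34,
                        nSnps = 10, nQtl = 600, nGwas = 1200, nRef = 200)
    cfg <- pipelineConfig()
    # weaken two probes below genome-wide significance
    probes <- st$mqtlProbes
    for (k in 3:4) {
        rec <- cisRecords(probes[[k]])
        rec$p <- pmax(rec$p, 1e-6)
        probes[[k]] <- QtlProbe(probeId(probes[[k]]),
            probeChrom(probes[[k]]), probePos(probes[[k]]),
            probeGene(probes[[k]]), "methylation", rec)
    }
    res <- runSmrLayer(probes, st$gwas, st$panel, cfg)
    expect_equal(nrow(res), 2L)
    log <- attr(res, "log")
    expect_setequal(log$reason, "no_significant_cis_qtl")
    # drop one top SNP from the GWAS: probe skipped with logged reason
    gwas2 <- st$gwas[st$gwas$snp != res$topSnp[1], ]
    res2 <- runSmrLayer(probes, gwas2, st$panel, cfg)
    expect_equal(nrow(res2), 1L)
    expect_true("top_snp_missing_from_outcome" %in%
                attr(res2, "log")$reason)
})

test_that("SMR results are invariant to allele re-coding of the GWAS", {
    set.seed(35)
    sim <- simulateMediationCohort(simulationScenario("mediation",
        seed = 35, nSnps = 12, nQtl = 800, nGwas = 3000, nRef = 300))
    cfg <- pipelineConfig()
    base <- runSmrLayer(list(sim$mqtlProbe), sim$gwas, sim$panel, cfg)
    flipped <- sim$gwas
    i <- seq(1, nrow(flipped), by = 2)
    tmp <- flipped$a1[i]
    flipped$a1[i] <- flipped$a2[i]
    flipped$a2[i] <- tmp
    flipped$b[i] <- -flipped$b[i]
    flipped$freq[i] <- 1 - flipped$freq[i]
    rec <- runSmrLayer(list(sim$mqtlProbe), flipped, sim$panel, cfg)
    expect_equal(rec$bXy, base$bXy, tolerance = 1e-12)
    expect_equal(rec$pSmr, base$pSmr, tolerance = 1e-12)
    expect_equal(rec$pHeidi, base$pHeidi, tolerance = 1e-10)
})
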