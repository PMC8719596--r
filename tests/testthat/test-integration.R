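test_that("Bonferroni threshold matches the corrected cutoffs in use", {
    expect_equal(bonferroniThreshold(0.05, 47), 0.05 / 47)
    expect_equal(round(bonferroniThreshold(0.05, 47), 3), 0.001)
    expect_equal(bonferroniThreshold(0.05, 1), 0.05)
    expect_equal(bonferroniThreshold(0.05, 8507), 0.05 / 8507)
    expect_error(bonferroniThreshold(0.05, 0), "positive")
    # strictly decreasing in the number of tests
    n <- c(1, 2, 10, 47, 100, 8507, 93211)
    thr <- vapply(n, function(k) bonferroniThreshold(0.05, k), numeric(1))
    expect_true(all(diff(thr) < 0))
})

test_that("probe pairing is strict-< on distance and same-chromosome", {
    mk <- function(probe, chrom, pos)
        data.frame(probe = probe, gene = paste0("G_", probe),
                   probeChrom = chrom, probePos = pos,
                   stringsAsFactors = FALSE)
    dn <- mk(c("cg1", "cg2", "cg3"), c("1", "1", "2"),
             c(1e6, 1e6, 1e6))
    ex <- mk("tx1", "1", 1e6 + 1999999)
    pairs <- m2tPairing(dn, ex)
    expect_equal(pairs$dnamProbe, c("cg1", "cg2"))   # cg3: other chrom
    ex2 <- mk("tx2", "1", 1e6 + 2e6)
    expect_equal(nrow(m2tPairing(dn, ex2)), 0L)       # exactly 2 Mb: out
    expect_equal(nrow(m2tPairing(dn[0, ], ex)), 0L)
})

test_that("mediation sign consistency reproduces the CPEB4-axis logic", {
    # published b-SMR triple: DNAm->trait 0.044, DNAm->gene -0.897,
    # gene->trait -0.049; predicted product agrees with the direct
    # estimate to two decimals
    cons <- mediationConsistency(0.044, -0.897, -0.049)
    expect_true(cons$consistent)
    expect_equal(cons$predictedBM2t, (-0.897) * (-0.049))
    expect_equal(round(cons$predictedBM2t, 2), round(0.044, 2))
    # sign flip breaks consistency
    expect_false(mediationConsistency(0.044, -0.897, 0.049)$consistent)
    # degenerate direct estimate
    deg <- mediationConsistency(0, -0.897, -0.049)
    expect_true(deg$degenerate)
    expect_true(is.na(deg$relativeDeviation))
})

test_that("gene overlap is plain set algebra", {
    ov <- overlapGenes(c("A", "B"), c("B", "C"))
    expect_equal(ov$union, c("A", "B", "C"))
    expect_equal(ov$intersection, "B")
    expect_equal(overlapGenes("A", "B")$intersection, character(0))
    expect_equal(overlapGenes(c("A", "B"), c("B", "A"))$intersection,
                 c("A", "B"))
})

test_that("TSEA Fisher p-values equal the hypergeometric tail exactly", {
    set.seed(41)
    nG <- 1000
    genes <- paste0("G", seq_len(nG))
    tmat <- matrix(rnorm(nG * 3), nG, 3,
                   dimnames = list(genes, c("heart", "blood", "muscle")))
    # plant 5 query genes in heart's top 5% (50 genes), query size 10
    top_heart <- genes[order(tmat[, "heart"], decreasing = TRUE)][1:50]
    query <- c(top_heart[1:5], setdiff(genes, top_heart)[1:5])
    res <- tseaFisher(query, tmat)
    expect_equal(res$tissueSetSize, rep(50L, 3), ignore_attr = TRUE)
    heart <- res[res$tissue == "heart", ]
    expect_equal(heart$overlap, 5L)
    expect_equal(heart$pFisher, oracleHypergeomTail(5, 10, 50, 1000),
                 tolerance = 1e-12)
    # every reported p matches enumeration for its own table
    for (i in seq_len(nrow(res)))
        expect_equal(res$pFisher[i],
                     oracleHypergeomTail(res$overlap[i], res$querySize[i],
                                         res$tissueSetSize[i], nG),
                     tolerance = 1e-12)
    # significance cutoff is Bonferroni over tissues
    expect_equal(res$significant,
                 res$pFisher < bonferroniThreshold(0.05, 3))
})

test_that("TSEA handles zero overlap and query genes off the background", {
    nG <- 200
    genes <- paste0("G", seq_len(nG))
    tmat <- matrix(seq_len(nG), nG, 1,
                   dimnames = list(genes, "tissue1"))
    # tissue set is the top 10 genes (G200..G191); query avoids them
    expect_message(
        res <- tseaFisher(c("G1", "G2", "NOT_A_GENE"), tmat),
        "dropped 1")
    expect_equal(res$overlap, 0L)
    expect_gte(res$pFisher, 0.99)
    expect_equal(attr(res, "nDroppedQueryGenes"), 1L)
    # query equal to the tissue set: minimal attainable tail
    res2 <- tseaFisher(genes[191:200], tmat)
    expect_equal(res2$overlap, 10L)
    expect_equal(res2$pFisher,
                 oracleHypergeomTail(10, 10, 10, nG), tolerance = 1e-12)
})

test_that("BH alternative flags at least the Bonferroni discoveries", {
    set.seed(42)
    p <- c(runif(50), 1e-6, 1e-8)
    bonf <- p < bonferroniThreshold(0.05, length(p))
    expect_true(all(bhSignificant(p)[bonf]))
})
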