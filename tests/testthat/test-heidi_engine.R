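# A workspace fixture: k SNPs with AR(1)-like LD, strong exposure effects.
mkRecords <- function(k, r = NULL, bx = NULL, sx = 0.03,
                      by = NULL, sy = 0.01) {
    if (is.null(bx)) bx <- seq(0.45, 0.30, length.out = k)
    if (is.null(by)) by <- seq(0.025, 0.012, length.out = k)
    rec <- function(b, se) data.frame(
        snp = paste0("rs", seq_len(k)), chrom = "1",
        pos = 1e6 + seq_len(k) * 1000, a1 = "A", a2 = "G", freq = 0.3,
        b = b, se = se, p = 2 * pnorm(-abs(b / se)),
        stringsAsFactors = FALSE)
    if (is.null(r)) r <- 0.6^abs(outer(seq_len(k), seq_len(k), "-"))
    dimnames(r) <- list(paste0("rs", seq_len(k)), paste0("rs", seq_len(k)))
    list(x = rec(bx, rep(sx, k)), y = rec(by, rep(sy, k)),
         ld = new("LDMatrix", snpIds = paste0("rs", seq_len(k)), r = r))
}

test_that("contrast variance reduces to the independence sum at r = 0", {
    w <- mkRecords(2, r = diag(2), bx = c(0.4, 0.4), by = c(0.02, 0.02))
    ws <- bxyCovariance(w$x, w$y, w$ld)
    varBxy <- function(b, sb, a, sa)      # delta-method var of b/a
        (b / a)^2 * (sb^2 / b^2 + sa^2 / a^2)
    expect_equal(as.numeric(ws$V),
                 varBxy(0.02, 0.01, 0.4, 0.03) * 2, tolerance = 1e-12)
})

test_that("perfect LD duplicates give a degenerate (zero-variance) contrast", {
    w <- mkRecords(2, r = matrix(1, 2, 2), bx = c(0.4, 0.4),
                   by = c(0.02, 0.02))
    ws <- bxyCovariance(w$x, w$y, w$ld)
    expect_lt(abs(ws$V[1, 1]), 1e-12)
})

test_that("contrast covariance matches Monte-Carlo propagation", {
    k <- 4
    bx <- c(0.45, 0.38, 0.30, 0.25)
    by <- c(0.025, 0.02, 0.018, 0.012)
    w <- mkRecords(k, bx = bx, by = by, sx = 0.025, sy = 0.004)
    ws <- bxyCovariance(w$x, w$y, w$ld)
    mc <- oracleMcCovD(bx, rep(0.025, k), by, rep(0.004, k),
                       ldr(w$ld), nDraw = 1e5, seed = 77)
    expect_lt(max(abs(ws$V - mc)) / max(abs(mc)), 0.05)
})

test_that("HEIDI requires the minimum SNP count and flags its method", {
    w <- mkRecords(2)
    ht <- heidiTest(w$x, w$y, w$ld)
    expect_false(ht$testable)
    expect_true(is.na(ht$pHeidi))
    w5 <- mkRecords(5)
    ht5 <- heidiTest(w5$x, w5$y, w5$ld)
    expect_true(ht5$testable)
    expect_gt(ht5$pHeidi, 0)
    expect_lte(ht5$pHeidi, 1)
    expect_true(ht5$method %in% c("imhof", "satterthwaite"))
})

test_that("p_heidi is invariant to the ordering of non-top SNPs", {
    w <- mkRecords(6, bx = seq(0.45, 0.3, length.out = 6),
                   by = seq(0.025, 0.012, length.out = 6))
    ht <- heidiTest(w$x, w$y, w$ld)
    perm <- c(1, 5, 3, 2, 6, 4)
    ld2 <- new("LDMatrix", snpIds = w$x$snp[perm],
               r = ldr(w$ld)[perm, perm])
    ht2 <- heidiTest(w$x[perm, ], w$y[perm, ], ld2, topSnp = "rs1")
    expect_equal(ht2$tHeidi, ht$tHeidi, tolerance = 1e-12)
    expect_equal(ht2$pHeidi, ht$pHeidi, tolerance = 1e-9)
})

test_that("a SNP with zero contrast leaves T_HEIDI unchanged", {
    w <- mkRecords(5)
    # make SNP 4's ratio exactly equal the top's: d = 0
    w$x$b[4] <- 0.4; w$x$se[4] <- 0.03
    w$y$b[4] <- w$y$b[1] * w$x$b[4] / w$x$b[1]
    ht <- heidiTest(w$x, w$y, w$ld)
    drop4 <- c(1, 2, 3, 5)
    ld2 <- new("LDMatrix", snpIds = w$x$snp[drop4],
               r = ldr(w$ld)[drop4, drop4])
    ht2 <- heidiTest(w$x[drop4, ], w$y[drop4, ], ld2)
    expect_equal(ht$tHeidi, ht2$tHeidi, tolerance = 1e-12)
})

test_that("quadratic-form p-values match Monte-Carlo tails", {
    lambda <- c(2.1, 1.3, 0.7, 0.4, 0.1)
    qs <- c(2, 6, 12, 20)
    mc <- oracleMcQuadTail(lambda, qs, nDraw = 1e5, seed = 5)
    for (i in seq_along(qs)) {
        p <- quadFormPvalue(qs[i], lambda)
        expect_lt(abs(p - mc[i]) / mc[i], 0.1)
        expect_equal(attr(p, "method"), "imhof")
    }
    # Satterthwaite fallback stays a sane approximation
    for (i in seq_along(qs)) {
        ps <- smrmediate:::.satterthwaitePvalue(qs[i], lambda)
        expect_lt(abs(ps - mc[i]), 0.05)
    }
})

test_that("HEIDI detects two causal variants in linkage", {
    p <- simHeidiPvalues("linkage", nrep = 60, seed = 101,
                         nGwas = 10000, nQtl = 2000)
    p <- p[!is.na(p)]
    expect_gt(length(p), 40)
    # rejection far above the nominal null rate at the 0.01 threshold
    expect_gt(mean(p < 0.01), 5 * 0.01)
})
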