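# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Pearson correlation from the definition (sums of squares).
oraclePearson <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Upper tail P(X >= ov) of the hypergeometric 2x2 enrichment table by
# direct enumeration: querySize draws, tissueSetSize successes in a
# background of backgroundSize.
oracleHypergeomTail <- function(ov, querySize, tissueSetSize,
                                backgroundSize) {
    xs <- ov:min(querySize, tissueSetSize)
    sum(choose(tissueSetSize, xs) *
        choose(backgroundSize - tissueSetSize, querySize - xs)) /
        choose(backgroundSize, querySize)
}

# Monte-Carlo propagation oracle for the covariance of the HEIDI contrast
# vector: resamples (bZx, bZy) from their stated multivariate normals and
# computes the empirical covariance of d = bXy[-top] - bXy[top].
oracleMcCovD <- function(bx, sx, by, sy, R, top = 1L,
                         nDraw = 1e5, seed = 1) {
    set.seed(seed)
    k <- length(bx)
    L <- chol(R)
    drawX <- matrix(rnorm(nDraw * k), nDraw, k) %*% L
    drawY <- matrix(rnorm(nDraw * k), nDraw, k) %*% L
    BX <- sweep(sweep(drawX, 2L, sx, `*`), 2L, bx, `+`)
    BY <- sweep(sweep(drawY, 2L, sy, `*`), 2L, by, `+`)
    bxy <- BY / BX
    d <- bxy[, -top, drop = FALSE] - bxy[, top]
    stats::cov(d)
}

# Monte-Carlo tail of a weighted sum of 1-df chi-squares.
oracleMcQuadTail <- function(lambda, q, nDraw = 1e5, seed = 1) {
    set.seed(seed)
    draws <- matrix(rnorm(nDraw * length(lambda))^2, nDraw) %*% lambda
    vapply(q, function(qq) mean(draws > qq), numeric(1))
}

# Instrumental-variable (2SLS, single instrument) estimate from
# individual-level data: cov(g, t) / cov(g, x).
oracleIv <- function(g, x, t) {
    stats::cov(g, t) / stats::cov(g, x)
}
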