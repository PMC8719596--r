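#' Covariance of the HEIDI contrast vector
#'
#' Each HEIDI SNP i yields a ratio estimate bXy(i) = bZy(i)/bZx(i); the
#' contrasts d_i = bXy(i) - bXy(top) (i != top) should all be zero when a
#' single causal variant drives both exposure and outcome associations.
#' This computes cov(d) by first-order error propagation, treating the
#' vectors of exposure and outcome effects as multivariate normal with
#' cov(bZy(i), bZy(j)) = r_ij * seZy(i) * seZy(j) (and analogously for bZx),
#' independent across the two datasets (two-sample design):
#' cov(bXy_i, bXy_j) = r_ij seZy_i seZy_j / (bZx_i bZx_j)
#'                   + bZy_i bZy_j r_ij seZx_i seZx_j / (bZx_i^2 bZx_j^2).
#'
#' @param recordsX exposure summary statistics for the HEIDI SNPs (top SNP
#'   first), harmonized to a common effect allele.
#' @param recordsY outcome summary statistics for the same SNPs, same order
#'   and coding.
#' @param ld [LDMatrix-class] over the same SNPs, same order and coding.
#' @param topSnp id of the top SNP (defaults to the first row).
#' @return list with `d` (named contrast vector), `V` (its covariance
#'   matrix), `bXy` (per-SNP ratio estimates), `snps` (non-top SNP ids).
#' @export
bxyCovariance <- function(recordsX, recordsY, ld,
                          topSnp = recordsX$snp[1L]) {
    stopifnot(identical(recordsX$snp, recordsY$snp),
              identical(recordsX$snp, snpIds(ld)),
              nrow(recordsX) >= 2L, topSnp %in% recordsX$snp)
    bx <- recordsX$b; sx <- recordsX$se
    by <- recordsY$b; sy <- recordsY$se
    if (any(bx == 0)) stop("zero exposure effect among HEIDI SNPs")
    r <- ldr(ld)
    bXy <- by / bx
    covY <- r * tcrossprod(sy)                 # cov(bZy_i, bZy_j)
    covX <- r * tcrossprod(sx)                 # cov(bZx_i, bZx_j)
    C <- covY / tcrossprod(bx) +
         tcrossprod(by) * covX / tcrossprod(bx^2)
    it <- match(topSnp, recordsX$snp)
    io <- setdiff(seq_along(bx), it)
    d <- bXy[io] - bXy[it]
    V <- C[io, io, drop = FALSE] -
        matrix(C[io, it], length(io), length(io)) -
        matrix(C[it, io], length(io), length(io), byrow = TRUE) +
        C[it, it]
    V <- (V + t(V)) / 2
    names(d) <- recordsX$snp[io]
    dimnames(V) <- list(names(d), names(d))
    list(d = d, V = V, bXy = stats::setNames(bXy, recordsX$snp),
         snps = names(d))
}

#' HEIDI heterogeneity test
#'
#' Tests the null hypothesis that a single causal variant underlies both
#' the QTL and the outcome association. Standardized contrasts
#' z_d(i) = d_i / sqrt(var(d_i)) are summed into T_HEIDI = sum z_d^2, whose
#' null distribution is the quadratic form sum lambda_k chi^2_1 with
#' lambda_k the eigenvalues of the correlation matrix of z_d; the upper
#' tail is evaluated by Imhof numerical inversion with a Satterthwaite
#' scaled-chi-square fallback (see [quadFormPvalue()]). SNPs with
#' var(d_i) < 1e-12 (near-perfect LD that survived pruning) are dropped.
#' Fewer than `minSnps` SNPs (including the top) is a non-testable signal.
#'
#' @param recordsX,recordsY,ld,topSnp as in [bxyCovariance()]; or pass a
#'   precomputed workspace via `workspace`.
#' @param minSnps minimum SNP count including the top (default 3).
#' @param workspace optional list from [bxyCovariance()].
#' @return list with `tHeidi`, `pHeidi`, `nSnps` (including the top),
#'   `testable`, `method` (`"imhof"` or `"satterthwaite"`).
#' @export
heidiTest <- function(recordsX = NULL, recordsY = NULL, ld = NULL,
                      topSnp = NULL, minSnps = 3L, workspace = NULL) {
    nontestable <- function(n) list(tHeidi = NA_real_, pHeidi = NA_real_,
        nSnps = n, testable = FALSE, method = NA_character_)
    if (is.null(workspace)) {
        if (nrow(recordsX) < minSnps) return(nontestable(nrow(recordsX)))
        if (is.null(topSnp)) topSnp <- recordsX$snp[1L]
        workspace <- tryCatch(
            bxyCovariance(recordsX, recordsY, ld, topSnp),
            error = function(e) NULL)
        if (is.null(workspace)) return(nontestable(nrow(recordsX)))
    }
    d <- workspace$d
    V <- workspace$V
    keep <- diag(V) >= 1e-12
    d <- d[keep]
    V <- V[keep, keep, drop = FALSE]
    if (length(d) + 1L < minSnps) return(nontestable(length(d) + 1L))
    sd_d <- sqrt(diag(V))
    z <- d / sd_d
    R <- V / tcrossprod(sd_d)
    R <- .regularizeLd(R)
    lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (any(!is.finite(lambda))) return(nontestable(length(d) + 1L))
    tHeidi <- sum(z^2)
    p <- quadFormPvalue(tHeidi, lambda)
    list(tHeidi = tHeidi, pHeidi = as.numeric(p),
         nSnps = length(d) + 1L, testable = TRUE,
         method = attr(p, "method"))
}
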