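#' Pairwise allelic correlation from a reference panel
#'
#' Pearson correlation of allele dosages over samples non-missing at both
#' SNPs (pairwise-complete). Dosages are re-oriented before correlation when
#' `effectAlleles` names an effect allele differing from the panel's `a1`
#' (the dosage becomes `2 - d`), so the signed r matrix is aligned to the
#' harmonized effect-allele coding of the summary statistics.
#'
#' @param panel A [GenotypePanel-class].
#' @param snpIds SNPs to include (default: all panel SNPs), in this order.
#' @param effectAlleles optional named character vector `snp -> effect
#'   allele`; must equal the panel's `a1` or `a2` for each SNP.
#' @return An [LDMatrix-class].
#' @export
ldCorrelation <- function(panel, snpIds = NULL, effectAlleles = NULL) {
    info <- snpInfo(panel)
    if (is.null(snpIds)) snpIds <- info$snp
    miss <- setdiff(snpIds, info$snp)
    if (length(miss) > 0L)
        stop("SNP(s) absent from panel: ", paste(miss, collapse = ", "))
    d <- dosages(panel)[, snpIds, drop = FALSE]
    info <- info[match(snpIds, info$snp), , drop = FALSE]
    if (!is.null(effectAlleles)) {
        ea <- effectAlleles[snpIds]
        if (any(is.na(ea)))
            stop("effectAlleles missing for: ",
                 paste(snpIds[is.na(ea)], collapse = ", "))
        flip <- ea == info$a2
        bad <- !flip & ea != info$a1
        if (any(bad))
            stop("effect allele matches neither panel allele for: ",
                 paste(snpIds[bad], collapse = ", "))
        d[, flip] <- 2 - d[, flip]
    }
    v <- apply(d, 2L, stats::var, na.rm = TRUE)
    mono <- !is.finite(v) | v == 0
    if (any(mono))
        stop("monomorphic SNP(s) in panel: ",
             paste(snpIds[mono], collapse = ", "))
    if (length(snpIds) > 1L) {
        nonmiss <- !is.na(d)
        overlap <- crossprod(nonmiss)
        if (min(overlap) < 2L)
            stop("fewer than 2 overlapping samples for some SNP pair")
    }
    r <- stats::cor(d, use = "pairwise.complete.obs")
    r[r > 1] <- 1; r[r < -1] <- -1
    diag(r) <- 1
    r <- (r + t(r)) / 2
    new("LDMatrix", snpIds = snpIds, r = r)
}

#' Select the SNP set for the HEIDI test
#'
#' Starting from all cis-SNPs of a probe, keeps SNPs whose QTL p-value is
#' below `pInclusion` (the chi-squared = 10 instrument-strength threshold,
#' p = 1.57e-3) and whose squared correlation with the top QTL lies in
#' [`r2Lower`, `r2Upper`] — pruning both near-duplicates of the top SNP and
#' near-independent SNPs. The top SNP is always first. If more than
#' `maxSnps` remain, the `maxSnps - 1` non-top SNPs with smallest QTL p are
#' kept (ties broken by position, then SNP id).
#'
#' @param probe A [QtlProbe-class].
#' @param topSnp id of the top cis-QTL.
#' @param ld An [LDMatrix-class] covering the candidate SNPs.
#' @param pInclusion QTL p-value inclusion threshold (default 1.57e-3).
#' @param r2Upper,r2Lower r-squared pruning bounds (defaults 0.9 and 0.05).
#' @param maxSnps maximum set size including the top SNP (default 20).
#' @return character vector of SNP ids, top SNP first.
#' @export
heidiSnpSet <- function(probe, topSnp, ld, pInclusion = 1.57e-3,
                        r2Upper = 0.9, r2Lower = 0.05, maxSnps = 20L) {
    rec <- cisRecords(probe)
    if (!topSnp %in% rec$snp)
        stop("top SNP ", topSnp, " not among the probe's cis records")
    ids <- intersect(rec$snp, snpIds(ld))
    rec <- rec[match(ids, rec$snp), , drop = FALSE]
    r <- ldr(ld)
    dimnames(r) <- list(snpIds(ld), snpIds(ld))
    r_top <- r[ids, topSnp]
    r2 <- r_top^2
    cand <- rec$snp != topSnp & rec$p < pInclusion &
        r2 >= r2Lower & r2 <= r2Upper
    others <- rec[cand, , drop = FALSE]
    ord <- order(others$p, others$pos, others$snp)
    others <- others$snp[ord]
    if (length(others) > maxSnps - 1L)
        others <- others[seq_len(maxSnps - 1L)]
    c(topSnp, others)
}

#' Nearest positive semidefinite regularization of an LD submatrix
#'
#' Adds a small ridge to the diagonal and renormalizes to unit diagonal when
#' the smallest eigenvalue is below `-tol`.
#'
#' @param r correlation matrix.
#' @param ridge ridge added to the diagonal (default 1e-8).
#' @param tol eigenvalue tolerance (default 1e-10).
#' @return regularized matrix.
#' @keywords internal
.regularizeLd <- function(r, ridge = 1e-8, tol = 1e-10) {
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    while (min(ev) < -tol && ridge < 1e-2) {
        r <- r + diag(ridge, nrow(r))
        r <- stats::cov2cor(r)
        ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
        ridge <- ridge * 10
    }
    r
}
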