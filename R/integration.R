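#' Bonferroni significance threshold
#'
#' Family-wise error control: the per-test threshold is `alpha / nTests`.
#' Strictly decreasing in the number of tests.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param nTests number of tests (>= 1).
#' @return p-value threshold.
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
    stopifnot(length(nTests) == 1L, alpha > 0, alpha < 1)
    if (is.na(nTests) || nTests < 1)
        stop("nTests must be a positive integer")
    alpha / nTests
}

#' Benjamini-Hochberg significant set (optional alternative)
#'
#' Provided for comparison with the Bonferroni filter; returns which
#' p-values are significant at FDR `alpha`.
#'
#' @param p p-values.
#' @param alpha FDR level.
#' @return logical vector.
#' @export
bhSignificant <- function(p, alpha = 0.05) {
    stats::p.adjust(p, method = "BH") < alpha
}

#' Pair passing DNAm probes with passing expression probes
#'
#' All cross-layer pairs on the same chromosome whose probe positions are
#' strictly less than `maxDistance` bp apart are candidate mediation pairs.
#'
#' @param dnamResults,exprResults SMR result data.frames (rows restricted to
#'   passing probes) with columns `probe`, `gene`, `probeChrom`, `probePos`.
#' @param maxDistance pairing distance in bp (default 2 Mb, strict `<`).
#' @return data.frame with columns `dnamProbe`, `exprProbe`, `gene`
#'   (expression probe's gene), `dnamGene`, `distanceBp`.
#' @export
m2tPairing <- function(dnamResults, exprResults, maxDistance = 2e6) {
    if (nrow(dnamResults) == 0L || nrow(exprResults) == 0L)
        return(data.frame(dnamProbe = character(), exprProbe = character(),
                          gene = character(), dnamGene = character(),
                          distanceBp = numeric()))
    grid <- expand.grid(i = seq_len(nrow(dnamResults)),
                        j = seq_len(nrow(exprResults)))
    same <- dnamResults$probeChrom[grid$i] == exprResults$probeChrom[grid$j]
    dist <- abs(dnamResults$probePos[grid$i] - exprResults$probePos[grid$j])
    keep <- same & dist < maxDistance
    out <- data.frame(
        dnamProbe = dnamResults$probe[grid$i[keep]],
        exprProbe = exprResults$probe[grid$j[keep]],
        gene = exprResults$gene[grid$j[keep]],
        dnamGene = dnamResults$gene[grid$i[keep]],
        distanceBp = dist[keep],
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Sign-consistency check for a mediation triplet
#'
#' Under the mediation model SNP -> DNAm -> expression -> trait, the direct
#' DNAm-to-trait SMR effect should equal the product of the DNAm-to-
#' expression and expression-to-trait effects. The primary check is on
#' sign: `consistent = (sign(bM2e * bE2t) == sign(bM2t))`. The relative
#' deviation of the product from the direct estimate is reported (with the
#' advisory `tolerance` echoed) but not used as a hard filter.
#'
#' @param bM2t DNAm-to-trait SMR effect.
#' @param bM2e DNAm-to-expression SMR effect.
#' @param bE2t expression-to-trait SMR effect.
#' @param tolerance advisory relative-deviation threshold (default 0.5).
#' @return list with `consistent`, `predictedBM2t` (= bM2e * bE2t),
#'   `relativeDeviation` (NA when `bM2t = 0`), `withinTolerance`,
#'   `degenerate` (TRUE when `bM2t = 0`).
#' @export
mediationConsistency <- function(bM2t, bM2e, bE2t, tolerance = 0.5) {
    predicted <- bM2e * bE2t
    degenerate <- bM2t == 0
    consistent <- !degenerate & sign(predicted) == sign(bM2t)
    relDev <- ifelse(degenerate, NA_real_,
                     abs(predicted - bM2t) / abs(bM2t))
    list(consistent = consistent, predictedBM2t = predicted,
         relativeDeviation = relDev,
         withinTolerance = !is.na(relDev) & relDev <= tolerance,
         degenerate = degenerate)
}

#' Gene-set overlap between omics layers
#'
#' @param exprGenes genes implicated by the expression layer.
#' @param dnamGenes closest genes of implicated DNAm probes.
#' @return list with `union` and `intersection` (sorted character vectors).
#' @export
overlapGenes <- function(exprGenes, dnamGenes) {
    list(union = sort(union(unique(exprGenes), unique(dnamGenes))),
         intersection = sort(intersect(unique(exprGenes),
                                       unique(dnamGenes))))
}

#' Tissue-specific enrichment analysis (TSEA)
#'
#' For each tissue, the genes in the top `topFraction` of that tissue's
#' specificity t-statistics are predefined as enriched in the tissue; the
#' overlap between the query gene set and each tissue set is evaluated by a
#' one-sided Fisher exact test against the background of all genes in the
#' matrix. Significance uses a Bonferroni cutoff `alpha / nTissues`.
#'
#' @param queryGenes character vector of query genes; genes absent from the
#'   background are dropped with a message.
#' @param tissueTStats numeric matrix, rows = genes (rownames required),
#'   columns = tissues.
#' @param topFraction fraction of genes defining each tissue set
#'   (default 0.05).
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with one row per tissue: `tissue`, `overlap`,
#'   `querySize`, `tissueSetSize`, `backgroundSize`, `pFisher`,
#'   `significant`; attribute `nDroppedQueryGenes`.
#' @export
tseaFisher <- function(queryGenes, tissueTStats, topFraction = 0.05,
                       alpha = 0.05) {
    stopifnot(is.matrix(tissueTStats), !is.null(rownames(tissueTStats)),
              topFraction > 0, topFraction < 1)
    background <- rownames(tissueTStats)
    query <- unique(queryGenes)
    absent <- setdiff(query, background)
    if (length(absent) > 0L)
        message("tseaFisher: dropped ", length(absent),
                " query gene(s) absent from the background")
    query <- intersect(query, background)
    nG <- length(background)
    k <- max(1L, round(topFraction * nG))
    nTissues <- ncol(tissueTStats)
    cutoff <- bonferroniThreshold(alpha, nTissues)
    rows <- lapply(seq_len(nTissues), function(j) {
        tset <- background[order(tissueTStats[, j],
                                 decreasing = TRUE)][seq_len(k)]
        ov <- length(intersect(query, tset))
        tab <- matrix(c(ov, length(query) - ov,
                        k - ov, nG - length(query) - k + ov), 2L, 2L)
        p <- stats::fisher.test(tab, alternative = "greater")$p.value
        data.frame(tissue = colnames(tissueTStats)[j], overlap = ov,
                   querySize = length(query), tissueSetSize = k,
                   backgroundSize = nG, pFisher = p,
                   significant = p < cutoff, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "nDroppedQueryGenes") <- length(absent)
    out
}
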