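#' @import methods
NULL

# Columns every summary-statistic data.frame must carry. `freq`, `n`, `chrom`
# and `pos` may be NA but the columns must exist where stated.
.SUMSTAT_CORE <- c("snp", "a1", "a2", "b", "se", "p")

#' Validate a summary-statistic table
#'
#' Checks that a data.frame of per-SNP marginal association records satisfies
#' the structural invariants assumed throughout the package: one row per SNP,
#' standard errors strictly positive, p-values in (0, 1], distinct alleles,
#' allele frequencies (when present) in [0, 1].
#'
#' @param x A data.frame with at least columns `snp`, `a1`, `a2`, `b`,
#'   `se`, `p`; optionally `chrom`, `pos`, `freq`, `n`.
#' @return `x` invisibly; errors describe the first violated invariant.
#' @export
validateSumStats <- function(x) {
    stopifnot(is.data.frame(x))
    missing_cols <- setdiff(.SUMSTAT_CORE, names(x))
    if (length(missing_cols) > 0L)
        stop("summary-statistic table lacks column(s): ",
             paste(missing_cols, collapse = ", "))
    if (nrow(x) > 0L) {
        if (anyDuplicated(x$snp))
            stop("duplicated SNP id(s): ",
                 paste(unique(x$snp[duplicated(x$snp)]), collapse = ", "))
        if (any(!is.finite(x$se) | x$se <= 0))
            stop("all standard errors must be finite and > 0")
        if (any(!is.finite(x$p) | x$p <= 0 | x$p > 1))
            stop("all p-values must lie in (0, 1]")
        if (any(x$a1 == x$a2))
            stop("effect and other allele identical for: ",
                 paste(x$snp[x$a1 == x$a2], collapse = ", "))
        if ("freq" %in% names(x)) {
            bad <- !is.na(x$freq) & (x$freq < 0 | x$freq > 1)
            if (any(bad)) stop("allele frequencies outside [0, 1]")
        }
        if ("pos" %in% names(x)) {
            bad <- !is.na(x$pos) & x$pos < 1
            if (any(bad)) stop("positions must be >= 1 (1-based)")
        }
    }
    invisible(x)
}

#' GenotypePanel: reference genotypes for LD estimation
#'
#' Holds allele dosages (samples x SNPs, values in [0, 2], NA allowed) along
#' with per-SNP metadata. Dosages count copies of the `a1` allele of each SNP,
#' so Pearson correlations of dosage columns are signed LD (r) on the `a1`
#' coding.
#'
#' @slot sampleIds character vector of sample identifiers.
#' @slot snps data.frame with columns `snp`, `chrom`, `pos`, `a1`, `a2`.
#' @slot dosages numeric matrix, rows = samples, columns = SNPs.
#' @export
setClass("GenotypePanel",
    representation(
        sampleIds = "character",
        snps      = "data.frame",
        dosages   = "matrix"
    )
)

setValidity("GenotypePanel", function(object) {
    msgs <- character()
    need <- c("snp", "chrom", "pos", "a1", "a2")
    if (!all(need %in% names(object@snps)))
        msgs <- c(msgs, paste("snps table needs columns:",
                              paste(need, collapse = ", ")))
    if (nrow(object@dosages) != length(object@sampleIds))
        msgs <- c(msgs, "dosage rows must match sampleIds")
    if (ncol(object@dosages) != nrow(object@snps))
        msgs <- c(msgs, "dosage columns must match snps table")
    if (length(msgs) == 0L && ncol(object@dosages) > 0L) {
        if (!identical(colnames(object@dosages), object@snps$snp))
            msgs <- c(msgs, "dosage colnames must equal snps$snp")
        rng <- range(object@dosages, na.rm = TRUE)
        if (is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 2))
            msgs <- c(msgs, "dosages must lie in [0, 2]")
        all_missing <- colSums(!is.na(object@dosages)) == 0L
        if (any(all_missing))
            msgs <- c(msgs, paste("SNP(s) with all dosages missing:",
                paste(object@snps$snp[all_missing], collapse = ", ")))
        if (anyDuplicated(object@snps$snp))
            msgs <- c(msgs, "duplicated SNP ids in panel")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypePanel
#'
#' @param sampleIds character vector of sample ids.
#' @param snps data.frame with columns `snp`, `chrom`, `pos`, `a1`, `a2`.
#' @param dosages numeric matrix (samples x SNPs) of `a1`-allele dosages.
#' @return A [GenotypePanel-class] object.
#' @export
GenotypePanel <- function(sampleIds, snps, dosages) {
    dosages <- as.matrix(dosages)
    colnames(dosages) <- snps$snp
    rownames(dosages) <- sampleIds
    new("GenotypePanel", sampleIds = as.character(sampleIds),
        snps = as.data.frame(snps), dosages = dosages)
}

#' LDMatrix: signed pairwise allelic correlation
#'
#' Symmetric matrix of Pearson correlations between allele dosages, unit
#' diagonal, aligned to the effect-allele coding used to compute it.
#'
#' @slot snpIds ordered character vector of SNP ids.
#' @slot r numeric correlation matrix.
#' @export
setClass("LDMatrix",
    representation(snpIds = "character", r = "matrix")
)

setValidity("LDMatrix", function(object) {
    msgs <- character()
    m <- object@r
    if (nrow(m) != length(object@snpIds) || ncol(m) != length(object@snpIds))
        msgs <- c(msgs, "r must be square with dim = length(snpIds)")
    if (length(msgs) == 0L && length(object@snpIds) > 0L) {
        if (max(abs(m - t(m))) > 1e-8) msgs <- c(msgs, "r must be symmetric")
        if (max(abs(diag(m) - 1)) > 1e-8) msgs <- c(msgs, "diagonal must be 1")
        if (max(abs(m)) > 1 + 1e-8) msgs <- c(msgs, "entries must be in [-1, 1]")
    }
    if (length(msgs)) msgs else TRUE
})

#' QtlProbe: a molecular phenotype with its cis-QTL summary statistics
#'
#' One expression or methylation probe, its genomic annotation (chromosome,
#' position, closest/tagged gene), and the marginal SNP associations within
#' its cis window.
#'
#' @slot probeId probe identifier.
#' @slot chrom probe chromosome.
#' @slot pos probe position (1-based bp).
#' @slot gene tagged/closest gene symbol.
#' @slot layer `"expression"` or `"methylation"`.
#' @slot cisRecords data.frame of summary-statistic records
#'   (columns `snp`, `chrom`, `pos`, `a1`, `a2`, `freq`, `b`, `se`, `p`).
#' @export
setClass("QtlProbe",
    representation(
        probeId = "character",
        chrom   = "character",
        pos     = "numeric",
        gene    = "character",
        layer   = "character",
        cisRecords = "data.frame"
    )
)

setValidity("QtlProbe", function(object) {
    msgs <- character()
    if (!object@layer %in% c("expression", "methylation"))
        msgs <- c(msgs, "layer must be 'expression' or 'methylation'")
    v <- tryCatch({ validateSumStats(object@cisRecords); NULL },
                  error = function(e) conditionMessage(e))
    if (!is.null(v)) msgs <- c(msgs, v)
    if (length(msgs)) msgs else TRUE
})

#' Construct a QtlProbe
#'
#' @param probeId,chrom,pos,gene,layer probe annotation fields.
#' @param cisRecords data.frame of cis-SNP summary statistics.
#' @return A [QtlProbe-class] object.
#' @export
QtlProbe <- function(probeId, chrom, pos, gene, layer, cisRecords) {
    new("QtlProbe", probeId = as.character(probeId),
        chrom = as.character(chrom), pos = as.numeric(pos),
        gene = as.character(gene), layer = layer,
        cisRecords = as.data.frame(cisRecords))
}

setMethod("show", "GenotypePanel", function(object) {
    cat("GenotypePanel:", length(object@sampleIds), "samples x",
        nrow(object@snps), "SNPs\n")
    if (nrow(object@snps) > 0L) {
        miss <- mean(is.na(object@dosages))
        cat("  chrom:", paste(unique(object@snps$chrom), collapse = ","),
            sprintf(" missing: %.2f%%\n", 100 * miss))
    }
})

setMethod("show", "LDMatrix", function(object) {
    cat("LDMatrix over", length(object@snpIds), "SNPs\n")
    if (length(object@snpIds) > 1L) {
        off <- object@r[upper.tri(object@r)]
        cat(sprintf("  mean |r| = %.3f, max |r| = %.3f\n",
                    mean(abs(off)), max(abs(off))))
    }
})

setMethod("show", "QtlProbe", function(object) {
    cat(sprintf("QtlProbe %s (%s) gene=%s %s:%d, %d cis records\n",
        object@probeId, object@layer, object@gene, object@chrom,
        as.integer(object@pos), nrow(object@cisRecords)))
})
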