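#' Select the top cis-QTL for a probe
#'
#' Returns the cis-SNP with smallest QTL p-value, provided it passes the
#' genome-wide significance threshold; probes with no passing cis-QTL are
#' excluded from the analysis (signalled by `NA`). Ties at the minimal p are
#' broken by smaller position, then lexicographic SNP id.
#'
#' @param probe A [QtlProbe-class].
#' @param pThreshold top-QTL significance threshold (default 5e-8).
#' @return SNP id, or `NA_character_` (exclusion signal).
#' @export
selectTopCisQtl <- function(probe, pThreshold = 5e-8) {
    rec <- cisRecords(probe)
    if (nrow(rec) == 0L) return(NA_character_)
    ord <- order(rec$p, rec$pos, rec$snp)
    best <- rec[ord[1L], ]
    if (best$p < pThreshold) best$snp else NA_character_
}

#' SMR ratio estimate and test
#'
#' The Mendelian-randomization estimate of the effect of an exposure on an
#' outcome through a single instrument SNP is the ratio of the instrument's
#' outcome effect to its exposure effect, `bXy = bZy / bZx`. With instrument
#' z-statistics `zZx = bZx/seZx` and `zZy = bZy/seZy`, the test statistic is
#' `tSmr = zZx^2 * zZy^2 / (zZx^2 + zZy^2)`, referred to a 1-df chi-square
#' upper tail; `seXy = |bXy| / sqrt(tSmr)` (delta method, reported `NA` when
#' `tSmr = 0`).
#'
#' All arguments are vectorized.
#'
#' @param bZx,seZx instrument effect and SE on the exposure.
#' @param bZy,seZy instrument effect and SE on the outcome.
#' @return data.frame with columns `bXy`, `seXy`, `tSmr`, `pSmr`, `zZx`,
#'   `zZy`. Rows with `bZx = 0` are `NA` (undefined ratio).
#' @export
smrEffect <- function(bZx, seZx, bZy, seZy) {
    stopifnot(all(seZx > 0), all(seZy > 0))
    zZx <- bZx / seZx
    zZy <- bZy / seZy
    bXy <- ifelse(bZx == 0, NA_real_, bZy / bZx)
    tSmr <- ifelse(bZx == 0, NA_real_,
                   zZx^2 * zZy^2 / (zZx^2 + zZy^2))
    tSmr[!is.na(bZy) & bZy == 0 & bZx != 0] <- 0
    pSmr <- stats::pchisq(tSmr, df = 1, lower.tail = FALSE)
    seXy <- ifelse(is.na(tSmr) | tSmr <= 0, NA_real_,
                   abs(bXy) / sqrt(tSmr))
    data.frame(bXy = bXy, seXy = seXy, tSmr = tSmr, pSmr = pSmr,
               zZx = zZx, zZy = zZy)
}

#' Run SMR + HEIDI over a layer of QTL probes
#'
#' For each probe: selects the top cis-QTL (p < `pTopQtl`); harmonizes the
#' outcome summary statistics to the probe's effect-allele coding; computes
#' the SMR ratio estimate and test at the top SNP; builds the HEIDI SNP set
#' from LD with the reference panel and evaluates the HEIDI heterogeneity
#' test. Probes whose HEIDI set is smaller than `minHeidiSnps` get
#' `pHeidi = NA` and `heidiTestable = FALSE` (excluded from HEIDI pass
#' lists, as non-testable probes are). Probes whose top SNP is absent from
#' the outcome stats or the panel are skipped with a logged reason.
#'
#' @param probes list of [QtlProbe-class] (one omics layer).
#' @param outcomeStats data.frame of outcome (e.g. GWAS) summary statistics
#'   keyed by `snp`.
#' @param panel A [GenotypePanel-class] LD reference.
#' @param config pipeline settings from [pipelineConfig()].
#' @return data.frame with one row per analyzed probe: `probe`, `gene`,
#'   `probeChrom`, `probePos`, `topSnp`, `a1`, `a2`, `bZx`, `seZx`, `bZy`,
#'   `seZy`, `bXy`, `seXy`, `pSmr`, `pHeidi`, `nHeidiSnps`,
#'   `heidiTestable`, `heidiMethod`. Attribute `log`: data.frame of
#'   excluded probes and reasons; attribute `nEligible`: number of analyzed
#'   probes (the layer's multiple-testing burden).
#' @export
runSmrLayer <- function(probes, outcomeStats, panel,
                        config = pipelineConfig()) {
    log <- data.frame(probe = character(), reason = character(),
                      stringsAsFactors = FALSE)
    note <- function(pid, why) {
        log <<- rbind(log, data.frame(probe = pid, reason = why))
    }
    panel_info <- snpInfo(panel)
    rows <- vector("list", length(probes))
    for (k in seq_along(probes)) {
        pr <- probes[[k]]
        pid <- probeId(pr)
        top <- selectTopCisQtl(pr, config$p_top_qtl)
        if (is.na(top)) { note(pid, "no_significant_cis_qtl"); next }
        expo <- cisRecords(pr)
        if (!top %in% outcomeStats$snp) {
            note(pid, "top_snp_missing_from_outcome"); next
        }
        if (!top %in% panel_info$snp) {
            note(pid, "top_snp_missing_from_panel"); next
        }
        out_h <- harmonizeAlleles(outcomeStats, expo)
        if (!top %in% out_h$snp) {
            note(pid, "top_snp_unharmonizable"); next
        }
        ex_top <- expo[expo$snp == top, ]
        oy_top <- out_h[out_h$snp == top, ]
        smr <- smrEffect(ex_top$b, ex_top$se, oy_top$b, oy_top$se)

        # HEIDI over SNPs shared by exposure, outcome and panel
        shared <- Reduce(intersect,
                         list(expo$snp, out_h$snp, panel_info$snp))
        pHeidi <- NA_real_; nHeidi <- 0L; testable <- FALSE
        method <- NA_character_
        if (top %in% shared) {
            ea <- stats::setNames(expo$a1, expo$snp)[shared]
            ld <- tryCatch(
                ldCorrelation(panel, shared, effectAlleles = ea),
                error = function(e) NULL)
            if (!is.null(ld)) {
                pr_shared <- QtlProbe(pid, probeChrom(pr), probePos(pr),
                    probeGene(pr), omicsLayer(pr),
                    expo[expo$snp %in% shared, , drop = FALSE])
                set <- heidiSnpSet(pr_shared, top, ld,
                    pInclusion = config$heidi_inclusion_p,
                    r2Upper = config$r2_upper, r2Lower = config$r2_lower,
                    maxSnps = config$max_heidi_snps)
                if (length(set) >= config$min_heidi_snps) {
                    ht <- heidiTest(
                        expo[match(set, expo$snp), , drop = FALSE],
                        out_h[match(set, out_h$snp), , drop = FALSE],
                        ldSubset(ld, set), topSnp = top,
                        minSnps = config$min_heidi_snps)
                    pHeidi <- ht$pHeidi
                    nHeidi <- ht$nSnps
                    testable <- ht$testable
                    method <- ht$method
                } else nHeidi <- length(set)
            }
        }
        rows[[k]] <- data.frame(
            probe = pid, gene = probeGene(pr),
            probeChrom = probeChrom(pr), probePos = probePos(pr),
            topSnp = top, a1 = ex_top$a1, a2 = ex_top$a2,
            bZx = ex_top$b, seZx = ex_top$se,
            bZy = oy_top$b, seZy = oy_top$se,
            bXy = smr$bXy, seXy = smr$seXy, pSmr = smr$pSmr,
            pHeidi = pHeidi, nHeidiSnps = nHeidi,
            heidiTestable = testable, heidiMethod = method,
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(res))
        res <- data.frame(probe = character(), gene = character(),
            probeChrom = character(), probePos = numeric(),
            topSnp = character(), a1 = character(), a2 = character(),
            bZx = numeric(), seZx = numeric(), bZy = numeric(),
            seZy = numeric(), bXy = numeric(), seXy = numeric(),
            pSmr = numeric(), pHeidi = numeric(), nHeidiSnps = integer(),
            heidiTestable = logical(), heidiMethod = character())
    rownames(res) <- NULL
    attr(res, "log") <- log
    attr(res, "nEligible") <- nrow(res)
    res
}

#' Extract an LD submatrix
#'
#' @param ld An [LDMatrix-class].
#' @param ids SNP ids to keep, in this order.
#' @return An [LDMatrix-class] restricted to `ids`.
#' @export
ldSubset <- function(ld, ids) {
    r <- ldr(ld)
    dimnames(r) <- list(snpIds(ld), snpIds(ld))
    new("LDMatrix", snpIds = ids, r = r[ids, ids, drop = FALSE])
}
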