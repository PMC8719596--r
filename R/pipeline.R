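#' Run the full multi-omics SMR analysis
#'
#' Executes the three SMR + HEIDI layers (expression x trait, methylation x
#' trait, methylation x expression on passing probe pairs), applies
#' multiple-testing control per layer, assembles mediation triplets with
#' sign-consistency verdicts, optionally runs tissue-specificity
#' enrichment, and writes result TSVs plus a stage-count summary. Fully
#' deterministic given its inputs.
#'
#' A probe "passes" a layer when its SMR p-value is below the corrected
#' threshold (Bonferroni alpha / n-eligible by default), it is
#' HEIDI-testable, and its HEIDI p-value is >= `heidi_pass_p`.
#' In the methylation-to-expression SMR, DNAm is always the exposure,
#' instrumented by its top cis-mQTL; the expression probe's cis records
#' supply the outcome effects. The multiple-testing burden for that layer
#' is the number of distance-eligible pairs actually analyzed.
#'
#' @param config a [pipelineConfig()] list; file paths are used when
#'   `study` is `NULL`.
#' @param study optional in-memory study from [simulateStudy()] (fields
#'   `gwas`, `eqtlProbes`, `mqtlProbes`, `panel`); bypasses file input.
#' @param tissueTStats optional gene x tissue t-statistic matrix; when
#'   given, TSEA runs on the union of passing genes.
#' @return list of class `"SmrAnalysis"`: `config`, `eqtlResults`,
#'   `mqtlResults`, `pairs`, `m2eResults`, `triplets`, `genes`
#'   (union/intersection of passing genes), `tsea` (or `NULL`), `counts`,
#'   `thresholds`, `logs`.
#' @export
runFullAnalysis <- function(config = pipelineConfig(), study = NULL,
                            tissueTStats = NULL) {
    validatePipelineConfig(config)
    if (is.null(study)) {
        for (f in c("gwas", "eqtl", "mqtl", "panel"))
            if (is.na(config[[f]]))
                stop("config lacks input path '", f,
                     "' and no in-memory study was given")
        study <- list(
            gwas = readGwasMa(config$gwas),
            eqtlProbes = readQtlFlat(config$eqtl, layer = "expression",
                                     cisWindow = config$cis_window),
            mqtlProbes = readQtlFlat(config$mqtl, layer = "methylation",
                                     cisWindow = config$cis_window),
            panel = readVcfPanel(config$panel))
    }
    eqtlRes <- runSmrLayer(study$eqtlProbes, study$gwas, study$panel,
                           config)
    mqtlRes <- runSmrLayer(study$mqtlProbes, study$gwas, study$panel,
                           config)
    if (nrow(eqtlRes) == 0L || nrow(mqtlRes) == 0L)
        warning("no eligible probes in at least one omics layer; ",
                "returning an empty-result report")

    passSet <- function(res, thr) {
        res[!is.na(res$pSmr) & res$pSmr < thr &
            res$heidiTestable & !is.na(res$pHeidi) &
            res$pHeidi >= config$heidi_pass_p, , drop = FALSE]
    }
    smrSig <- function(res) {
        if (nrow(res) == 0L) return(res)
        if (config$multiple_testing == "bh") {
            res[bhSignificant(res$pSmr, config$alpha), , drop = FALSE]
        } else {
            thr <- bonferroniThreshold(config$alpha, nrow(res))
            res[res$pSmr < thr, , drop = FALSE]
        }
    }
    thrE <- if (nrow(eqtlRes)) bonferroniThreshold(config$alpha,
                                                   nrow(eqtlRes)) else NA
    thrM <- if (nrow(mqtlRes)) bonferroniThreshold(config$alpha,
                                                   nrow(mqtlRes)) else NA
    eqtlSig <- smrSig(eqtlRes)
    mqtlSig <- smrSig(mqtlRes)
    eqtlPass <- passSet(eqtlSig, Inf)
    mqtlPass <- passSet(mqtlSig, Inf)

    pairs <- m2tPairing(mqtlPass, eqtlPass, config$m2t_max_distance)

    # methylation -> expression SMR per candidate pair
    m2eRows <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        mp <- study$mqtlProbes[[pairs$dnamProbe[i]]]
        ep <- study$eqtlProbes[[pairs$exprProbe[i]]]
        res <- runSmrLayer(stats::setNames(list(mp), probeId(mp)),
                           cisRecords(ep), study$panel, config)
        if (nrow(res) == 1L) {
            res$exprProbe <- probeId(ep)
            m2eRows[[i]] <- res
        }
    }
    m2eRes <- do.call(rbind,
                      m2eRows[!vapply(m2eRows, is.null, logical(1))])
    if (is.null(m2eRes)) {
        m2eRes <- eqtlRes[0, , drop = FALSE]
        m2eRes$exprProbe <- character()
    }
    nPairTests <- nrow(m2eRes)
    if (nPairTests > 0L)
        message("runFullAnalysis: methylation-expression burden = ",
                nPairTests, " distance-eligible pair(s)")
    thrP <- if (nPairTests) bonferroniThreshold(config$alpha,
                                                nPairTests) else NA
    m2ePass <- if (nPairTests) passSet(
        if (config$multiple_testing == "bh")
            m2eRes[bhSignificant(m2eRes$pSmr, config$alpha), ,
                   drop = FALSE]
        else m2eRes[m2eRes$pSmr < thrP, , drop = FALSE], Inf)
        else m2eRes

    # mediation triplets for pairs whose m2e link passed all filters
    tripletRows <- lapply(seq_len(nrow(m2ePass)), function(i) {
        dn <- m2ePass$probe[i]; ex <- m2ePass$exprProbe[i]
        mrow <- mqtlPass[mqtlPass$probe == dn, ][1L, ]
        erow <- eqtlPass[eqtlPass$probe == ex, ][1L, ]
        cons <- mediationConsistency(mrow$bXy, m2ePass$bXy[i], erow$bXy)
        data.frame(dnamProbe = dn, exprProbe = ex, gene = erow$gene,
            dnamGene = mrow$gene,
            distanceBp = pairs$distanceBp[pairs$dnamProbe == dn &
                                          pairs$exprProbe == ex][1L],
            bM2t = mrow$bXy, pSmrM2t = mrow$pSmr, pHeidiM2t = mrow$pHeidi,
            bE2t = erow$bXy, pSmrE2t = erow$pSmr, pHeidiE2t = erow$pHeidi,
            bM2e = m2ePass$bXy[i], pSmrM2e = m2ePass$pSmr[i],
            pHeidiM2e = m2ePass$pHeidi[i],
            predictedBM2t = cons$predictedBM2t,
            relativeDeviation = cons$relativeDeviation,
            consistent = cons$consistent, stringsAsFactors = FALSE)
    })
    triplets <- do.call(rbind, tripletRows)
    if (is.null(triplets))
        triplets <- data.frame(dnamProbe = character(),
            exprProbe = character(), gene = character(),
            dnamGene = character(), distanceBp = numeric(),
            bM2t = numeric(), pSmrM2t = numeric(), pHeidiM2t = numeric(),
            bE2t = numeric(), pSmrE2t = numeric(), pHeidiE2t = numeric(),
            bM2e = numeric(), pSmrM2e = numeric(), pHeidiM2e = numeric(),
            predictedBM2t = numeric(), relativeDeviation = numeric(),
            consistent = logical())

    genes <- overlapGenes(eqtlPass$gene, mqtlPass$gene)
    tsea <- if (!is.null(tissueTStats) && length(genes$union) > 0L)
        tseaFisher(genes$union, tissueTStats, alpha = config$alpha)
        else NULL

    bundle <- list(config = config,
        eqtlResults = eqtlRes, mqtlResults = mqtlRes,
        eqtlSignificant = eqtlSig, mqtlSignificant = mqtlSig,
        eqtlPass = eqtlPass, mqtlPass = mqtlPass,
        pairs = pairs, m2eResults = m2eRes, m2ePass = m2ePass,
        triplets = triplets, genes = genes, tsea = tsea,
        thresholds = list(eqtl = thrE, mqtl = thrM, m2e = thrP),
        logs = list(eqtl = attr(eqtlRes, "log"),
                    mqtl = attr(mqtlRes, "log")))
    bundle$counts <- stageCounts(bundle)
    class(bundle) <- "SmrAnalysis"

    if (!is.na(config$outputDir)) {
        dir.create(config$outputDir, recursive = TRUE,
                   showWarnings = FALSE)
        o <- function(f) file.path(config$outputDir, f)
        writeSmrResults(eqtlRes, o("smr_eqtl.tsv"))
        writeSmrResults(mqtlRes, o("smr_mqtl.tsv"))
        writeSmrResults(m2eRes, o("smr_m2e.tsv"))
        utils::write.table(triplets, o("mediation_triplets.tsv"),
                           quote = FALSE, sep = "\t", row.names = FALSE)
        utils::write.table(bundle$counts, o("stage_counts.tsv"),
                           quote = FALSE, sep = "\t", row.names = FALSE)
        if (!is.null(tsea))
            utils::write.table(tsea, o("enrichment.tsv"), quote = FALSE,
                               sep = "\t", row.names = FALSE)
    }
    bundle
}

#' Stage-count summary of an analysis
#'
#' Counts per layer (eligible probes, SMR-significant probes and distinct
#' genes, HEIDI-testable, HEIDI-passing probes and distinct genes) and for
#' the integration stage (candidate pairs, pairs passing the
#' methylation-expression SMR + HEIDI, consistent triplets). Counts are
#' monotone non-increasing along each filter chain.
#'
#' @param bundle an `"SmrAnalysis"` list from [runFullAnalysis()].
#' @return data.frame with columns `stage` and `count`.
#' @export
stageCounts <- function(bundle) {
    layer <- function(res, sig, pass, name) {
        testable <- sig[sig$heidiTestable, , drop = FALSE]
        data.frame(stage = paste0(name, c("_eligible",
                "_smr_significant", "_smr_significant_genes",
                "_heidi_testable", "_heidi_pass", "_heidi_pass_genes")),
            count = c(nrow(res), nrow(sig), length(unique(sig$gene)),
                      nrow(testable), nrow(pass),
                      length(unique(pass$gene))))
    }
    rbind(
        layer(bundle$eqtlResults, bundle$eqtlSignificant,
              bundle$eqtlPass, "expression"),
        layer(bundle$mqtlResults, bundle$mqtlSignificant,
              bundle$mqtlPass, "methylation"),
        data.frame(stage = c("candidate_pairs", "pairs_analyzed",
                             "pairs_pass", "consistent_triplets",
                             "genes_union", "genes_intersection"),
                   count = c(nrow(bundle$pairs), nrow(bundle$m2eResults),
                             nrow(bundle$m2ePass),
                             sum(bundle$triplets$consistent),
                             length(bundle$genes$union),
                             length(bundle$genes$intersection))))
}

#' @export
print.SmrAnalysis <- function(x, ...) {
    cat("SmrAnalysis\n")
    print(x$counts, row.names = FALSE)
    invisible(x)
}
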