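#' Read GWAS summary statistics in COJO .ma format
#'
#' Whitespace-delimited text with header `SNP A1 A2 freq b se p n`. Rows with
#' non-numeric effect, standard error or p-value, with `se <= 0`, with p
#' outside (0, 1], or with identical alleles are rejected; the number of
#' rejected rows is reported via a message and the `"nRejected"` attribute.
#' Duplicated SNP ids keep the first occurrence, with a warning.
#'
#' @param path path to a .ma file.
#' @return data.frame with columns `snp`, `a1`, `a2`, `freq`, `b`, `se`,
#'   `p`, `n`; attribute `nRejected` holds the rejected-row count.
#' @export
readGwasMa <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                             colClasses = "character",
                             check.names = FALSE)
    need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "n")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols) > 0L)
        stop("GWAS .ma file missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    out <- data.frame(
        snp  = raw$SNP,
        a1   = toupper(raw$A1),
        a2   = toupper(raw$A2),
        freq = suppressWarnings(as.numeric(raw$freq)),
        b    = suppressWarnings(as.numeric(raw$b)),
        se   = suppressWarnings(as.numeric(raw$se)),
        p    = suppressWarnings(as.numeric(raw$p)),
        n    = suppressWarnings(as.numeric(raw$n)),
        stringsAsFactors = FALSE
    )
    bad <- !is.finite(out$b) | !is.finite(out$se) | !is.finite(out$p) |
        out$se <= 0 | out$p <= 0 | out$p > 1 | out$a1 == out$a2
    nRejected <- sum(bad)
    if (nRejected > 0L)
        message("readGwasMa: rejected ", nRejected, " malformed row(s)")
    out <- out[!bad, , drop = FALSE]
    if (anyDuplicated(out$snp)) {
        dup <- unique(out$snp[duplicated(out$snp)])
        warning("duplicated SNP id(s) dropped (first kept): ",
                paste(utils::head(dup, 5L), collapse = ", "))
        out <- out[!duplicated(out$snp), , drop = FALSE]
    }
    rownames(out) <- NULL
    attr(out, "nRejected") <- nRejected
    validateSumStats(out)
    out
}

#' Write GWAS summary statistics in COJO .ma format
#'
#' @param stats data.frame as returned by [readGwasMa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGwasMa <- function(stats, path) {
    validateSumStats(stats)
    out <- data.frame(SNP = stats$snp, A1 = stats$a1, A2 = stats$a2,
                      freq = stats$freq, b = stats$b, se = stats$se,
                      p = stats$p, n = stats$n)
    utils::write.table(out, path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    invisible(path)
}

#' Read cis-QTL summary statistics from flat TSV
#'
#' Tab/whitespace-delimited with header
#' `probe probe_chr probe_pos gene layer snp chr pos a1 a2 b se p`
#' (`layer` optional when given as an argument). Records farther than
#' `cisWindow` bp from the probe (inclusive boundary) or on another
#' chromosome are dropped with a logged count; probes with zero in-window
#' records are retained empty and excluded later by the top-QTL eligibility
#' rule.
#'
#' @param path path to the flat QTL file.
#' @param layer `"expression"` or `"methylation"`; overrides/substitutes the
#'   file's `layer` column.
#' @param cisWindow cis window half-width in bp (default 2 Mb).
#' @return named list of [QtlProbe-class]; attribute `nDropped` counts
#'   out-of-window records.
#' @export
readQtlFlat <- function(path, layer = NULL, cisWindow = 2e6) {
    if (!file.exists(path)) stop("file not found: ", path)
    stopifnot(cisWindow > 0)
    raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("probe", "probe_chr", "probe_pos", "gene",
              "snp", "chr", "pos", "a1", "a2", "b", "se", "p")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols) > 0L)
        stop("QTL flat file missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    if (is.null(layer)) {
        if (!"layer" %in% names(raw))
            stop("no 'layer' column in file and no layer argument given")
        layers <- raw$layer
    } else {
        layers <- rep(layer, nrow(raw))
    }
    raw$probe_chr <- as.character(raw$probe_chr)
    raw$chr <- as.character(raw$chr)
    in_window <- raw$chr == raw$probe_chr &
        abs(raw$pos - raw$probe_pos) <= cisWindow
    nDropped <- sum(!in_window)
    if (nDropped > 0L)
        message("readQtlFlat: dropped ", nDropped,
                " record(s) outside the ", cisWindow, " bp cis window")
    keep_probes <- unique(raw$probe)
    raw_in <- raw[in_window, , drop = FALSE]
    layers_in <- layers[in_window]
    probes <- lapply(keep_probes, function(pid) {
        i <- which(raw_in$probe == pid)
        meta_i <- which(raw$probe == pid)[1L]
        rec <- data.frame(
            snp = raw_in$snp[i], chrom = raw_in$chr[i], pos = raw_in$pos[i],
            a1 = toupper(raw_in$a1[i]), a2 = toupper(raw_in$a2[i]),
            freq = if ("freq" %in% names(raw_in)) raw_in$freq[i]
                   else rep(NA_real_, length(i)),
            b = raw_in$b[i], se = raw_in$se[i], p = raw_in$p[i],
            stringsAsFactors = FALSE
        )
        lyr <- if (length(i)) layers_in[i[1L]] else
            if (is.null(layer)) raw$layer[meta_i] else layer
        QtlProbe(probeId = pid, chrom = raw$probe_chr[meta_i],
                 pos = raw$probe_pos[meta_i], gene = raw$gene[meta_i],
                 layer = lyr, cisRecords = rec)
    })
    names(probes) <- keep_probes
    attr(probes, "nDropped") <- nDropped
    probes
}

#' Write cis-QTL probes to flat TSV
#'
#' Inverse of [readQtlFlat()].
#'
#' @param probes list of [QtlProbe-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeQtlFlat <- function(probes, path) {
    rows <- lapply(probes, function(p) {
        rec <- cisRecords(p)
        if (nrow(rec) == 0L) return(NULL)
        data.frame(probe = probeId(p), probe_chr = probeChrom(p),
                   probe_pos = probePos(p), gene = probeGene(p),
                   layer = omicsLayer(p), snp = rec$snp, chr = rec$chrom,
                   pos = rec$pos, a1 = rec$a1, a2 = rec$a2,
                   freq = if ("freq" %in% names(rec)) rec$freq else NA_real_,
                   b = rec$b, se = rec$se, p = rec$p)
    })
    out <- do.call(rbind, rows)
    utils::write.table(out, path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    invisible(path)
}

#' Read a reference genotype panel from VCF
#'
#' Biallelic SNVs with GT genotypes; dosages count the ALT allele, so the
#' panel's effect allele (`a1`) is ALT and `a2` is REF. Multi-allelic or
#' non-SNV records are dropped with a message.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @return A [GenotypePanel-class].
#' @export
readVcfPanel <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
        !grepl(",", fix$ALT, fixed = TRUE)
    if (any(!snv))
        message("readVcfPanel: dropped ", sum(!snv),
                " non-biallelic-SNV record(s)")
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[snv, , drop = FALSE]
    fix <- fix[snv, , drop = FALSE]
    # count ALT alleles in the GT string; "." anywhere -> missing
    dose_row <- function(g) {
        miss <- is.na(g) | grepl("\\.", g)
        d <- vapply(strsplit(g, "[/|]"), function(a)
            sum(a == "1"), numeric(1))
        d[miss] <- NA_real_
        d
    }
    dos <- t(apply(gt, 1L, dose_row))
    ids <- fix$ID
    ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
        is.na(ids) | ids == "."]
    snps <- data.frame(snp = ids, chrom = fix$CHROM,
                       pos = as.numeric(fix$POS),
                       a1 = toupper(fix$ALT), a2 = toupper(fix$REF),
                       stringsAsFactors = FALSE)
    GenotypePanel(sampleIds = colnames(gt), snps = snps,
                  dosages = t(dos))
}

#' Write a reference genotype panel as VCF
#'
#' Emits a minimal VCF 4.2 with GT genotypes. Requires integer dosages
#' (0/1/2); heterozygotes are written `0/1`, missing as `./.`.
#'
#' @param panel A [GenotypePanel-class].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
writeVcfPanel <- function(panel, path) {
    d <- dosages(panel)
    if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE))
        stop("writeVcfPanel requires integer dosages (0/1/2)")
    s <- snpInfo(panel)
    gt_of <- c("0/0", "0/1", "1/1")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", sampleIds(panel)), collapse = "\t")),
        con)
    for (j in seq_len(nrow(s))) {
        dj <- round(d[, j])
        gt <- ifelse(is.na(dj), "./.", gt_of[dj + 1L])
        writeLines(paste(c(s$chrom[j], s$pos[j], s$snp[j], s$a2[j], s$a1[j],
                           ".", "PASS", ".", "GT", gt), collapse = "\t"),
                   con)
    }
    invisible(path)
}

#' Read a genotype panel from dosage + map text files
#'
#' A minimal PLINK-like text alternative to VCF: `mapPath` is a TSV with
#' header `snp chrom pos a1 a2`; `dosPath` is a TSV with header
#' `sample <snp1> <snp2> ...`, one row per sample, dosages in [0, 2]
#' (fractional allowed, `NA` for missing). Dosages count the `a1` allele.
#'
#' @param dosPath path to the dosage table.
#' @param mapPath path to the SNP map.
#' @return A [GenotypePanel-class].
#' @export
readDosagePanel <- function(dosPath, mapPath) {
    map <- utils::read.table(mapPath, header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("snp", "chrom", "pos", "a1", "a2")
    if (!all(need %in% names(map)))
        stop("map file needs columns: ", paste(need, collapse = ", "))
    dos <- utils::read.table(dosPath, header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (names(dos)[1L] != "sample")
        stop("dosage file must start with a 'sample' column")
    samples <- as.character(dos$sample)
    m <- as.matrix(dos[, -1L, drop = FALSE])
    if (!identical(colnames(m), map$snp))
        m <- m[, map$snp, drop = FALSE]
    GenotypePanel(sampleIds = samples, snps = map, dosages = m)
}

#' Write a genotype panel as dosage + map text files
#'
#' @param panel A [GenotypePanel-class].
#' @param dosPath,mapPath output paths (see [readDosagePanel()]).
#' @return `dosPath`, invisibly.
#' @export
writeDosagePanel <- function(panel, dosPath, mapPath) {
    utils::write.table(snpInfo(panel), mapPath, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    d <- as.data.frame(dosages(panel))
    out <- cbind(sample = sampleIds(panel), d)
    utils::write.table(out, dosPath, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    invisible(dosPath)
}

#' Write SMR results as TSV
#'
#' Mirrors the SMR-software column set
#' (`probe, gene, topSNP, A1, A2, b_SMR, se_SMR, p_SMR, p_HEIDI, nsnp_HEIDI`).
#'
#' @param results data.frame from [runSmrLayer()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSmrResults <- function(results, path) {
    out <- data.frame(probe = results$probe, gene = results$gene,
                      topSNP = results$topSnp, A1 = results$a1,
                      A2 = results$a2, b_SMR = results$bXy,
                      se_SMR = results$seXy, p_SMR = results$pSmr,
                      p_HEIDI = results$pHeidi,
                      nsnp_HEIDI = results$nHeidiSnps)
    utils::write.table(out, path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    invisible(path)
}
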