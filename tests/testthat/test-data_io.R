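test_that("COJO .ma parsing accepts valid rows and rejects malformed ones", {
    f <- withr::local_tempfile(fileext = ".ma")
    writeLines(c("SNP A1 A2 freq b se p n",
                 "rs1 A G 0.3 0.1 0.02 1e-6 50000"), f)
    g <- readGwasMa(f)
    expect_equal(nrow(g), 1L)
    expect_equal(g$b, 0.1)
    expect_equal(g$snp, "rs1")
    expect_equal(attr(g, "nRejected"), 0L)

    writeLines(c("SNP A1 A2 freq b se p n",
                 "rs1 A G 0.3 0.1 0 1e-6 50000"), f)
    expect_message(g <- readGwasMa(f), "rejected 1")
    expect_equal(nrow(g), 0L)
    expect_equal(attr(g, "nRejected"), 1L)

    writeLines(c("SNP A1 A2 freq b se p n",
                 "rs1 A G 0.3 xyz 0.02 1e-6 50000",
                 "rs2 A G 0.3 0.1 0.02 1e-6 50000"), f)
    expect_message(g <- readGwasMa(f), "rejected 1")
    expect_equal(g$snp, "rs2")

    writeLines(c("SNP A1 A2 freq b p n",
                 "rs1 A G 0.3 0.1 1e-6 50000"), f)
    expect_error(readGwasMa(f), "se")
})

test_that("duplicated SNP ids are dropped with a warning", {
    f <- withr::local_tempfile(fileext = ".ma")
    writeLines(c("SNP A1 A2 freq b se p n",
                 "rs1 A G 0.3 0.1 0.02 1e-6 50000",
                 "rs1 A G 0.3 0.2 0.02 1e-6 50000"), f)
    expect_warning(g <- readGwasMa(f), "duplicated")
    expect_equal(nrow(g), 1L)
    expect_equal(g$b, 0.1)
})

test_that("GWAS read-write-read round trip preserves all records", {
    set.seed(3)
    sim <- simulateMediationCohort(simulationScenario("null", seed = 3,
        nSnps = 8, nGwas = 300, nQtl = 100, nRef = 50))
    f <- withr::local_tempfile(fileext = ".ma")
    writeGwasMa(sim$gwas, f)
    back <- readGwasMa(f)
    keep <- c("snp", "a1", "a2", "freq", "b", "se", "p", "n")
    expect_equal(back[keep], sim$gwas[keep], tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("cis window enforcement at load is inclusive at 2 Mb", {
    f <- withr::local_tempfile(fileext = ".tsv")
    hdr <- "probe\tprobe_chr\tprobe_pos\tgene\tlayer\tsnp\tchr\tpos\ta1\ta2\tb\tse\tp"
    row <- function(snp, pos, chr = "1")
        paste("cg1", "1", "1000000", "G1", "methylation", snp, chr, pos,
              "A", "G", "0.1", "0.02", "1e-9", sep = "\t")
    writeLines(c(hdr, row("rsIn", 3000000), row("rsOut", 3000001),
                 row("rsChr", 1000000, chr = "2")), f)
    expect_message(probes <- readQtlFlat(f), "dropped 2")
    expect_equal(cisRecords(probes[["cg1"]])$snp, "rsIn")
})

test_that("QTL records are grouped per probe and survive a round trip", {
    f <- withr::local_tempfile(fileext = ".tsv")
    hdr <- "probe\tprobe_chr\tprobe_pos\tgene\tlayer\tsnp\tchr\tpos\ta1\ta2\tb\tse\tp"
    rows <- unlist(lapply(c("cg1", "cg2"), function(pr)
        vapply(1:3, function(i)
            paste(pr, "1", "1000000", "G1", "methylation",
                  paste0(pr, "_rs", i), "1", 1000000 + i * 1000,
                  "A", "G", "0.1", "0.02", "1e-9", sep = "\t"),
            character(1))))
    writeLines(c(hdr, rows), f)
    probes <- readQtlFlat(f)
    expect_equal(length(probes), 2L)
    expect_equal(vapply(probes, function(p) nrow(cisRecords(p)),
                        integer(1)), c(cg1 = 3L, cg2 = 3L))
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeQtlFlat(probes, f2)
    back <- readQtlFlat(f2)
    expect_equal(cisRecords(back[["cg2"]])$snp,
                 cisRecords(probes[["cg2"]])$snp)
    expect_equal(cisRecords(back[["cg1"]])$b, cisRecords(probes[["cg1"]])$b)
})

test_that("VCF and dosage-panel round trips preserve genotypes", {
    set.seed(9)
    panel <- simulateGenotypes(20, 6, 0.5, seed = 9)
    f <- withr::local_tempfile(fileext = ".vcf")
    writeVcfPanel(panel, f)
    back <- readVcfPanel(f)
    expect_equal(dosages(back), dosages(panel), ignore_attr = TRUE)
    expect_equal(snpInfo(back)$snp, snpInfo(panel)$snp)
    expect_equal(snpInfo(back)$a1, snpInfo(panel)$a1)

    fd <- withr::local_tempfile(fileext = ".dos")
    fm <- withr::local_tempfile(fileext = ".map")
    writeDosagePanel(panel, fd, fm)
    back2 <- readDosagePanel(fd, fm)
    expect_equal(dosages(back2), dosages(panel), ignore_attr = TRUE)
})

test_that("summary-statistic invariants are enforced", {
    bad <- data.frame(snp = "rs1", a1 = "A", a2 = "A", b = 0.1,
                      se = 0.02, p = 0.5)
    expect_error(validateSumStats(bad), "identical")
    bad2 <- data.frame(snp = "rs1", a1 = "A", a2 = "G", b = 0.1,
                       se = 0.02, p = 0)
    expect_error(validateSumStats(bad2), "p-values")
})
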