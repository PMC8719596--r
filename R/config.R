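#' Pipeline configuration
#'
#' All thresholds of the SMR/HEIDI/mediation pipeline with their default
#' settings: 2 Mb cis window, top-QTL significance 5e-8, HEIDI SNP
#' inclusion p 1.57e-3 (chi-squared = 10), HEIDI pass threshold 0.01,
#' family-wise alpha 0.05, LD pruning r-squared bounds [0.05, 0.9], at
#' most 20 and at least 3 HEIDI SNPs, 2 Mb methylation-expression pairing
#' distance.
#'
#' @param gwas,eqtl,mqtl,panel input file paths (GWAS .ma, QTL flat TSVs,
#'   VCF reference panel); may be `NA` when the pipeline is driven from
#'   in-memory objects.
#' @param outputDir directory for result TSVs (`NA` = do not write).
#' @param p_top_qtl top cis-QTL significance threshold.
#' @param cis_window cis window half-width, bp.
#' @param heidi_inclusion_p HEIDI SNP inclusion p threshold.
#' @param heidi_pass_p HEIDI pass threshold (pass when p >= this).
#' @param alpha family-wise significance level.
#' @param r2_upper,r2_lower LD pruning bounds on r-squared with the top SNP.
#' @param max_heidi_snps,min_heidi_snps HEIDI SNP-set size bounds.
#' @param m2t_max_distance methylation-expression pairing distance, bp
#'   (strict `<`).
#' @param multiple_testing `"bonferroni"` (the default interpretation of
#'   the corrected threshold) or `"bh"` (Benjamini-Hochberg comparison
#'   option).
#' @param seed RNG seed recorded with the run.
#' @return a validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(gwas = NA_character_, eqtl = NA_character_,
        mqtl = NA_character_, panel = NA_character_,
        outputDir = NA_character_,
        p_top_qtl = 5e-8, cis_window = 2e6,
        heidi_inclusion_p = 1.57e-3, heidi_pass_p = 0.01,
        alpha = 0.05, r2_upper = 0.9, r2_lower = 0.05,
        max_heidi_snps = 20L, min_heidi_snps = 3L,
        m2t_max_distance = 2e6,
        multiple_testing = c("bonferroni", "bh"), seed = 1L) {
    multiple_testing <- match.arg(multiple_testing)
    cfg <- list(gwas = gwas, eqtl = eqtl, mqtl = mqtl, panel = panel,
        outputDir = outputDir, p_top_qtl = p_top_qtl,
        cis_window = cis_window, heidi_inclusion_p = heidi_inclusion_p,
        heidi_pass_p = heidi_pass_p, alpha = alpha,
        r2_upper = r2_upper, r2_lower = r2_lower,
        max_heidi_snps = as.integer(max_heidi_snps),
        min_heidi_snps = as.integer(min_heidi_snps),
        m2t_max_distance = m2t_max_distance,
        multiple_testing = multiple_testing, seed = as.integer(seed))
    validatePipelineConfig(cfg)
    structure(cfg, class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' @param cfg a configuration list.
#' @return `cfg` invisibly; errors on the first invalid field.
#' @export
validatePipelineConfig <- function(cfg) {
    chk <- function(ok, what) if (!ok) stop("invalid config: ", what)
    inP <- function(x) is.numeric(x) && x > 0 && x <= 1
    chk(inP(cfg$p_top_qtl), "p_top_qtl must be in (0, 1]")
    chk(inP(cfg$heidi_inclusion_p), "heidi_inclusion_p must be in (0, 1]")
    chk(inP(cfg$heidi_pass_p), "heidi_pass_p must be in (0, 1]")
    chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
        "alpha must be in (0, 1)")
    chk(cfg$cis_window > 0, "cis_window must be > 0")
    chk(cfg$m2t_max_distance > 0, "m2t_max_distance must be > 0")
    chk(cfg$r2_lower >= 0 && cfg$r2_upper <= 1 &&
        cfg$r2_lower < cfg$r2_upper, "r2 bounds must satisfy 0 <= lower < upper <= 1")
    chk(cfg$min_heidi_snps >= 2, "min_heidi_snps must be >= 2")
    chk(cfg$max_heidi_snps >= cfg$min_heidi_snps,
        "max_heidi_snps must be >= min_heidi_snps")
    chk(cfg$multiple_testing %in% c("bonferroni", "bh"),
        "multiple_testing must be 'bonferroni' or 'bh'")
    invisible(cfg)
}

#' Read / write pipeline configuration as YAML
#'
#' Round-trip safe: `readPipelineConfig(writePipelineConfig(cfg, f))` has
#' identical effective settings.
#'
#' @param cfg a [pipelineConfig()] list.
#' @param path YAML file path.
#' @return `writePipelineConfig`: `path` invisibly;
#'   `readPipelineConfig`: a `"PipelineConfig"` list.
#' @export
writePipelineConfig <- function(cfg, path) {
    yaml::write_yaml(unclass(cfg), path)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    raw <- lapply(raw, function(x) if (is.null(x)) NA else x)
    do.call(pipelineConfig, raw)
}
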