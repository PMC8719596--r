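.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.complementAllele <- function(a) {
    out <- .COMPLEMENT[a]
    out[is.na(out)] <- NA_character_
    unname(out)
}

.isPalindromic <- function(a1, a2) {
    (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize effect alleles of one dataset against a reference
#'
#' Aligns the effect-allele coding of `target` summary statistics to that of
#' `reference`, matching rows by SNP id. For each shared SNP:
#' \itemize{
#'   \item same (a1, a2) as the reference: record kept unchanged;
#'   \item swapped alleles: sign of `b` flipped, `freq` mapped to `1 - freq`,
#'     alleles swapped;
#'   \item strand flip (complemented alleles), direct or swapped: resolved the
#'     same way;
#'   \item any other allele pair: dropped (mismatch).
#' }
#' Palindromic SNPs (A/T or C/G) are strand-ambiguous. They are dropped when
#' the target frequency is missing or in [`ambiguousMaf[1]`,
#' `ambiguousMaf[2]`]; otherwise orientation is taken from allele frequency
#' when the reference frequency is informative, falling back to allele-label
#' matching when it is not.
#'
#' Harmonization is an involution: applying it twice against the same
#' reference returns the first result.
#'
#' @param target data.frame of summary statistics to re-code (columns `snp`,
#'   `a1`, `a2`, `b`, optionally `freq`, `se`, `p`, ...).
#' @param reference data.frame supplying the desired allele coding (columns
#'   `snp`, `a1`, `a2`, optionally `freq`).
#' @param ambiguousMaf frequency band within which palindromic SNPs are
#'   considered unresolvable (default `c(0.4, 0.6)`).
#' @return The harmonized subset of `target` (rows restricted to resolvable
#'   SNPs shared with the reference), with attribute `dropped`: a data.frame
#'   of `snp` and `reason` (`"not_in_reference"`, `"allele_mismatch"`,
#'   `"palindromic_ambiguous"`).
#' @export
harmonizeAlleles <- function(target, reference,
                             ambiguousMaf = c(0.4, 0.6)) {
    stopifnot(is.data.frame(target), is.data.frame(reference))
    has_freq <- "freq" %in% names(target)
    ref_freq <- if ("freq" %in% names(reference)) reference$freq else
        rep(NA_real_, nrow(reference))
    idx <- match(target$snp, reference$snp)
    dropped <- data.frame(snp = character(), reason = character(),
                          stringsAsFactors = FALSE)
    keep <- !is.na(idx)
    if (any(!keep))
        dropped <- rbind(dropped, data.frame(
            snp = target$snp[!keep], reason = "not_in_reference"))
    tg <- target[keep, , drop = FALSE]
    rf <- reference[idx[keep], , drop = FALSE]
    rfreq <- ref_freq[idx[keep]]

    t1 <- toupper(tg$a1); t2 <- toupper(tg$a2)
    r1 <- toupper(rf$a1); r2 <- toupper(rf$a2)
    c1 <- .complementAllele(t1); c2 <- .complementAllele(t2)

    same    <- t1 == r1 & t2 == r2
    swap    <- t1 == r2 & t2 == r1
    fsame   <- !is.na(c1) & !is.na(c2) & c1 == r1 & c2 == r2
    fswap   <- !is.na(c1) & !is.na(c2) & c1 == r2 & c2 == r1
    pal     <- .isPalindromic(t1, t2)

    action <- rep(NA_character_, nrow(tg))   # "keep", "flip", "drop"
    action[same | fsame] <- "keep"
    action[(swap | fswap) & is.na(action)] <- "flip"
    action[is.na(action)] <- "mismatch"

    if (any(pal)) {
        tfreq <- if (has_freq) tg$freq else rep(NA_real_, nrow(tg))
        ambiguous <- is.na(tfreq) |
            (tfreq >= ambiguousMaf[1L] & tfreq <= ambiguousMaf[2L])
        action[pal & ambiguous] <- "pal_drop"
        # orient resolvable palindromes by frequency when the reference
        # frequency is informative; otherwise trust the allele labels
        fixable <- pal & !ambiguous & action %in% c("keep", "flip")
        informative <- fixable & !is.na(rfreq) &
            !(rfreq >= ambiguousMaf[1L] & rfreq <= ambiguousMaf[2L])
        if (any(informative)) {
            agree <- abs(tg$freq[informative] - rfreq[informative]) <=
                     abs(tg$freq[informative] - (1 - rfreq[informative]))
            action[informative] <- ifelse(agree, "keep", "flip")
        }
    }

    if (any(action == "mismatch"))
        dropped <- rbind(dropped, data.frame(
            snp = tg$snp[action == "mismatch"], reason = "allele_mismatch"))
    if (any(action == "pal_drop"))
        dropped <- rbind(dropped, data.frame(
            snp = tg$snp[action == "pal_drop"],
            reason = "palindromic_ambiguous"))

    out <- tg[action %in% c("keep", "flip"), , drop = FALSE]
    act <- action[action %in% c("keep", "flip")]
    ref_kept <- rf[action %in% c("keep", "flip"), , drop = FALSE]
    flip <- act == "flip"
    out$b[flip] <- -out$b[flip]
    if (has_freq) out$freq[flip] <- 1 - out$freq[flip]
    # adopt the reference's allele labels (also normalizes strand flips)
    out$a1 <- toupper(ref_kept$a1)
    out$a2 <- toupper(ref_kept$a2)
    rownames(out) <- NULL
    attr(out, "dropped") <- dropped
    out
}
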