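#' @include AllClasses.R
NULL

#' Contig N50
#'
#' The smallest contig length L such that contigs of length at least L
#' together contain at least half of the total assembly. When the cumulative
#' sum first meets exactly half the total, that contig's length is the N50.
#'
#' @param contigLengths positive integer contig lengths.
#' @return integer N50 in bp; always the length of some contig.
#' @examples
#' computeN50(c(5, 4, 3, 2, 1))  # 4
#' @export
computeN50 <- function(contigLengths) {
    if (length(contigLengths) == 0L)
        stop("N50 undefined for an empty assembly")
    if (any(contigLengths <= 0)) stop("contig lengths must be positive")
    lens <- sort(as.numeric(contigLengths), decreasing = TRUE)
    half <- sum(lens) / 2
    idx <- which(cumsum(lens) >= half)[1L]
    as.integer(lens[idx])
}

#' Genomic GC fraction and GC bias
#'
#' Pools base counts over all contigs and reports (G+C)/(A+C+G+T) together
#' with its deviation from 0.50. Ambiguity codes (including N) are excluded
#' from both numerator and denominator. GC bias, the deviation from an
#' equal-substitution expectation of 50%, tracks reduced per-read information
#' content and harder assembly.
#'
#' @param assembly an [Assembly-class], `DNAStringSet`, or character vector
#'   of contig sequences.
#' @return list with `gc_fraction` and `gc_deviation` (both proportions).
#' @export
computeGcDeviation <- function(assembly) {
    dna <- if (is(assembly, "Assembly")) contigs(assembly)
           else if (is(assembly, "DNAStringSet")) assembly
           else Biostrings::DNAStringSet(assembly)
    counts <- colSums(Biostrings::letterFrequency(dna, c("A", "C", "G", "T")))
    denom <- sum(counts)
    if (denom == 0) stop("no unambiguous A/C/G/T bases present")
    gc <- (counts[["C"]] + counts[["G"]]) / denom
    list(gc_fraction = gc, gc_deviation = abs(gc - 0.5))
}

#' Summarize ORF completeness
#'
#' Counts complete versus partial ORFs (partial = any truncation), the
#' percentage of all predicted ORFs that are fragments, and the mean ORF
#' length in amino acids over all ORFs. Percentages are rounded half-up to
#' one decimal at reporting time; `pct_partial_raw` keeps full precision.
#'
#' @param orfs an [OrfSet-class].
#' @return list with `n_complete`, `n_partial`, `pct_partial` (one decimal),
#'   `pct_partial_raw`, and `mean_orf_length_aa` (`NaN` when no ORFs).
#' @examples
#' ## counting directly from printed complete/partial totals:
#' ## 5442 complete + 575 partial -> 9.6% partial
#' @export
summarizeOrfs <- function(orfs) {
    tr <- truncation(orfs)
    nPartial <- sum(tr != "NONE")
    nComplete <- length(tr) - nPartial
    total <- nComplete + nPartial
    raw <- if (total > 0L) 100 * nPartial / total else NaN
    list(n_complete = nComplete, n_partial = nPartial,
         pct_partial = roundHalfUp(raw, 1L), pct_partial_raw = raw,
         mean_orf_length_aa = if (total > 0L) mean(orfLengths(orfs)) else NaN)
}

## round half away from zero, as printed tables do (base round() is banker's)
roundHalfUp <- function(x, digits = 1L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent-partial from printed counts
#'
#' Convenience for reproducing published complete/partial tallies:
#' `100 * partial / (complete + partial)` rounded half-up to one decimal.
#'
#' @param nComplete,nPartial ORF counts.
#' @return percent to one decimal.
#' @examples
#' pctPartial(5442, 575)  # 9.6
#' pctPartial(2503, 8392) # 77.0
#' @export
pctPartial <- function(nComplete, nPartial) {
    total <- nComplete + nPartial
    if (any(total == 0)) stop("no ORFs")
    roundHalfUp(100 * nPartial / total, 1L)
}

#' Per-genome assembly and ORF quality report
#'
#' Aggregates [computeN50()], [computeGcDeviation()] and [summarizeOrfs()]
#' into one row of per-genome quality metrics.
#'
#' @param assembly an [Assembly-class].
#' @param orfs an [OrfSet-class] from the same genome.
#' @return one-row `data.frame` with columns `genome_id`, `n_contigs`,
#'   `total_bp`, `n50`, `gc_fraction`, `gc_deviation`, `n_complete_orfs`,
#'   `n_partial_orfs`, `pct_partial`, `mean_orf_length_aa`.
#' @export
genomeReport <- function(assembly, orfs) {
    if (!identical(genomeId(assembly), genomeId(orfs)))
        stop("genome_id mismatch: assembly is ", sQuote(genomeId(assembly)),
             " but ORFs are ", sQuote(genomeId(orfs)))
    lens <- Biostrings::width(contigs(assembly))
    gc <- computeGcDeviation(assembly)
    os <- summarizeOrfs(orfs)
    data.frame(genome_id = genomeId(assembly),
               n_contigs = length(lens),
               total_bp = sum(lens),
               n50 = computeN50(lens),
               gc_fraction = gc$gc_fraction,
               gc_deviation = gc$gc_deviation,
               n_complete_orfs = os$n_complete,
               n_partial_orfs = os$n_partial,
               pct_partial = os$pct_partial,
               mean_orf_length_aa = os$mean_orf_length_aa,
               stringsAsFactors = FALSE)
}
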