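#' @import methods
#' @importFrom Biostrings AAStringSet DNAStringSet width
NULL

TRUNCATION_LEVELS <- c("NONE", "FIVE_PRIME", "THREE_PRIME", "BOTH")

#' Set of predicted ORFs for one genome
#'
#' An `OrfSet` holds every predicted protein of one genome together with its
#' contig location, coding strand and truncation state. Truncation is defined
#' on the coding strand: `FIVE_PRIME` means the start codon is missing (the
#' ORF runs off a contig end upstream of its start), `THREE_PRIME` means the
#' stop codon is missing, `BOTH` means the ORF is an internal piece bounded
#' by contig ends on both sides, and `NONE` marks a complete ORF.
#'
#' @slot genomeId single genome identifier.
#' @slot table `data.frame` with columns `orf_id`, `contig_id`, `start`,
#'   `end` (1-based inclusive bp on the contig), `strand` (+1/-1) and
#'   `truncation` (one of NONE, FIVE_PRIME, THREE_PRIME, BOTH).
#' @slot sequences [Biostrings::AAStringSet] of amino-acid sequences, named
#'   by `orf_id` and parallel to `table`.
#'
#' @seealso [readProteins()], [summarizeOrfs()], [linkFragments()]
#' @export
setClass("OrfSet", representation(
    genomeId = "character",
    table = "data.frame",
    sequences = "AAStringSet"
))

setValidity("OrfSet", function(object) {
    tb <- object@table
    need <- c("orf_id", "contig_id", "start", "end", "strand", "truncation")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    if (length(object@genomeId) != 1L || is.na(object@genomeId))
        return("genomeId must be a single non-NA string")
    if (nrow(tb) != length(object@sequences))
        return("table and sequences differ in length")
    if (nrow(tb) == 0L) return(TRUE)
    if (anyDuplicated(tb$orf_id)) return("duplicated orf_id")
    if (!identical(as.character(names(object@sequences)), as.character(tb$orf_id)))
        return("sequence names must equal table$orf_id, in order")
    if (any(Biostrings::width(object@sequences) == 0L))
        return("empty amino-acid sequence")
    if (any(tb$start > tb$end)) return("start > end")
    if (any(tb$start < 1L)) return("start < 1")
    if (!all(tb$strand %in% c(1L, -1L, 1, -1))) return("strand must be +1 or -1")
    if (!all(tb$truncation %in% TRUNCATION_LEVELS))
        return(paste("truncation must be one of", paste(TRUNCATION_LEVELS, collapse = "/")))
    TRUE
})

#' Construct an OrfSet
#'
#' @param genomeId genome identifier.
#' @param table ORF table (see [OrfSet-class]).
#' @param sequences `AAStringSet` (or named character vector) of amino-acid
#'   sequences in table order.
#' @return an [OrfSet-class] object.
#' @export
OrfSet <- function(genomeId, table, sequences) {
    if (!is(sequences, "AAStringSet"))
        sequences <- Biostrings::AAStringSet(sequences)
    table <- as.data.frame(table, stringsAsFactors = FALSE)
    if (nrow(table) > 0L) {
        table$orf_id <- as.character(table$orf_id)
        table$contig_id <- as.character(table$contig_id)
        table$start <- as.integer(table$start)
        table$end <- as.integer(table$end)
        table$strand <- as.integer(table$strand)
        table$truncation <- as.character(table$truncation)
        names(sequences) <- table$orf_id
    }
    rownames(table) <- NULL
    new("OrfSet", genomeId = as.character(genomeId), table = table,
        sequences = sequences)
}

#' Nucleotide assembly for one genome
#'
#' Wraps the contig sequences of one assembly; contig names must be unique.
#'
#' @slot genomeId single genome identifier.
#' @slot contigs named [Biostrings::DNAStringSet] of contig sequences.
#' @export
setClass("Assembly", representation(
    genomeId = "character",
    contigs = "DNAStringSet"
))

setValidity("Assembly", function(object) {
    if (length(object@genomeId) != 1L) return("genomeId must be length 1")
    if (length(object@contigs) > 0L) {
        if (is.null(names(object@contigs))) return("contigs must be named")
        if (anyDuplicated(names(object@contigs))) return("duplicated contig_id")
    }
    TRUE
})

#' Construct an Assembly
#' @param genomeId genome identifier.
#' @param contigs named `DNAStringSet` or character vector of contig sequences.
#' @return an [Assembly-class] object.
#' @export
Assembly <- function(genomeId, contigs) {
    if (!is(contigs, "DNAStringSet"))
        contigs <- Biostrings::DNAStringSet(contigs)
    new("Assembly", genomeId = as.character(genomeId), contigs = contigs)
}

#' Scaffold layout of contigs
#'
#' Ordered, oriented arrangement of contigs per scaffold, used as ground
#' truth when validating fragment links: two fragments linked in a set are
#' congruent with the scaffold when their contigs are consecutive in one
#' scaffold and their truncated ends face the intervening gap.
#'
#' @slot table `data.frame` with columns `scaffold_id`, `rank` (1-based
#'   consecutive within scaffold), `contig_id`, `orientation` ("+" or "-").
#' @seealso [readScaffoldMap()], [classifyPair()]
#' @export
setClass("ScaffoldMap", representation(table = "data.frame"))

setValidity("ScaffoldMap", function(object) {
    tb <- object@table
    need <- c("scaffold_id", "rank", "contig_id", "orientation")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    if (nrow(tb) == 0L) return(TRUE)
    if (anyDuplicated(tb$contig_id))
        return("a contig appears in more than one scaffold entry")
    if (!all(tb$orientation %in% c("+", "-")))
        return("orientation must be '+' or '-'")
    bad <- vapply(split(tb$rank, tb$scaffold_id), function(r)
        !identical(sort(as.integer(r)), seq_along(r)), logical(1))
    if (any(bad))
        return("ranks must be consecutive integers starting at 1 per scaffold")
    TRUE
})

#' Construct a ScaffoldMap
#' @param table data.frame with scaffold_id, rank, contig_id, orientation.
#' @return a [ScaffoldMap-class] object.
#' @export
ScaffoldMap <- function(table) {
    table <- as.data.frame(table, stringsAsFactors = FALSE)
    if (nrow(table) > 0L) {
        table$scaffold_id <- as.character(table$scaffold_id)
        table$rank <- as.integer(table$rank)
        table$contig_id <- as.character(table$contig_id)
        table$orientation <- as.character(table$orientation)
    }
    rownames(table) <- NULL
    new("ScaffoldMap", table = table)
}

#' Linked fragment sets
#'
#' Long-format container for fragment sets: each row is one member fragment
#' of one set. Members are ordered within a set by ascending start on the
#' complete reference homolog that anchors the set.
#'
#' @slot table `data.frame` with columns `set_id`, `genome_id`,
#'   `fragment_id`, `member_rank`, `identity` (percent identity of the
#'   member to the reference), `ref_start`, `ref_end` (aa interval covered on
#'   the reference), `reference_protein_id`, `reference_genome_id`,
#'   `mean_identity` (arithmetic mean of member identities, repeated per row).
#' @seealso [linkFragments()], [resolveConflicts()], [mergeInventory()]
#' @export
setClass("FragmentSets", representation(table = "data.frame"))

fragmentSetCols <- c("set_id", "genome_id", "fragment_id", "member_rank",
                     "identity", "ref_start", "ref_end",
                     "reference_protein_id", "reference_genome_id",
                     "mean_identity")

setValidity("FragmentSets", function(object) {
    tb <- object@table
    if (!all(fragmentSetCols %in% names(tb)))
        return(paste("table must have columns:",
                     paste(fragmentSetCols, collapse = ", ")))
    if (nrow(tb) == 0L) return(TRUE)
    for (s in split(tb, tb$set_id)) {
        if (nrow(s) < 2L) return("a fragment set must have >= 2 members")
        if (anyDuplicated(s$fragment_id))
            return("duplicated member within a set")
        if (abs(mean(s$identity) - s$mean_identity[1L]) > 1e-8)
            return("mean_identity inconsistent with member identities")
    }
    TRUE
})

#' Construct a FragmentSets object
#' @param table long-format member table (see [FragmentSets-class]).
#' @return a [FragmentSets-class] object.
#' @export
FragmentSets <- function(table = emptyFragmentTable()) {
    table <- as.data.frame(table, stringsAsFactors = FALSE)
    rownames(table) <- NULL
    new("FragmentSets", table = table)
}

emptyFragmentTable <- function() {
    data.frame(set_id = character(), genome_id = character(),
               fragment_id = character(), member_rank = integer(),
               identity = numeric(), ref_start = integer(),
               ref_end = integer(), reference_protein_id = character(),
               reference_genome_id = character(), mean_identity = numeric(),
               stringsAsFactors = FALSE)
}

#' Linkage thresholds
#'
#' The four stringency thresholds of the fragment-linkage procedure plus the
#' truncation budget and end-order rule.
#'
#' @slot minIdentityPct minimum percent identity of a fragment to the
#'   complete reference homolog (threshold i, default 30).
#' @slot minOverlapFrac minimum fraction of the fragment's length that must
#'   be covered by the alignment to the reference (threshold ii, default 0.7).
#' @slot maxIdentitySpreadPct maximum allowed difference between a member's
#'   identity and the seed member's identity within one set (threshold iii,
#'   default 40).
#' @slot maxFragmentOverlapAa maximum number of amino acids by which the
#'   reference intervals of two set members may overlap (threshold iv,
#'   default 10).
#' @slot maxSingleEndTruncated maximum number of members truncated at only
#'   one end (5' or 3') per set; internal (BOTH-truncated) pieces are
#'   unlimited (default 2).
#' @slot enforceEndOrder when TRUE, a 3'-truncated member (which carries the
#'   start) must be leftmost on the reference and a 5'-truncated member
#'   (which carries the stop) rightmost.
#' @slot overlapMode coverage basis for threshold ii: "fragment" (default)
#'   or "reference".
#' @export
setClass("LinkageParams", representation(
    minIdentityPct = "numeric",
    minOverlapFrac = "numeric",
    maxIdentitySpreadPct = "numeric",
    maxFragmentOverlapAa = "numeric",
    maxSingleEndTruncated = "numeric",
    enforceEndOrder = "logical",
    overlapMode = "character"
))

setValidity("LinkageParams", function(object) {
    if (object@minIdentityPct < 0 || object@minIdentityPct > 100)
        return("minIdentityPct must be in [0, 100]")
    if (object@minOverlapFrac <= 0 || object@minOverlapFrac > 1)
        return("minOverlapFrac must be in (0, 1]")
    if (object@maxIdentitySpreadPct < 0)
        return("maxIdentitySpreadPct must be non-negative")
    if (object@maxFragmentOverlapAa < 0)
        return("maxFragmentOverlapAa must be non-negative")
    if (object@maxSingleEndTruncated < 0)
        return("maxSingleEndTruncated must be non-negative")
    if (!object@overlapMode %in% c("fragment", "reference"))
        return("overlapMode must be 'fragment' or 'reference'")
    TRUE
})

#' Construct linkage parameters
#'
#' @param minIdentityPct,minOverlapFrac,maxIdentitySpreadPct,maxFragmentOverlapAa
#'   the four thresholds (see [LinkageParams-class]).
#' @param maxSingleEndTruncated single-end truncation budget per set.
#' @param enforceEndOrder require start-bearing/stop-bearing members at the
#'   reference ends.
#' @param overlapMode coverage basis for the overlap threshold.
#' @return a [LinkageParams-class] object.
#' @export
LinkageParams <- function(minIdentityPct = 30, minOverlapFrac = 0.7,
                          maxIdentitySpreadPct = 40, maxFragmentOverlapAa = 10,
                          maxSingleEndTruncated = 2, enforceEndOrder = TRUE,
                          overlapMode = c("fragment", "reference")) {
    new("LinkageParams",
        minIdentityPct = minIdentityPct, minOverlapFrac = minOverlapFrac,
        maxIdentitySpreadPct = maxIdentitySpreadPct,
        maxFragmentOverlapAa = maxFragmentOverlapAa,
        maxSingleEndTruncated = maxSingleEndTruncated,
        enforceEndOrder = enforceEndOrder,
        overlapMode = match.arg(overlapMode))
}

#' AAI filter parameters
#'
#' Filters applied to bidirectional best-hit pairs before averaging percent
#' identity into an AAI value: a pair is kept when both members are complete
#' ORFs, both directional hits reach the identity floor, and the alignment
#' covers at least the coverage fraction of both protein lengths.
#'
#' @slot minIdentityPct identity floor in percent (default 30).
#' @slot minCoverageFrac coverage floor as a fraction of both protein
#'   lengths (default 0.70).
#' @slot completeOnly restrict to complete (non-truncated) ORFs.
#' @export
setClass("AaiParams", representation(
    minIdentityPct = "numeric",
    minCoverageFrac = "numeric",
    completeOnly = "logical"
))

setValidity("AaiParams", function(object) {
    if (object@minCoverageFrac <= 0 || object@minCoverageFrac > 1)
        return("minCoverageFrac must be in (0, 1]")
    if (object@minIdentityPct < 0 || object@minIdentityPct > 100)
        return("minIdentityPct must be in [0, 100]")
    TRUE
})

#' Construct AAI parameters
#' @param minIdentityPct identity floor (percent).
#' @param minCoverageFrac coverage floor (fraction of both lengths).
#' @param completeOnly restrict to complete ORFs.
#' @return an [AaiParams-class] object.
#' @export
AaiParams <- function(minIdentityPct = 30, minCoverageFrac = 0.70,
                      completeOnly = TRUE) {
    new("AaiParams", minIdentityPct = minIdentityPct,
        minCoverageFrac = minCoverageFrac, completeOnly = completeOnly)
}
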