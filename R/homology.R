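#' @include AllClasses.R io.R
#' @import data.table
NULL

#' Best hit per query
#'
#' Reduces a one-direction hit table to the single best hit per query:
#' highest bitscore, ties broken by lowest e-value, then lexicographically
#' smallest subject id.
#'
#' @param hits hit `data.frame` (see [readHits()]).
#' @return hit `data.frame` with one row per distinct `qseqid`.
#' @export
bestHitPerQuery <- function(hits) {
    if (nrow(hits) == 0L) return(hits)
    ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(hits$qseqid), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Bidirectional best hits between two proteomes
#'
#' A pair (a, b) is kept when a's best hit in the other proteome is b and
#' b's best hit is a.
#'
#' @param bestAB best-hit table for the A-to-B search direction (one row per
#'   query; see [bestHitPerQuery()]).
#' @param bestBA best-hit table for the B-to-A direction.
#' @return `data.frame` with one row per BBH pair: `a_id`, `b_id`,
#'   `pident_ab`, `align_len_ab`, `bitscore_ab`, `pident_ba`,
#'   `align_len_ba`, `bitscore_ba`.
#' @export
bidirectionalBestHits <- function(bestAB, bestBA) {
    empty <- data.frame(a_id = character(), b_id = character(),
                        pident_ab = numeric(), align_len_ab = integer(),
                        bitscore_ab = numeric(), pident_ba = numeric(),
                        align_len_ba = integer(), bitscore_ba = numeric(),
                        stringsAsFactors = FALSE)
    if (nrow(bestAB) == 0L || nrow(bestBA) == 0L) return(empty)
    ab <- data.frame(a_id = bestAB$qseqid, b_id = bestAB$sseqid,
                     pident_ab = bestAB$pident, align_len_ab = bestAB$length,
                     bitscore_ab = bestAB$bitscore, stringsAsFactors = FALSE)
    ba <- data.frame(b_id = bestBA$qseqid, a_id = bestBA$sseqid,
                     pident_ba = bestBA$pident, align_len_ba = bestBA$length,
                     bitscore_ba = bestBA$bitscore, stringsAsFactors = FALSE)
    m <- merge(ab, ba, by = c("a_id", "b_id"))
    m <- m[order(m$a_id, m$b_id), , drop = FALSE]
    rownames(m) <- NULL
    m[, names(empty)]
}

#' Average amino acid identity between two proteomes
#'
#' AAI over bidirectional best-hit pairs passing the filters of
#' [AaiParams-class]: both members complete ORFs (when `completeOnly`), both
#' directional hits at or above the identity floor, and each direction's
#' alignment covering at least `minCoverageFrac` of both protein lengths.
#' The per-pair identity is the mean of the two directional percent
#' identities, and the AAI is the unweighted mean over kept pairs.
#'
#' @param bbh BBH table from [bidirectionalBestHits()].
#' @param orfsA,orfsB the two [OrfSet-class] proteomes.
#' @param params an [AaiParams-class].
#' @return list with `genome_a`, `genome_b`, `aai` (percent; `NaN` when no
#'   pair survives) and `n_pairs`.
#' @export
computeAai <- function(bbh, orfsA, orfsB, params = AaiParams()) {
    keep <- rep(TRUE, nrow(bbh))
    lenA <- orfLengths(orfsA)
    lenB <- orfLengths(orfsB)
    if (nrow(bbh) > 0L) {
        unknown <- !(bbh$a_id %in% names(lenA)) | !(bbh$b_id %in% names(lenB))
        if (any(unknown))
            stop("BBH ids not found in proteomes: ",
                 paste(unique(c(bbh$a_id[!(bbh$a_id %in% names(lenA))],
                                bbh$b_id[!(bbh$b_id %in% names(lenB))])),
                       collapse = ", "))
        if (params@completeOnly) {
            trA <- truncation(orfsA)[bbh$a_id]
            trB <- truncation(orfsB)[bbh$b_id]
            keep <- keep & trA == "NONE" & trB == "NONE"
        }
        keep <- keep & bbh$pident_ab >= params@minIdentityPct &
            bbh$pident_ba >= params@minIdentityPct
        la <- lenA[bbh$a_id]
        lb <- lenB[bbh$b_id]
        covOk <- function(alnLen)
            alnLen >= params@minCoverageFrac * la &
            alnLen >= params@minCoverageFrac * lb
        keep <- keep & covOk(bbh$align_len_ab) & covOk(bbh$align_len_ba)
    }
    kept <- bbh[keep, , drop = FALSE]
    aai <- if (nrow(kept) > 0L)
        mean((kept$pident_ab + kept$pident_ba) / 2) else NaN
    list(genome_a = genomeId(orfsA), genome_b = genomeId(orfsB),
         aai = aai, n_pairs = nrow(kept))
}

#' AAI distance matrix
#'
#' Builds a symmetric distance matrix from pairwise AAI values:
#' `distance(a, b) = 100 - mean(AAI values reported for the pair)`, so both
#' study directions inform the value when both are present; the diagonal
#' is 0.
#'
#' @param aaiTable `data.frame` with columns `genome_a`, `genome_b`, `aai`
#'   (one or two rows per unordered pair).
#' @return symmetric numeric matrix with zero diagonal, dimnames = genome
#'   ids (sorted).
#' @export
aaiMatrix <- function(aaiTable) {
    gids <- sort(unique(c(aaiTable$genome_a, aaiTable$genome_b)))
    n <- length(gids)
    dm <- matrix(0, n, n, dimnames = list(gids, gids))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    agg <- tapply(aaiTable$aai, key(aaiTable$genome_a, aaiTable$genome_b),
                  mean)
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
        k <- key(gids[i], gids[j])
        if (!k %in% names(agg) || is.na(agg[[k]]))
            stop("missing AAI for pair ", gids[i], " / ", gids[j])
        dm[i, j] <- dm[j, i] <- 100 - agg[[k]]
    }
    dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining on a symmetric distance matrix; negative branch
#' lengths are clamped to zero. The two-taxon case splits the distance into
#' two equal branches.
#'
#' @param dm symmetric numeric matrix with zero diagonal and dimnames.
#' @return newick string (single line, terminated by `;`).
#' @export
njTree <- function(dm) {
    dm <- as.matrix(dm)
    if (nrow(dm) < 2L) stop("need at least 2 taxa")
    if (is.null(rownames(dm))) stop("distance matrix must have dimnames")
    if (max(abs(dm - t(dm))) > 1e-8)
        stop("distance matrix is not symmetric")
    if (any(abs(diag(dm)) > 1e-12)) stop("diagonal must be zero")
    if (nrow(dm) == 2L) {
        d <- dm[1L, 2L] / 2
        return(sprintf("(%s:%g,%s:%g);", rownames(dm)[1L], d,
                       rownames(dm)[2L], d))
    }
    tr <- ape::nj(dm)
    tr$edge.length[tr$edge.length < 0] <- 0
    ape::write.tree(tr)
}

#' Local pairwise protein alignment
#'
#' Smith-Waterman local alignment under BLOSUM-style scoring with affine
#' gaps (a gap of length L costs `gapOpen + L * gapExtend`), reported as one
#' 12-column hit row. Percent identity is identities over alignment columns
#' (including gap columns); the bitscore column carries the raw alignment
#' score and is used only for ranking; the e-value column is set to 0.
#'
#' @param seqA,seqB amino-acid sequences (character or `AAString`).
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gapOpen,gapExtend gap penalties (defaults 11 and 1).
#' @param queryId,subjectId ids written into the hit row.
#' @return one-row hit `data.frame` (same columns as [readHits()]).
#' @export
alignPair <- function(seqA, seqB, matrix = "BLOSUM62", gapOpen = 11,
                      gapExtend = 1, queryId = "query", subjectId = "subject") {
    seqA <- as.character(seqA); seqB <- as.character(seqB)
    if (nchar(seqA) == 0L || nchar(seqB) == 0L)
        stop("cannot align an empty sequence")
    subMat <- getSubMatrix(matrix)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqA), Biostrings::AAString(seqB),
        type = "local", substitutionMatrix = subMat,
        gapOpening = gapOpen, gapExtension = gapExtend)
    nid <- Biostrings::nmatch(aln)
    nmis <- Biostrings::nmismatch(aln)
    indels <- Biostrings::nindel(aln)
    ins <- Biostrings::insertion(indels)
    del <- Biostrings::deletion(indels)
    alen <- nid + nmis + ins[1L, "WidthSum"] + del[1L, "WidthSum"]
    gapOpens <- ins[1L, "Length"] + del[1L, "Length"]
    data.frame(qseqid = queryId, sseqid = subjectId,
               pident = 100 * nid / alen,
               length = alen,
               mismatch = Biostrings::nmismatch(aln),
               gapopen = gapOpens,
               qstart = Biostrings::start(Biostrings::pattern(aln)),
               qend = Biostrings::end(Biostrings::pattern(aln)),
               sstart = Biostrings::start(Biostrings::subject(aln)),
               send = Biostrings::end(Biostrings::subject(aln)),
               evalue = 0, bitscore = Biostrings::score(aln),
               stringsAsFactors = FALSE)
}

subMatrixCache <- new.env(parent = emptyenv())

getSubMatrix <- function(name) {
    if (!exists(name, envir = subMatrixCache)) {
        e <- new.env()
        utils::data(list = name, package = "Biostrings", envir = e)
        assign(name, get(name, envir = e), envir = subMatrixCache)
    }
    get(name, envir = subMatrixCache)
}

#' All-vs-all hit table between two proteomes
#'
#' Generates a 12-column hit table by local alignment, shortlisting
#' candidate subject proteins through shared amino-acid words (exact k-mers)
#' before running [alignPair()] on each shortlisted pair. This keeps
#' self-contained fixtures free of any external search tool; when exactness
#' to an external aligner's statistics matters, supply its tabular output to
#' [readHits()] instead.
#'
#' @param query,subject [OrfSet-class] proteomes.
#' @param k word size for the shortlist (default 6).
#' @param minSharedKmers minimum number of shared words to shortlist a
#'   subject (default 1).
#' @param maxSubjectsPerQuery keep at most this many subjects per query,
#'   ranked by shared-word count (default 10).
#' @param queryIds optionally restrict to these query ORFs (e.g. fragments
#'   only).
#' @param ... passed to [alignPair()].
#' @return hit `data.frame`, rows ordered by query then descending bitscore.
#' @export
alignProteomes <- function(query, subject, k = 6L, minSharedKmers = 1L,
                           maxSubjectsPerQuery = 10L, queryIds = NULL, ...) {
    qtab <- orfTable(query)
    qseqs <- orfSequences(query)
    sseqs <- orfSequences(subject)
    if (!is.null(queryIds)) {
        keep <- qtab$orf_id %in% queryIds
        qtab <- qtab[keep, , drop = FALSE]
        qseqs <- qseqs[qtab$orf_id]
    }
    if (nrow(qtab) == 0L || length(sseqs) == 0L) return(emptyHitTable())
    sk <- kmerTable(sseqs, k)
    qk <- kmerTable(qseqs, k)
    shared <- merge(qk, sk, by = "kmer", allow.cartesian = TRUE)
    if (nrow(shared) == 0L) return(emptyHitTable())
    counts <- shared[, list(n_shared = .N), by = c("id.x", "id.y")]
    counts <- counts[counts$n_shared >= minSharedKmers]
    data.table::setorderv(counts, c("id.x", "n_shared", "id.y"),
                          c(1L, -1L, 1L))
    counts <- counts[, utils::head(.SD, maxSubjectsPerQuery), by = "id.x"]
    rows <- vector("list", nrow(counts))
    for (i in seq_len(nrow(counts))) {
        qi <- counts$id.x[i]; si <- counts$id.y[i]
        rows[[i]] <- alignPair(qseqs[[qi]], sseqs[[si]],
                               queryId = qi, subjectId = si, ...)
    }
    hits <- do.call(rbind, rows)
    hits <- hits[order(hits$qseqid, -hits$bitscore, hits$sseqid), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    hits
}

## one row per (sequence id, distinct k-mer)
kmerTable <- function(seqs, k) {
    ids <- names(seqs)
    ch <- as.character(seqs)
    res <- lapply(seq_along(ch), function(i) {
        s <- ch[[i]]
        n <- nchar(s)
        if (n < k) return(NULL)
        data.table::data.table(id = ids[i],
                               kmer = unique(substring(s, 1:(n - k + 1L),
                                                       k:n)))
    })
    data.table::rbindlist(res)
}
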