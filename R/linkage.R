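#' @include AllClasses.R homology.R
NULL

## closed-interval overlap in aa
intervalOverlap <- function(s1, e1, s2, e2)
    pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)

#' Candidate placements of fragments on complete reference homologs
#'
#' Filters a fragment-to-reference hit table down to admissible placements:
#' the subject must be a complete (non-truncated) reference ORF, percent
#' identity must reach `minIdentityPct`, and the alignment must cover at
#' least `minOverlapFrac` of the fragment (or of the reference, under
#' `overlapMode = "reference"`). One placement is kept per
#' (fragment, reference) pair: the highest-bitscore hit.
#'
#' @param fragments [OrfSet-class] of the genome whose partial ORFs are to
#'   be linked; only ORFs with truncation other than `NONE` are considered.
#' @param hits hit table in the fragment-to-reference direction.
#' @param referenceOrfs [OrfSet-class] of the reference proteome.
#' @param params a [LinkageParams-class].
#' @return `data.frame` with columns `fragment_id`, `reference_protein_id`,
#'   `reference_genome_id`, `pident`, `s_start`, `s_end`, `frag_coverage`,
#'   `bitscore`, `truncation`.
#' @export
candidatePlacements <- function(fragments, hits, referenceOrfs,
                                params = LinkageParams()) {
    empty <- data.frame(fragment_id = character(),
                        reference_protein_id = character(),
                        reference_genome_id = character(),
                        pident = numeric(), s_start = integer(),
                        s_end = integer(), frag_coverage = numeric(),
                        bitscore = numeric(), truncation = character(),
                        stringsAsFactors = FALSE)
    if (nrow(hits) == 0L) return(empty)
    fragTrunc <- truncation(fragments)
    fragLen <- orfLengths(fragments)
    refTrunc <- truncation(referenceOrfs)
    refLen <- orfLengths(referenceOrfs)
    h <- hits[hits$qseqid %in% names(fragTrunc) &
              hits$sseqid %in% names(refTrunc), , drop = FALSE]
    if (nrow(h) == 0L) return(empty)
    h <- h[fragTrunc[h$qseqid] != "NONE", , drop = FALSE]
    h <- h[refTrunc[h$sseqid] == "NONE", , drop = FALSE]
    if (nrow(h) == 0L) return(empty)
    fragCov <- (h$qend - h$qstart + 1L) / fragLen[h$qseqid]
    refCov <- (h$send - h$sstart + 1L) / refLen[h$sseqid]
    cov <- if (params@overlapMode == "fragment") fragCov else refCov
    keep <- h$pident >= params@minIdentityPct & cov >= params@minOverlapFrac
    h <- h[keep, , drop = FALSE]
    fragCov <- fragCov[keep]
    if (nrow(h) == 0L) return(empty)
    ## best hit per (fragment, reference) pair
    ord <- order(h$qseqid, h$sseqid, -h$bitscore, h$evalue, h$sstart)
    h <- h[ord, , drop = FALSE]
    fragCov <- fragCov[ord]
    first <- !duplicated(paste(h$qseqid, h$sseqid, sep = "\r"))
    h <- h[first, , drop = FALSE]
    data.frame(fragment_id = h$qseqid,
               reference_protein_id = h$sseqid,
               reference_genome_id = genomeId(referenceOrfs),
               pident = h$pident,
               s_start = h$sstart, s_end = h$send,
               frag_coverage = fragCov[first],
               bitscore = h$bitscore,
               truncation = unname(fragTrunc[h$qseqid]),
               stringsAsFactors = FALSE)
}

## end-order rule: a 3'-truncated member carries the start and must be the
## leftmost interval on the reference; a 5'-truncated member carries the
## stop and must be rightmost; internal (BOTH) pieces may sit anywhere.
endOrderOk <- function(sStart, sEnd, trunc) {
    ord <- order(sStart, sEnd)
    trunc <- trunc[ord]
    n <- length(trunc)
    i3 <- which(trunc == "THREE_PRIME")
    i5 <- which(trunc == "FIVE_PRIME")
    if (length(i3) > 1L || length(i5) > 1L) return(FALSE)
    if (length(i3) == 1L && i3 != 1L) return(FALSE)
    if (length(i5) == 1L && i5 != n) return(FALSE)
    TRUE
}

#' Assemble fragment sets anchored on one reference protein
#'
#' Greedy deterministic assembly of placements that share one complete
#' reference homolog. Placements are sorted by descending identity (ties by
#' ascending fragment id); the top unused placement seeds a set, and each
#' subsequent unused placement joins when (a) its reference interval
#' overlaps every current member by at most `maxFragmentOverlapAa`, (b) its
#' identity is within `maxIdentitySpreadPct` of the seed's, (c) the set
#' keeps at most `maxSingleEndTruncated` single-end-truncated members, and
#' (d) under `enforceEndOrder` the start-bearing and stop-bearing members
#' remain at the reference ends. Sets with at least two members are emitted;
#' seeding repeats until placements are exhausted.
#'
#' @param placements placements on one reference protein (see
#'   [candidatePlacements()]).
#' @param params a [LinkageParams-class].
#' @param genomeId genome the fragments belong to.
#' @param idPrefix prefix for generated set ids.
#' @return long-format member `data.frame` (columns of
#'   [FragmentSets-class]), possibly empty.
#' @export
assembleSetsForReference <- function(placements, params = LinkageParams(),
                                     genomeId = "genome",
                                     idPrefix = "set") {
    if (nrow(placements) == 0L) return(emptyFragmentTable())
    refp <- unique(placements$reference_protein_id)
    if (length(refp) != 1L)
        stop("placements must share a single reference protein")
    pl <- placements[order(-placements$pident, placements$fragment_id), ,
                     drop = FALSE]
    used <- rep(FALSE, nrow(pl))
    out <- list()
    counter <- 0L
    repeat {
        seedIdx <- which(!used)[1L]
        if (is.na(seedIdx)) break
        members <- seedIdx
        used[seedIdx] <- TRUE
        seedPident <- pl$pident[seedIdx]
        for (i in which(!used)) {
            cand <- c(members, i)
            if (abs(pl$pident[i] - seedPident) > params@maxIdentitySpreadPct)
                next
            ov <- intervalOverlap(pl$s_start[members], pl$s_end[members],
                                  pl$s_start[i], pl$s_end[i])
            if (any(ov > params@maxFragmentOverlapAa)) next
            nSingle <- sum(pl$truncation[cand] %in%
                           c("FIVE_PRIME", "THREE_PRIME"))
            if (nSingle > params@maxSingleEndTruncated) next
            if (params@enforceEndOrder &&
                !endOrderOk(pl$s_start[cand], pl$s_end[cand],
                            pl$truncation[cand]))
                next
            members <- cand
            used[i] <- TRUE
        }
        if (length(members) >= 2L) {
            counter <- counter + 1L
            mm <- pl[members, , drop = FALSE]
            mm <- mm[order(mm$s_start, mm$s_end), , drop = FALSE]
            out[[counter]] <- data.frame(
                set_id = sprintf("%s|%s|%s|%d", idPrefix,
                                 mm$reference_genome_id[1L], refp, counter),
                genome_id = genomeId,
                fragment_id = mm$fragment_id,
                member_rank = seq_len(nrow(mm)),
                identity = mm$pident,
                ref_start = mm$s_start, ref_end = mm$s_end,
                reference_protein_id = refp,
                reference_genome_id = mm$reference_genome_id[1L],
                mean_identity = mean(mm$pident),
                stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L) return(emptyFragmentTable())
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

assembleAllReferences <- function(placements, params, genomeId,
                                  idPrefix = "set") {
    if (nrow(placements) == 0L) return(emptyFragmentTable())
    parts <- split(placements, placements$reference_protein_id)
    parts <- parts[order(names(parts))]
    res <- lapply(names(parts), function(rp)
        assembleSetsForReference(parts[[rp]], params, genomeId,
                                 idPrefix = idPrefix))
    res <- do.call(rbind, res)
    if (is.null(res)) return(emptyFragmentTable())
    rownames(res) <- NULL
    res
}

#' Resolve conflicts among candidate fragment sets
#'
#' Two candidate sets conflict when they share at least one fragment. Among
#' conflicting sets the one with the higher mean identity to its reference
#' survives; ties are broken by larger member count, then lexicographic
#' (reference genome, reference protein, set id). Resolution is global over
#' all candidates, so the outcome is independent of input order.
#'
#' @param candidates a [FragmentSets-class] or long-format member table of
#'   candidate sets (may share fragments).
#' @return conflict-free [FragmentSets-class].
#' @export
resolveConflicts <- function(candidates) {
    tb <- if (is(candidates, "FragmentSets")) setTable(candidates)
          else candidates
    if (nrow(tb) == 0L) return(FragmentSets())
    info <- do.call(rbind, lapply(split(tb, tb$set_id), function(s)
        data.frame(set_id = s$set_id[1L], mean_identity = s$mean_identity[1L],
                   n_members = nrow(s),
                   reference_genome_id = s$reference_genome_id[1L],
                   reference_protein_id = s$reference_protein_id[1L],
                   stringsAsFactors = FALSE)))
    info <- info[order(-info$mean_identity, -info$n_members,
                       info$reference_genome_id, info$reference_protein_id,
                       info$set_id), , drop = FALSE]
    taken <- character(0)
    keep <- character(0)
    members <- split(tb$fragment_id, tb$set_id)
    for (sid in info$set_id) {
        frs <- members[[sid]]
        if (!any(frs %in% taken)) {
            keep <- c(keep, sid)
            taken <- c(taken, frs)
        }
    }
    res <- tb[tb$set_id %in% keep, , drop = FALSE]
    res <- res[order(res$set_id, res$member_rank), , drop = FALSE]
    rownames(res) <- NULL
    FragmentSets(res)
}

#' Link fragments between two genomes, reciprocally
#'
#' Runs [candidatePlacements()] and [assembleSetsForReference()] in both
#' directions: complete homologs in genome B anchor fragment sets in genome
#' A, and vice versa. Within each genome, conflicts are resolved by
#' [resolveConflicts()] so every fragment belongs to at most one set.
#'
#' @param orfsA,orfsB [OrfSet-class] proteomes with truncation states.
#' @param hitsAB hit table, A-proteins as queries against B.
#' @param hitsBA hit table, B-proteins as queries against A.
#' @param params a [LinkageParams-class].
#' @return list with elements `sets_a` and `sets_b`
#'   ([FragmentSets-class] each).
#' @export
linkFragments <- function(orfsA, orfsB, hitsAB, hitsBA,
                          params = LinkageParams()) {
    if (identical(genomeId(orfsA), genomeId(orfsB)))
        stop("genome id collision: both proteomes are ",
             sQuote(genomeId(orfsA)))
    plA <- candidatePlacements(orfsA, hitsAB, orfsB, params)
    plB <- candidatePlacements(orfsB, hitsBA, orfsA, params)
    setsA <- assembleAllReferences(plA, params, genomeId(orfsA),
                                   idPrefix = genomeId(orfsA))
    setsB <- assembleAllReferences(plB, params, genomeId(orfsB),
                                   idPrefix = genomeId(orfsB))
    list(sets_a = resolveConflicts(setsA), sets_b = resolveConflicts(setsB))
}

#' Link a target genome's fragments against multiple references
#'
#' Accumulates candidate fragment sets for one target genome across several
#' reference proteomes (typically ordered by decreasing AAI), applying
#' global conflict resolution after each reference: an existing set is
#' rejected and replaced when a later reference offers an alternative set
#' with a higher mean identity between the fragments and their complete
#' homolog. Per-reference newly-linked fragment counts and the cumulative
#' count are reported for relatedness-versus-linkage curves.
#'
#' @param target [OrfSet-class] whose fragments are linked.
#' @param references list of reference [OrfSet-class] proteomes, in
#'   caller-chosen order.
#' @param hitTables list of hit tables (target proteins as queries against
#'   each reference), parallel to `references`; when `NULL`, tables are
#'   computed with [alignProteomes()] restricted to the target's fragments.
#' @param params a [LinkageParams-class].
#' @return list with `sets` (final [FragmentSets-class]) and
#'   `contributions` (`data.frame` with `reference_genome_id`,
#'   `n_new_fragments`, `n_cumulative`).
#' @export
linkAgainstReferences <- function(target, references, hitTables = NULL,
                                  params = LinkageParams()) {
    if (length(references) == 0L) stop("need at least one reference")
    refIds <- vapply(references, genomeId, "")
    if (genomeId(target) %in% refIds)
        stop("genome id collision: target ", sQuote(genomeId(target)),
             " also appears among references")
    if (anyDuplicated(refIds))
        stop("duplicated reference genome ids")
    fragIds <- names(which(isPartial(target)))
    accepted <- emptyFragmentTable()
    contributions <- data.frame(reference_genome_id = character(),
                                n_new_fragments = integer(),
                                n_cumulative = integer(),
                                stringsAsFactors = FALSE)
    prevLinked <- 0L
    for (i in seq_along(references)) {
        ref <- references[[i]]
        hits <- if (is.null(hitTables))
            alignProteomes(target, ref, queryIds = fragIds)
        else hitTables[[i]]
        pl <- candidatePlacements(target, hits, ref, params)
        cand <- assembleAllReferences(pl, params, genomeId(target),
                                      idPrefix = genomeId(target))
        accepted <- setTable(resolveConflicts(rbind(accepted, cand)))
        nLinked <- length(unique(accepted$fragment_id))
        contributions <- rbind(contributions, data.frame(
            reference_genome_id = genomeId(ref),
            n_new_fragments = nLinked - prevLinked,
            n_cumulative = nLinked, stringsAsFactors = FALSE))
        prevLinked <- nLinked
    }
    list(sets = FragmentSets(accepted), contributions = contributions)
}

#' Merge linked fragments into a corrected ORF inventory
#'
#' Each fragment set collapses into one merged unit carrying its members'
#' ids; unlinked ORFs pass through unchanged, so the corrected inventory has
#' `n_orfs - sum(set size - 1)` units.
#'
#' @param orfs [OrfSet-class] inventory.
#' @param sets conflict-free [FragmentSets-class].
#' @return `data.frame` with columns `unit_id`, `member_ids`
#'   (comma-separated), `n_members`.
#' @export
mergeInventory <- function(orfs, sets) {
    tb <- setTable(sets)
    ids <- orfTable(orfs)$orf_id
    if (nrow(tb) > 0L) {
        if (anyDuplicated(tb$fragment_id))
            stop("overlapping sets: fragment ",
                 tb$fragment_id[duplicated(tb$fragment_id)][1L],
                 " appears in more than one set")
        unknown <- setdiff(tb$fragment_id, ids)
        if (length(unknown))
            stop("set members missing from inventory: ",
                 paste(unknown, collapse = ", "))
    }
    linked <- unique(tb$fragment_id)
    solo <- setdiff(ids, linked)
    merged <- if (nrow(tb) > 0L) {
        do.call(rbind, lapply(split(tb, tb$set_id), function(s) {
            s <- s[order(s$member_rank), , drop = FALSE]
            data.frame(unit_id = s$set_id[1L],
                       member_ids = paste(s$fragment_id, collapse = ","),
                       n_members = nrow(s), stringsAsFactors = FALSE)
        }))
    } else NULL
    res <- rbind(data.frame(unit_id = solo, member_ids = solo,
                            n_members = 1L, stringsAsFactors = FALSE),
                 merged)
    rownames(res) <- NULL
    res
}
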