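#' @include AllClasses.R linkage.R
NULL

## which contig edges an ORF's truncation touches, given its strand
touchedEdges <- function(truncation, strand) {
    list(left = truncation == "BOTH" |
             (truncation == "FIVE_PRIME" & strand == 1L) |
             (truncation == "THREE_PRIME" & strand == -1L),
         right = truncation == "BOTH" |
             (truncation == "THREE_PRIME" & strand == 1L) |
             (truncation == "FIVE_PRIME" & strand == -1L))
}

#' Classify a linked fragment pair against scaffold adjacency
#'
#' A linked pair is congruent with the scaffold (`"TRUE"`) when the two
#' fragments lie on distinct contigs that are consecutive within one
#' scaffold and, under the default strict mode, each fragment's truncated
#' side faces the inter-contig gap once contig orientation is applied.
#' `"FALSE"` is returned when both contigs are scaffold-placed but the
#' condition fails; `"UNKNOWN"` when either contig is unplaced or no
#' scaffold data exists.
#'
#' @param fragId1,fragId2 fragment ORF ids from the same genome.
#' @param orfs the genome's [OrfSet-class].
#' @param scaffolds a [ScaffoldMap-class], or `NULL` when the genome has no
#'   scaffold information.
#' @param mode `"strict"` (rank adjacency + gap-facing truncated ends) or
#'   `"adjacency"` (rank adjacency only).
#' @return one of `"TRUE"`, `"FALSE"`, `"UNKNOWN"`.
#' @export
classifyPair <- function(fragId1, fragId2, orfs,
                         scaffolds = NULL,
                         mode = c("strict", "adjacency")) {
    mode <- match.arg(mode)
    if (is.null(scaffolds)) return("UNKNOWN")
    stb <- scaffoldTable(scaffolds)
    if (nrow(stb) == 0L) return("UNKNOWN")
    otb <- orfTable(orfs)
    i1 <- match(fragId1, otb$orf_id)
    i2 <- match(fragId2, otb$orf_id)
    if (is.na(i1) || is.na(i2))
        stop("fragment not found in ORF set: ",
             if (is.na(i1)) fragId1 else fragId2)
    c1 <- otb$contig_id[i1]; c2 <- otb$contig_id[i2]
    p1 <- match(c1, stb$contig_id)
    p2 <- match(c2, stb$contig_id)
    if (is.na(p1) || is.na(p2)) return("UNKNOWN")
    if (c1 == c2) return("FALSE")
    if (stb$scaffold_id[p1] != stb$scaffold_id[p2]) return("FALSE")
    if (abs(stb$rank[p1] - stb$rank[p2]) != 1L) return("FALSE")
    if (mode == "adjacency") return("TRUE")
    ## order the pair left-to-right along the scaffold
    if (stb$rank[p1] > stb$rank[p2]) {
        tmp <- p1; p1 <- p2; p2 <- tmp
        tmp <- i1; i1 <- i2; i2 <- tmp
    }
    edges1 <- touchedEdges(otb$truncation[i1], otb$strand[i1])
    edges2 <- touchedEdges(otb$truncation[i2], otb$strand[i2])
    ## gap-facing end of the left contig is its scaffold-right side
    leftOk <- if (stb$orientation[p1] == "+") edges1$right else edges1$left
    rightOk <- if (stb$orientation[p2] == "+") edges2$left else edges2$right
    if (leftOk && rightOk) "TRUE" else "FALSE"
}

#' Validate fragment sets against scaffold information
#'
#' Classifies every consecutive member pair of every set with
#' [classifyPair()] and aggregates at the fragment level: a fragment counts
#' as truly linked when every pair it participates in is scaffold-congruent,
#' falsely linked when any pair is incongruent, and unknown otherwise.
#' Percentages use the genome's partial-ORF total as denominator and are
#' rounded half-up to one decimal.
#'
#' @param sets conflict-free [FragmentSets-class].
#' @param orfs the genome's [OrfSet-class].
#' @param scaffolds [ScaffoldMap-class] or `NULL`.
#' @param partialTotal total number of partial ORFs in the genome.
#' @param mode passed to [classifyPair()].
#' @return list with `genome_id`, `n_linked_fragments`, `n_true`, `n_false`,
#'   `n_unknown`, `pct_true_of_partial`, `pct_false_of_partial`.
#' @export
evaluateSets <- function(sets, orfs, scaffolds, partialTotal,
                         mode = c("strict", "adjacency")) {
    mode <- match.arg(mode)
    tb <- setTable(sets)
    if (nrow(tb) > 0L && partialTotal == 0L)
        stop("partialTotal is 0 but fragment sets are non-empty")
    status <- character(0)
    if (nrow(tb) > 0L) {
        if (anyDuplicated(tb$fragment_id))
            stop("sets are not conflict-free")
        fragStatus <- new.env(parent = emptyenv())
        for (s in split(tb, tb$set_id)) {
            s <- s[order(s$member_rank), , drop = FALSE]
            pairCls <- vapply(seq_len(nrow(s) - 1L), function(j)
                classifyPair(s$fragment_id[j], s$fragment_id[j + 1L],
                             orfs, scaffolds, mode), "")
            for (j in seq_len(nrow(s))) {
                own <- pairCls[intersect(c(j - 1L, j), seq_along(pairCls))]
                st <- if (any(own == "FALSE")) "FALSE"
                      else if (all(own == "TRUE")) "TRUE"
                      else "UNKNOWN"
                assign(s$fragment_id[j], st, envir = fragStatus)
            }
        }
        status <- unlist(mget(ls(fragStatus), envir = fragStatus))
    }
    nTrue <- sum(status == "TRUE")
    nFalse <- sum(status == "FALSE")
    nUnknown <- sum(status == "UNKNOWN")
    list(genome_id = genomeId(orfs),
         n_linked_fragments = length(status),
         n_true = nTrue, n_false = nFalse, n_unknown = nUnknown,
         pct_true_of_partial =
             if (partialTotal > 0L) roundHalfUp(100 * nTrue / partialTotal)
             else NaN,
         pct_false_of_partial =
             if (partialTotal > 0L) roundHalfUp(100 * nFalse / partialTotal)
             else NaN)
}

#' Threshold grid search over the linkage pipeline
#'
#' Runs the full linkage plus scaffold validation for every combination of
#' identity, overlap and identity-spread thresholds, producing one row per
#' grid point for sensitivity/specificity surfaces.
#'
#' @param target [OrfSet-class] whose fragments are linked.
#' @param references list of reference [OrfSet-class] proteomes.
#' @param hitTables list of precomputed hit tables parallel to
#'   `references`, or `NULL` to compute them (see
#'   [linkAgainstReferences()]).
#' @param scaffolds [ScaffoldMap-class] (ground truth) or `NULL`.
#' @param identityGrid,overlapGrid,spreadGrid numeric vectors of threshold
#'   values to sweep.
#' @param baseParams [LinkageParams-class] supplying the remaining
#'   parameters.
#' @param mode passed to [evaluateSets()].
#' @return `data.frame` with one row per grid point: the three swept
#'   thresholds, `n_linked`, `n_true`, `n_false`, `true_fraction`.
#' @export
gridSearch <- function(target, references, hitTables = NULL, scaffolds = NULL,
                       identityGrid, overlapGrid, spreadGrid,
                       baseParams = LinkageParams(),
                       mode = c("strict", "adjacency")) {
    mode <- match.arg(mode)
    if (length(identityGrid) == 0L || length(overlapGrid) == 0L ||
        length(spreadGrid) == 0L)
        stop("grids must be non-empty")
    if (is.null(hitTables)) {
        fragIds <- names(which(isPartial(target)))
        hitTables <- lapply(references, function(ref)
            alignProteomes(target, ref, queryIds = fragIds))
    }
    partialTotal <- sum(isPartial(target))
    combos <- expand.grid(min_identity_pct = identityGrid,
                          min_overlap_frac = overlapGrid,
                          max_identity_spread_pct = spreadGrid,
                          KEEP.OUT.ATTRS = FALSE)
    rows <- lapply(seq_len(nrow(combos)), function(i) {
        params <- LinkageParams(
            minIdentityPct = combos$min_identity_pct[i],
            minOverlapFrac = combos$min_overlap_frac[i],
            maxIdentitySpreadPct = combos$max_identity_spread_pct[i],
            maxFragmentOverlapAa = baseParams@maxFragmentOverlapAa,
            maxSingleEndTruncated = baseParams@maxSingleEndTruncated,
            enforceEndOrder = baseParams@enforceEndOrder,
            overlapMode = baseParams@overlapMode)
        res <- linkAgainstReferences(target, references, hitTables, params)
        ev <- evaluateSets(res$sets, target, scaffolds, partialTotal, mode)
        data.frame(combos[i, , drop = FALSE],
                   n_linked = ev$n_linked_fragments,
                   n_true = ev$n_true, n_false = ev$n_false,
                   true_fraction = if (ev$n_linked_fragments > 0L)
                       ev$n_true / ev$n_linked_fragments else NaN,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
}
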