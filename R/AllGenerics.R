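#' @include AllClasses.R
NULL

#' Accessors for fragLink objects
#'
#' `genomeId` returns the genome identifier; `orfTable` the ORF coordinate
#' table; `orfSequences` the amino-acid sequences; `orfLengths` per-ORF
#' lengths in aa; `truncation` the per-ORF truncation state; `isPartial` a
#' logical marking ORF fragments; `scaffoldTable` and `setTable` the
#' underlying data frames; `nSets` the number of fragment sets; `linkedIds`
#' the identifiers of all linked fragments.
#'
#' @param x an [OrfSet-class], [Assembly-class], [ScaffoldMap-class] or
#'   [FragmentSets-class] object, as applicable.
#' @return see the per-accessor descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname accessors
#' @export
setMethod("genomeId", "OrfSet", function(x) x@genomeId)

#' @rdname accessors
#' @export
setMethod("genomeId", "Assembly", function(x) x@genomeId)

#' @rdname accessors
#' @export
setGeneric("orfTable", function(x) standardGeneric("orfTable"))

#' @rdname accessors
#' @export
setMethod("orfTable", "OrfSet", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("orfSequences", function(x) standardGeneric("orfSequences"))

#' @rdname accessors
#' @export
setMethod("orfSequences", "OrfSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("orfLengths", function(x) standardGeneric("orfLengths"))

#' @rdname accessors
#' @export
setMethod("orfLengths", "OrfSet", function(x) {
    w <- Biostrings::width(x@sequences)
    names(w) <- x@table$orf_id
    w
})

#' @rdname accessors
#' @export
setGeneric("truncation", function(x) standardGeneric("truncation"))

#' @rdname accessors
#' @export
setMethod("truncation", "OrfSet", function(x) {
    tr <- x@table$truncation
    names(tr) <- x@table$orf_id
    tr
})

#' @rdname accessors
#' @export
setGeneric("isPartial", function(x) standardGeneric("isPartial"))

#' @rdname accessors
#' @export
setMethod("isPartial", "OrfSet", function(x) {
    p <- x@table$truncation != "NONE"
    names(p) <- x@table$orf_id
    p
})

#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname accessors
#' @export
setMethod("contigs", "Assembly", function(x) x@contigs)

#' @rdname accessors
#' @export
setGeneric("scaffoldTable", function(x) standardGeneric("scaffoldTable"))

#' @rdname accessors
#' @export
setMethod("scaffoldTable", "ScaffoldMap", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("setTable", function(x) standardGeneric("setTable"))

#' @rdname accessors
#' @export
setMethod("setTable", "FragmentSets", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))

#' @rdname accessors
#' @export
setMethod("nSets", "FragmentSets", function(x)
    length(unique(x@table$set_id)))

#' @rdname accessors
#' @export
setGeneric("linkedIds", function(x) standardGeneric("linkedIds"))

#' @rdname accessors
#' @export
setMethod("linkedIds", "FragmentSets", function(x)
    unique(x@table$fragment_id))

setMethod("show", "OrfSet", function(object) {
    tb <- object@table
    cat("OrfSet for genome", sQuote(object@genomeId), "with",
        nrow(tb), "ORFs (", sum(tb$truncation != "NONE"), "partial )\n")
})

setMethod("show", "Assembly", function(object) {
    cat("Assembly", sQuote(object@genomeId), "with",
        length(object@contigs), "contigs,",
        sum(Biostrings::width(object@contigs)), "bp\n")
})

setMethod("show", "ScaffoldMap", function(object) {
    cat("ScaffoldMap:", length(unique(object@table$scaffold_id)),
        "scaffolds covering", nrow(object@table), "contigs\n")
})

setMethod("show", "FragmentSets", function(object) {
    cat("FragmentSets:", nSets(object), "sets over",
        nrow(object@table), "fragments\n")
})

setMethod("show", "LinkageParams", function(object) {
    cat("LinkageParams: identity >=", object@minIdentityPct,
        "%, overlap >=", object@minOverlapFrac,
        "(", object@overlapMode, "), spread <=",
        object@maxIdentitySpreadPct, "%, member overlap <=",
        object@maxFragmentOverlapAa, "aa, single-end budget",
        object@maxSingleEndTruncated,
        if (object@enforceEndOrder) ", end order enforced" else "", "\n")
})

setMethod("show", "AaiParams", function(object) {
    cat("AaiParams: identity >=", object@minIdentityPct,
        "%, coverage >=", object@minCoverageFrac, "of both lengths",
        if (object@completeOnly) ", complete ORFs only" else "", "\n")
})
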