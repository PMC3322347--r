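#' @include AllClasses.R linkage.R
NULL

#' Fraction of ORFs with at least one annotation term
#'
#' @param table annotation `data.frame` with columns `orf_id`, `term` (see
#'   [readAnnotations()]). Terms for ids absent from `orfs` raise a warning
#'   and are ignored.
#' @param orfs [OrfSet-class] inventory.
#' @return percent of ORFs with at least one term (full precision).
#' @export
annotationRate <- function(table, orfs) {
    ids <- orfTable(orfs)$orf_id
    if (length(ids) == 0L) stop("annotation rate undefined for zero ORFs")
    unknown <- setdiff(unique(table$orf_id), ids)
    if (length(unknown))
        warning("annotation terms for unknown ORFs ignored: ",
                paste(utils::head(unknown, 5L), collapse = ", "),
                if (length(unknown) > 5L) ", ...")
    annotated <- intersect(unique(table$orf_id), ids)
    100 * length(annotated) / length(ids)
}

#' Annotation rate after fragment-set correction
#'
#' Applies [mergeInventory()] and counts a merged unit as annotated when any
#' of its member fragments carries a term, so a gene whose fragments were
#' each annotated contributes once instead of several times. This is the
#' mechanism by which linkage compensates for over-annotation of fragmented
#' genes.
#'
#' @inheritParams annotationRate
#' @param sets conflict-free [FragmentSets-class].
#' @return percent of corrected inventory units with at least one term.
#' @export
correctedAnnotationRate <- function(table, orfs, sets) {
    inv <- mergeInventory(orfs, sets)
    annotatedIds <- intersect(unique(table$orf_id), orfTable(orfs)$orf_id)
    memberLists <- strsplit(inv$member_ids, ",", fixed = TRUE)
    unitAnnotated <- vapply(memberLists, function(m)
        any(m %in% annotatedIds), logical(1))
    100 * sum(unitAnnotated) / nrow(inv)
}

#' Pearson correlation with two-sided t-test
#'
#' Standard Pearson product-moment correlation; the two-sided p-value comes
#' from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y equal-length numeric vectors (length >= 3, both with non-zero
#'   variance).
#' @return list with `r`, `p_value`, `n`.
#' @export
pearsonCor <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need at least 3 observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance in x or y")
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Annotation category profile of partial versus complete ORFs
#'
#' Pools annotation counts across genomes separately for partial and
#' complete ORFs and expresses, for each category (e.g. COG superfamily),
#' the percentage of that ORF class's annotated members carrying the
#' category. Pooling (rather than averaging per-genome percentages) keeps
#' genomes with few fragments from dominating through unstable percentages.
#' Terms missing from the category map are grouped as `"unclassified"` with
#' a warning.
#'
#' @param tables list of annotation `data.frame`s, one per genome.
#' @param orfSets list of [OrfSet-class] objects, parallel to `tables`.
#' @param categoryMap `data.frame` with columns `term`, `category`.
#' @return list with `profile` (`data.frame`: `category`,
#'   `pct_of_complete_orfs`, `pct_of_partial_orfs`), `n_annotated_complete`,
#'   `n_annotated_partial`, and `per_genome` (long `data.frame` of per-genome
#'   counts for inspection). Partial percentages are `NaN` (flagged) when no
#'   partial ORF is annotated.
#' @export
categoryProfile <- function(tables, orfSets, categoryMap) {
    stopifnot(length(tables) == length(orfSets))
    catOf <- function(terms) {
        i <- match(terms, categoryMap$term)
        if (anyNA(i))
            warning("terms without category grouped as 'unclassified': ",
                    paste(utils::head(unique(terms[is.na(i)]), 5L),
                          collapse = ", "))
        ifelse(is.na(i), "unclassified", categoryMap$category[i])
    }
    perGenome <- list()
    for (g in seq_along(tables)) {
        tab <- tables[[g]]
        orfs <- orfSets[[g]]
        partial <- isPartial(orfs)
        tab <- tab[tab$orf_id %in% names(partial), , drop = FALSE]
        if (nrow(tab) == 0L) next
        tab$category <- catOf(tab$term)
        tab$class <- ifelse(partial[tab$orf_id], "partial", "complete")
        ## one count per (ORF, category): an ORF carries a category or not
        tab <- unique(tab[, c("orf_id", "category", "class")])
        agg <- stats::aggregate(orf_id ~ category + class, tab, length)
        names(agg)[3L] <- "n_orfs"
        agg$genome_id <- genomeId(orfs)
        nAnn <- tapply(tab$orf_id, tab$class,
                       function(v) length(unique(v)))
        agg$n_annotated_in_class <- as.integer(nAnn[agg$class])
        perGenome[[length(perGenome) + 1L]] <- agg
    }
    pg <- if (length(perGenome)) do.call(rbind, perGenome) else
        data.frame(category = character(), class = character(),
                   n_orfs = integer(), genome_id = character(),
                   n_annotated_in_class = integer())
    pooledClass <- function(cls) {
        sub <- pg[pg$class == cls, , drop = FALSE]
        denom <- sum(tapply(sub$n_annotated_in_class,
                            sub$genome_id, function(v) v[1L]))
        counts <- tapply(sub$n_orfs, sub$category, sum)
        list(denom = if (length(denom) == 0L || is.na(denom)) 0L else denom,
             counts = counts)
    }
    comp <- pooledClass("complete")
    part <- pooledClass("partial")
    cats <- sort(unique(c(names(comp$counts), names(part$counts))))
    pct <- function(side, cat) {
        n <- side$counts[cat]
        n <- if (is.na(n)) 0 else n
        if (side$denom > 0L) 100 * n / side$denom else NaN
    }
    profile <- data.frame(
        category = cats,
        pct_of_complete_orfs = vapply(cats, function(ct) pct(comp, ct), 0),
        pct_of_partial_orfs = vapply(cats, function(ct) pct(part, ct), 0),
        stringsAsFactors = FALSE)
    rownames(profile) <- NULL
    list(profile = profile,
         n_annotated_complete = comp$denom,
         n_annotated_partial = part$denom,
         per_genome = pg)
}

#' Genome quality versus annotation rate correlations
#'
#' Correlates two genome-quality proxies (percent partial ORFs and mean ORF
#' length) with per-genome annotation rates, before and after fragment-set
#' correction, optionally repeating each correlation with one genome left
#' out (to probe the influence of outlier assemblies).
#'
#' @param stats `data.frame` of per-genome quality metrics (needs columns
#'   `genome_id`, `pct_partial`, `mean_orf_length_aa`; see
#'   [genomeReport()]).
#' @param rates numeric vector of uncorrected annotation rates, parallel to
#'   `stats` rows.
#' @param correctedRates corrected rates, parallel to `stats` rows, or
#'   `NULL` to skip the corrected block.
#' @param excludeGenome optional genome id to leave out in an additional
#'   block of rows.
#' @return `data.frame` with columns `block`, `quality_metric`, `r`,
#'   `p_value`, `n`.
#' @export
qualityVsAnnotationReport <- function(stats, rates, correctedRates = NULL,
                                      excludeGenome = NULL) {
    if (nrow(stats) < 3L) stop("need at least 3 genomes")
    if (length(rates) != nrow(stats))
        stop("rates must be parallel to stats rows")
    oneBlock <- function(label, keep, yRates) {
        rows <- lapply(c(pct_partial = "pct_partial",
                         mean_orf_length = "mean_orf_length_aa"),
                       function(col) {
            res <- tryCatch(pearsonCor(stats[[col]][keep], yRates[keep]),
                            error = function(e)
                                list(r = NA_real_, p_value = NA_real_,
                                     n = sum(keep)))
            data.frame(block = label, quality_metric = col, r = res$r,
                       p_value = res$p_value, n = res$n,
                       stringsAsFactors = FALSE)
        })
        do.call(rbind, rows)
    }
    all <- rep(TRUE, nrow(stats))
    out <- oneBlock("uncorrected", all, rates)
    if (!is.null(correctedRates))
        out <- rbind(out, oneBlock("corrected", all, correctedRates))
    if (!is.null(excludeGenome)) {
        keep <- stats$genome_id != excludeGenome
        out <- rbind(out, oneBlock("uncorrected_excluding", keep, rates))
        if (!is.null(correctedRates))
            out <- rbind(out,
                         oneBlock("corrected_excluding", keep, correctedRates))
    }
    rownames(out) <- NULL
    out
}
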