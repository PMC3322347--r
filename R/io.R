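#' @include AllClasses.R
NULL

## Edge flags are genomic (left/right edge of the contig); truncation is
## strand-relative (missing start vs missing stop).
truncationFromFlags <- function(left, right, strand) {
    ifelse(left & right, "BOTH",
    ifelse(left,  ifelse(strand == 1L, "FIVE_PRIME", "THREE_PRIME"),
    ifelse(right, ifelse(strand == 1L, "THREE_PRIME", "FIVE_PRIME"),
           "NONE")))
}

flagsFromTruncation <- function(truncation, strand) {
    left <- truncation == "BOTH" |
        (truncation == "FIVE_PRIME" & strand == 1L) |
        (truncation == "THREE_PRIME" & strand == -1L)
    right <- truncation == "BOTH" |
        (truncation == "THREE_PRIME" & strand == 1L) |
        (truncation == "FIVE_PRIME" & strand == -1L)
    paste0(as.integer(left), as.integer(right))
}

#' Read a predicted proteome with truncation flags
#'
#' Reads one genome's predicted proteins and normalizes the gene caller's
#' contig-edge partial flags into the strand-relative truncation convention
#' used throughout the package. Two dialects are supported: `"caller-header"`
#' for protein FASTA whose headers carry coordinates, strand and a two-bit
#' `partial=XY` flag (`X` = left contig edge, `Y` = right contig edge, as
#' written by Prodigal), and `"gff3"` for a GFF3 file with a `partial`
#' attribute plus a plain protein FASTA whose identifiers match the GFF `ID`.
#'
#' A left-edge partial gene on the plus strand is missing its start
#' (`FIVE_PRIME` truncated); the same flag on the minus strand is missing its
#' stop (`THREE_PRIME`); both bits set mean `BOTH`.
#'
#' @param path protein FASTA (caller-header dialect) or GFF3 file.
#' @param dialect `"caller-header"` or `"gff3"`.
#' @param genomeId genome identifier to attach.
#' @param proteinFasta for the gff3 dialect, path to the matching protein
#'   FASTA (headers are the GFF `ID` values).
#' @return an [OrfSet-class].
#' @export
readProteins <- function(path, dialect = c("caller-header", "gff3"),
                         genomeId = tools::file_path_sans_ext(basename(path)),
                         proteinFasta = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    if (dialect == "caller-header")
        readProteinsCaller(path, genomeId)
    else
        readProteinsGff3(path, genomeId, proteinFasta)
}

readProteinsCaller <- function(path, genomeId) {
    aa <- Biostrings::readAAStringSet(path)
    if (length(aa) == 0L)
        return(OrfSet(genomeId, emptyOrfTable(), Biostrings::AAStringSet()))
    headers <- names(aa)
    parts <- strsplit(headers, "\\s+#\\s+")
    rows <- lapply(seq_along(parts), function(i) {
        p <- parts[[i]]
        if (length(p) < 5L)
            stop("malformed caller header (need 'id # start # end # strand # attrs'): ",
                 headers[i])
        start <- suppressWarnings(as.integer(p[2L]))
        end <- suppressWarnings(as.integer(p[3L]))
        strand <- suppressWarnings(as.integer(p[4L]))
        if (is.na(start) || is.na(end) || !strand %in% c(1L, -1L))
            stop("malformed coordinates in header: ", headers[i])
        m <- regmatches(p[5L], regexpr("partial=([01]{2})", p[5L]))
        if (length(m) == 0L)
            stop("missing partial=XY flag in header: ", headers[i])
        flag <- sub("partial=", "", m)
        data.frame(orf_id = p[1L],
                   start = start, end = end, strand = strand,
                   left = substr(flag, 1L, 1L) == "1",
                   right = substr(flag, 2L, 2L) == "1",
                   stringsAsFactors = FALSE)
    })
    tb <- do.call(rbind, rows)
    tb$contig_id <- sub("_[0-9]+$", "", tb$orf_id)
    tb$genome_id <- genomeId
    tb$truncation <- truncationFromFlags(tb$left, tb$right, tb$strand)
    names(aa) <- tb$orf_id
    OrfSet(genomeId,
           tb[, c("orf_id", "contig_id", "start", "end", "strand", "truncation")],
           aa)
}

readProteinsGff3 <- function(path, genomeId, proteinFasta) {
    if (is.null(proteinFasta))
        stop("gff3 dialect requires proteinFasta with the amino-acid sequences")
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    rows <- lapply(seq_along(fields), function(i) {
        f <- fields[[i]]
        if (length(f) != 9L)
            stop("malformed GFF3 line ", i, ": expected 9 columns, got ",
                 length(f))
        if (!f[3L] %in% c("CDS", "gene")) return(NULL)
        attrs <- f[9L]
        id <- sub(".*\\bID=([^;]+).*", "\\1", attrs)
        pm <- regmatches(attrs, regexpr("partial=([01]{2})", attrs))
        flag <- if (length(pm)) sub("partial=", "", pm) else "00"
        strand <- if (f[7L] == "-") -1L else 1L
        data.frame(orf_id = id, contig_id = f[1L],
                   start = as.integer(f[4L]), end = as.integer(f[5L]),
                   strand = strand,
                   left = substr(flag, 1L, 1L) == "1",
                   right = substr(flag, 2L, 2L) == "1",
                   stringsAsFactors = FALSE)
    })
    tb <- do.call(rbind, rows)
    if (is.null(tb))
        return(OrfSet(genomeId, emptyOrfTable(), Biostrings::AAStringSet()))
    tb$truncation <- truncationFromFlags(tb$left, tb$right, tb$strand)
    aa <- Biostrings::readAAStringSet(proteinFasta)
    names(aa) <- sub("\\s.*$", "", names(aa))
    missing <- setdiff(tb$orf_id, names(aa))
    if (length(missing))
        stop("proteins missing from FASTA: ", paste(missing, collapse = ", "))
    OrfSet(genomeId,
           tb[, c("orf_id", "contig_id", "start", "end", "strand", "truncation")],
           aa[tb$orf_id])
}

emptyOrfTable <- function() {
    data.frame(orf_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = integer(),
               truncation = character(), stringsAsFactors = FALSE)
}

#' Write a proteome with caller-style headers
#'
#' Inverse of [readProteins()] for the caller-header dialect; truncation
#' states are encoded back into genomic edge flags.
#'
#' @param orfs an [OrfSet-class].
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
writeProteins <- function(orfs, path) {
    tb <- orfTable(orfs)
    aa <- orfSequences(orfs)
    flags <- flagsFromTruncation(tb$truncation, tb$strand)
    names(aa) <- sprintf("%s # %d # %d # %d # ID=%s;partial=%s",
                         tb$orf_id, tb$start, tb$end, tb$strand, tb$orf_id,
                         flags)
    Biostrings::writeXStringSet(aa, path)
    invisible(path)
}

#' Read contig sequences into an Assembly
#'
#' @param path nucleotide FASTA of contigs.
#' @param genomeId genome identifier.
#' @return an [Assembly-class].
#' @export
readContigs <- function(path,
                        genomeId = tools::file_path_sans_ext(basename(path))) {
    dna <- Biostrings::readDNAStringSet(path)
    names(dna) <- sub("\\s.*$", "", names(dna))
    Assembly(genomeId, dna)
}

#' Write an Assembly to FASTA
#' @param assembly an [Assembly-class].
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
writeContigs <- function(assembly, path) {
    Biostrings::writeXStringSet(contigs(assembly), path)
    invisible(path)
}

hitCols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
             "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a 12-column tabular hit file
#'
#' Standard tabular alignment format (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), whitespace- or
#' tab-separated. Row order is preserved.
#'
#' @param path hit table path.
#' @return `data.frame` with the 12 standard columns; zero rows for an empty
#'   file.
#' @export
readHits <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(emptyHitTable())
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf != 12L))
        stop("hit table parse error at line ", which(nf != 12L)[1L],
             ": expected 12 columns, got ", nf[nf != 12L][1L])
    m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
    df <- data.frame(qseqid = m[, 1L], sseqid = m[, 2L],
                     stringsAsFactors = FALSE)
    num <- apply(m[, 3:12, drop = FALSE], 2L, as.numeric)
    if (is.null(dim(num))) num <- matrix(num, nrow = 1L)
    colnames(num) <- hitCols[3:12]
    df <- cbind(df, as.data.frame(num))
    for (col in c("length", "mismatch", "gapopen", "qstart", "qend",
                  "sstart", "send"))
        df[[col]] <- as.integer(df[[col]])
    if (anyNA(df[, 3:12]))
        stop("hit table parse error: non-numeric value at line ",
             which(rowSums(is.na(df[, 3:12])) > 0)[1L])
    df
}

emptyHitTable <- function() {
    data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
               length = integer(), mismatch = integer(), gapopen = integer(),
               qstart = integer(), qend = integer(), sstart = integer(),
               send = integer(), evalue = numeric(), bitscore = numeric(),
               stringsAsFactors = FALSE)
}

#' Write a hit table in 12-column tabular format
#' @param hits hit `data.frame` as returned by [readHits()] or
#'   [alignProteomes()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeHits <- function(hits, path) {
    utils::write.table(hits[, hitCols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a scaffold map
#'
#' Supports AGP v2.0 (component lines only; gap lines are skipped) and a
#' simple 3-column TSV (`scaffold_id`, `contig_id`, `orientation`) listed in
#' scaffold order. Ranks are assigned by file order within each scaffold.
#'
#' @param path scaffold file.
#' @param dialect `"tsv"` or `"agp"`.
#' @return a [ScaffoldMap-class].
#' @export
readScaffoldMap <- function(path, dialect = c("tsv", "agp")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) == 0L)
        return(ScaffoldMap(data.frame(scaffold_id = character(),
                                      rank = integer(), contig_id = character(),
                                      orientation = character())))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (dialect == "tsv") {
        bad <- which(lengths(fields) != 3L)
        if (length(bad))
            stop("scaffold TSV parse error at line ", bad[1L],
                 ": expected 3 columns")
        tb <- data.frame(scaffold_id = vapply(fields, `[`, "", 1L),
                         contig_id = vapply(fields, `[`, "", 2L),
                         orientation = vapply(fields, `[`, "", 3L),
                         stringsAsFactors = FALSE)
    } else {
        bad <- which(lengths(fields) < 8L)
        if (length(bad))
            stop("AGP parse error at line ", bad[1L], ": too few columns")
        comp <- !vapply(fields, `[`, "", 5L) %in% c("N", "U")
        fields <- fields[comp]
        ori <- vapply(fields, function(f)
            if (length(f) >= 9L) f[9L] else "+", "")
        ori[!ori %in% c("+", "-")] <- "+"
        tb <- data.frame(scaffold_id = vapply(fields, `[`, "", 1L),
                         contig_id = vapply(fields, `[`, "", 6L),
                         orientation = ori, stringsAsFactors = FALSE)
    }
    if (anyDuplicated(tb$contig_id))
        stop("scaffold integrity error: contig ",
             tb$contig_id[duplicated(tb$contig_id)][1L],
             " listed more than once")
    tb$rank <- stats::ave(seq_len(nrow(tb)), tb$scaffold_id,
                          FUN = seq_along)
    ScaffoldMap(tb[, c("scaffold_id", "rank", "contig_id", "orientation")])
}

#' Write a scaffold map as TSV
#' @param map a [ScaffoldMap-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeScaffoldMap <- function(map, path) {
    tb <- scaffoldTable(map)
    tb <- tb[order(tb$scaffold_id, tb$rank), ]
    utils::write.table(tb[, c("scaffold_id", "contig_id", "orientation")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' Write and read fragment sets
#'
#' Lossless TSV round trip for [FragmentSets-class]: one row per member with
#' a set-id column, header row included.
#'
#' @param sets a [FragmentSets-class].
#' @param path file path.
#' @return `writeFragmentSets` invisibly returns `path`;
#'   `readFragmentSets` returns a [FragmentSets-class].
#' @export
writeFragmentSets <- function(sets, path) {
    utils::write.table(setTable(sets)[, fragmentSetCols], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeFragmentSets
#' @export
readFragmentSets <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tb <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c(set_id = "character",
                                           genome_id = "character",
                                           fragment_id = "character",
                                           reference_protein_id = "character",
                                           reference_genome_id = "character"),
                            stringsAsFactors = FALSE)
    if (nrow(tb) == 0L) return(FragmentSets())
    if (!all(fragmentSetCols %in% names(tb)))
        stop("fragment set file missing columns: ",
             paste(setdiff(fragmentSetCols, names(tb)), collapse = ", "))
    FragmentSets(tb[, fragmentSetCols])
}

#' Read an ORF-to-annotation-term table
#'
#' Two-column TSV mapping `orf_id` to an annotation term (COG/Pfam/KEGG
#' accession); an ORF may appear on multiple rows. An optional third file
#' column is ignored.
#'
#' @param path annotation TSV path.
#' @return `data.frame` with columns `orf_id`, `term`.
#' @export
readAnnotations <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tb <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(tb) < 2L) stop("annotation table needs >= 2 columns")
    data.frame(orf_id = as.character(tb[[1L]]), term = as.character(tb[[2L]]),
               stringsAsFactors = FALSE)
}
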