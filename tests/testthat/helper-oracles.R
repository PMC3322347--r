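# Independent oracles and small in-code fixtures shared across test files.

# Exhaustive N50: try every distinct length as the threshold and take the
# smallest one whose >=L contigs hold at least half of the total.
n50Oracle <- function(lens) {
    total <- sum(lens)
    cand <- sort(unique(lens))
    for (L in sort(cand, decreasing = TRUE)) {
        if (sum(lens[lens >= L]) >= total / 2) return(L)
    }
    stop("unreachable")
}

# Exhaustive affine-gap Smith-Waterman for short sequences, scored like the
# built-in aligner: a gap of length L costs gapOpen + L * gapExtend.
# Returns the best local score (Gotoh three-state recursion).
swOracle <- function(a, b, subMat, gapOpen = 11, gapExtend = 1) {
    a <- strsplit(a, "")[[1]]
    b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    NEG <- -1e9
    M <- matrix(0, n + 1, m + 1)    # match/mismatch state
    X <- matrix(NEG, n + 1, m + 1)  # gap in b (deletion from a)
    Y <- matrix(NEG, n + 1, m + 1)  # gap in a
    best <- 0
    for (i in 1:n) for (j in 1:m) {
        s <- subMat[a[i], b[j]]
        M[i + 1, j + 1] <- max(0,
                               M[i, j] + s, X[i, j] + s, Y[i, j] + s)
        X[i + 1, j + 1] <- max(M[i, j + 1] - gapOpen - gapExtend,
                               X[i, j + 1] - gapExtend)
        Y[i + 1, j + 1] <- max(M[i + 1, j] - gapOpen - gapExtend,
                               Y[i + 1, j] - gapExtend)
        best <- max(best, M[i + 1, j + 1])
    }
    best
}

blosum62 <- local({
    mat <- NULL
    function() {
        if (is.null(mat)) {
            e <- new.env()
            utils::data("BLOSUM62", package = "Biostrings", envir = e)
            mat <<- e$BLOSUM62
        }
        mat
    }
})

# Pearson r and two-sided p from first principles, at full precision.
pearsonOracle <- function(x, y) {
    n <- length(x)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

randomAa <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y"),
                 n, replace = TRUE), collapse = "")
}

# Minimal OrfSet builder for hand-constructed cases.
makeOrfs <- function(genome, ids, trunc, seqs,
                     contig = paste0("c_", ids),
                     strand = rep(1L, length(ids)),
                     start = rep(1L, length(ids)),
                     end = nchar(seqs) * 3L) {
    OrfSet(genome,
           data.frame(orf_id = ids, contig_id = contig, start = start,
                      end = end, strand = strand, truncation = trunc,
                      stringsAsFactors = FALSE),
           stats::setNames(seqs, ids))
}

# One hit-table row with sensible defaults.
hitRow <- function(q, s, pident = 100, len = 100, qstart = 1,
                   qend = qstart + len - 1, sstart = 1,
                   send = sstart + len - 1, evalue = 0, bitscore = len * 2) {
    data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
               mismatch = 0L, gapopen = 0L, qstart = as.integer(qstart),
               qend = as.integer(qend), sstart = as.integer(sstart),
               send = as.integer(send), evalue = evalue, bitscore = bitscore,
               stringsAsFactors = FALSE)
}

# Placement rows for assembleSetsForReference tests.
placementRow <- function(frag, ref = "R1", refGenome = "ref",
                         pident = 95, s_start = 1, s_end = 100,
                         truncation = "BOTH", cov = 1) {
    data.frame(fragment_id = frag, reference_protein_id = ref,
               reference_genome_id = refGenome, pident = pident,
               s_start = as.integer(s_start), s_end = as.integer(s_end),
               frag_coverage = cov, bitscore = pident,
               truncation = truncation, stringsAsFactors = FALSE)
}
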