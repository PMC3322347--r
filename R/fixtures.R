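#' @include AllClasses.R io.R homology.R
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Fixture generator configuration
#'
#' Parameters of the synthetic draft-genome fixture: a clean proteome is
#' generated, optionally duplicated into near-identical paralog decoys,
#' broken at random points so each piece becomes a contig-terminal ORF
#' fragment with the correct truncation state, and paired with a diverged
#' complete reference proteome and a scaffold map recording the true layout.
#'
#' @param seed integer seed; every random draw in the fixture flows from it.
#' @param n_genes number of genes in the clean proteome.
#' @param gene_length_range min/max gene length in aa (uniform).
#' @param break_rate Poisson mean of breaks per gene.
#' @param min_fragment_aa pieces shorter than this are dropped (no ORF is
#'   called on them), emulating gene-caller minimum lengths; their contigs
#'   are left out of the scaffold like typical unplaced short contigs.
#' @param reference_divergence per-residue substitution probability for the
#'   reference proteome; expected fragment-to-reference identity is
#'   `100 * (1 - reference_divergence)`.
#' @param paralog_count number of genes duplicated into low-divergence
#'   paralog decoys (false-link bait, mimicking multi-modular repetitive
#'   gene families).
#' @param paralog_divergence per-residue substitution probability for decoy
#'   copies.
#' @param scaffold_fraction proportion of fragmented genes whose contigs are
#'   placed in a scaffold.
#' @param flank_bp flanking sequence added to non-truncated contig sides.
#' @return validated config list of class `fixtureConfig`.
#' @export
fixtureConfig <- function(seed = 1L, n_genes = 1000L,
                          gene_length_range = c(100L, 600L),
                          break_rate = 0.5, min_fragment_aa = 30L,
                          reference_divergence = 0.10,
                          paralog_count = 0L, paralog_divergence = 0.05,
                          scaffold_fraction = 1.0, flank_bp = 60L) {
    stopifnot(length(gene_length_range) == 2L,
              gene_length_range[1L] >= 1L,
              gene_length_range[1L] <= gene_length_range[2L],
              min_fragment_aa >= 1L,
              reference_divergence >= 0, reference_divergence < 1,
              paralog_divergence >= 0, paralog_divergence < 1,
              break_rate >= 0, n_genes >= 1L,
              scaffold_fraction >= 0, scaffold_fraction <= 1)
    structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                   gene_length_range = as.integer(gene_length_range),
                   break_rate = break_rate,
                   min_fragment_aa = as.integer(min_fragment_aa),
                   reference_divergence = reference_divergence,
                   paralog_count = as.integer(paralog_count),
                   paralog_divergence = paralog_divergence,
                   scaffold_fraction = scaffold_fraction,
                   flank_bp = as.integer(flank_bp)),
              class = "fixtureConfig")
}

#' Generate a clean complete proteome
#'
#' Random amino-acid sequences, uniform over the 20 standard residues;
#' deterministic under the config seed. Each gene is placed on its own
#' contig with flanking sequence, so every ORF is complete.
#'
#' @param config a [fixtureConfig()].
#' @param genomeId genome identifier.
#' @return an [OrfSet-class] with truncation all `NONE`.
#' @export
generateProteome <- function(config, genomeId = "target") {
    set.seed(config$seed)
    n <- config$n_genes
    lens <- sample(seq(config$gene_length_range[1L],
                       config$gene_length_range[2L]), n, replace = TRUE)
    ids <- sprintf("g%04d", seq_len(n))
    seqs <- vapply(lens, function(L)
        paste(sample(AA20, L, replace = TRUE), collapse = ""), "")
    strands <- sample(c(1L, -1L), n, replace = TRUE)
    tb <- data.frame(orf_id = ids, contig_id = ids,
                     start = 1L, end = 3L * lens + 3L, strand = strands,
                     truncation = "NONE", stringsAsFactors = FALSE)
    OrfSet(genomeId, tb, stats::setNames(seqs, ids))
}

#' Mutate a proteome to a target divergence
#'
#' Substitutes each residue independently with the given probability to a
#' different, uniformly chosen residue, emulating a related reference genome
#' with expected pairwise identity `100 * (1 - divergence)`.
#'
#' @param proteome an [OrfSet-class].
#' @param divergence per-residue substitution probability in `[0, 1)`.
#' @param seed RNG seed.
#' @param genomeId genome identifier of the mutated copy.
#' @return an [OrfSet-class] with the same ids and coordinates.
#' @export
mutateProteome <- function(proteome, divergence, seed,
                           genomeId = paste0(genomeId(proteome), "_ref")) {
    set.seed(seed)
    seqs <- as.character(orfSequences(proteome))
    mutated <- vapply(seqs, function(s) {
        ch <- strsplit(s, "")[[1]]
        hit <- stats::runif(length(ch)) < divergence
        if (any(hit))
            ch[hit] <- vapply(ch[hit], function(a)
                sample(setdiff(AA20, a), 1L), "")
        paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
    tb <- orfTable(proteome)
    OrfSet(genomeId, tb, stats::setNames(mutated, tb$orf_id))
}

## inverted genetic code: AA letter -> DNA codons
codonsByAa <- local({
    inv <- NULL
    function() {
        if (is.null(inv)) {
            gc <- Biostrings::GENETIC_CODE
            inv <<- split(names(gc), unname(gc))
        }
        inv
    }
})

reverseTranslate <- function(aa) {
    inv <- codonsByAa()
    codons <- vapply(strsplit(aa, "")[[1]], function(a) {
        opts <- inv[[a]]
        if (length(opts) == 1L) opts else sample(opts, 1L)
    }, "", USE.NAMES = FALSE)
    paste(codons, collapse = "")
}

randomNt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

revComp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Fragment a proteome into a synthetic draft genome with truth
#'
#' Emulates assembly fragmentation: per gene a Poisson number of breaks is
#' drawn and placed uniformly within the gene; each piece becomes a
#' contig-terminal ORF with the correct truncation state (the start-bearing
#' piece is 3'-truncated, the stop-bearing piece 5'-truncated, interior
#' pieces truncated at both ends). Pieces shorter than `min_fragment_aa`
#' are dropped: no ORF is called and their contig is left out of the
#' scaffold. Contigs are reverse-translated with uniform codon choice and
#' flanked on non-broken sides; fragmented genes are laid out into
#' single-gene scaffolds (in genomic order, with occasional stored-strand
#' flips recorded as "-" orientations) for `scaffold_fraction` of genes.
#' Decoy paralog copies, fragmented like every other gene but absent from
#' the clean proteome, provide false-link bait.
#'
#' @param proteome clean complete proteome from [generateProteome()].
#' @param config a [fixtureConfig()].
#' @return list with `orfs` ([OrfSet-class] of the fragmented genome),
#'   `assembly` ([Assembly-class]), `scaffolds` ([ScaffoldMap-class]) and
#'   `truth` (list: `fragments` per-piece table, `adjacencies` table of
#'   truly adjacent kept fragment pairs, `paralogs` decoy map, `dropped`
#'   ids of genes with a dropped piece).
#' @export
fragmentGenome <- function(proteome, config) {
    set.seed(config$seed + 1L)
    tb <- orfTable(proteome)
    seqs <- as.character(orfSequences(proteome))
    geneIds <- tb$orf_id
    strands <- stats::setNames(tb$strand, geneIds)
    paralogMap <- data.frame(gene_id = character(), paralog_id = character(),
                             stringsAsFactors = FALSE)
    if (config$paralog_count > 0L) {
        src <- sample(geneIds, min(config$paralog_count, length(geneIds)))
        for (g in src) {
            pid <- paste0(g, "p")
            ch <- strsplit(seqs[[match(g, geneIds)]], "")[[1]]
            hit <- stats::runif(length(ch)) < config$paralog_divergence
            if (any(hit))
                ch[hit] <- vapply(ch[hit], function(a)
                    sample(setdiff(AA20, a), 1L), "")
            seqs <- c(seqs, paste(ch, collapse = ""))
            geneIds <- c(geneIds, pid)
            strands <- c(strands, stats::setNames(sample(c(1L, -1L), 1L), pid))
            paralogMap <- rbind(paralogMap,
                                data.frame(gene_id = g, paralog_id = pid,
                                           stringsAsFactors = FALSE))
        }
    }
    orfRows <- list(); contigSeqs <- character(0)
    scafRows <- list(); fragRows <- list(); adjRows <- list()
    droppedGenes <- character(0)
    for (gi in seq_along(geneIds)) {
        g <- geneIds[gi]
        aa <- seqs[[gi]]
        L <- nchar(aa)
        strand <- strands[[g]]
        k <- stats::rpois(1L, config$break_rate)
        k <- min(k, L - 1L)
        breaks <- if (k > 0L) sort(sample(seq_len(L - 1L), k)) else integer(0)
        starts <- c(1L, breaks + 1L)
        ends <- c(breaks, L)
        nPieces <- length(starts)
        pieceLens <- ends - starts + 1L
        kept <- nPieces == 1L | pieceLens >= config$min_fragment_aa
        if (any(!kept)) droppedGenes <- c(droppedGenes, g)
        scaffolded <- nPieces > 1L &&
            stats::runif(1L) < config$scaffold_fraction
        keptFragIds <- rep(NA_character_, nPieces)
        pieceInfo <- vector("list", nPieces)
        for (p in seq_len(nPieces)) {
            fiveTrunc <- p > 1L
            threeTrunc <- p < nPieces
            contigId <- if (nPieces == 1L) paste0("ctg_", g)
                        else sprintf("ctg_%s_%d", g, p)
            pieceAa <- substr(aa, starts[p], ends[p])
            cds <- reverseTranslate(pieceAa)
            if (!threeTrunc) cds <- paste0(cds, "TAA")
            flank5 <- if (!fiveTrunc) randomNt(config$flank_bp) else ""
            flank3 <- if (!threeTrunc) randomNt(config$flank_bp) else ""
            sense <- paste0(flank5, cds, flank3)
            cdsStart <- nchar(flank5) + 1L
            cdsEnd <- nchar(flank5) + nchar(cds)
            contigSeq <- sense
            orfStrand <- 1L
            if (strand == -1L) {
                contigSeq <- revComp(sense)
                Ln <- nchar(sense)
                tmp <- cdsStart
                cdsStart <- Ln - cdsEnd + 1L
                cdsEnd <- Ln - tmp + 1L
                orfStrand <- -1L
            }
            flipped <- FALSE
            if (scaffolded && kept[p] && stats::runif(1L) < 0.2) {
                ## store the contig reverse-complemented; the scaffold
                ## records a "-" orientation
                contigSeq <- revComp(contigSeq)
                Ln <- nchar(contigSeq)
                tmp <- cdsStart
                cdsStart <- Ln - cdsEnd + 1L
                cdsEnd <- Ln - tmp + 1L
                orfStrand <- -orfStrand
                flipped <- TRUE
            }
            truncState <- if (fiveTrunc && threeTrunc) "BOTH"
                          else if (fiveTrunc) "FIVE_PRIME"
                          else if (threeTrunc) "THREE_PRIME"
                          else "NONE"
            pieceInfo[[p]] <- list(contig_id = contigId, flipped = flipped)
            if (!kept[p]) {
                ## contig exists but is too short for an ORF call
                contigSeqs[contigId] <- contigSeq
                fragRows[[length(fragRows) + 1L]] <- data.frame(
                    gene_id = g, fragment_id = NA_character_,
                    contig_id = contigId, piece_index = p,
                    piece_length_aa = pieceLens[p], kept = FALSE,
                    stringsAsFactors = FALSE)
                next
            }
            orfId <- paste0(contigId, "_1")
            keptFragIds[p] <- orfId
            contigSeqs[contigId] <- contigSeq
            orfRows[[length(orfRows) + 1L]] <- data.frame(
                orf_id = orfId, contig_id = contigId,
                start = cdsStart, end = cdsEnd, strand = orfStrand,
                truncation = truncState, aa = pieceAa,
                stringsAsFactors = FALSE)
            fragRows[[length(fragRows) + 1L]] <- data.frame(
                gene_id = g, fragment_id = orfId, contig_id = contigId,
                piece_index = p, piece_length_aa = pieceLens[p], kept = TRUE,
                stringsAsFactors = FALSE)
        }
        keptIdx <- which(!is.na(keptFragIds))
        if (length(keptIdx) >= 2L)
            for (j in seq_len(length(keptIdx) - 1L))
                adjRows[[length(adjRows) + 1L]] <- data.frame(
                    gene_id = g,
                    fragment_1 = keptFragIds[keptIdx[j]],
                    fragment_2 = keptFragIds[keptIdx[j + 1L]],
                    scaffolded = scaffolded, stringsAsFactors = FALSE)
        if (scaffolded && length(keptIdx) >= 2L) {
            ## genomic order: piece order for + genes, reversed for - genes
            ordIdx <- if (strand == 1L) keptIdx else rev(keptIdx)
            for (r in seq_along(ordIdx)) {
                p <- ordIdx[r]
                scafRows[[length(scafRows) + 1L]] <- data.frame(
                    scaffold_id = paste0("scf_", g), rank = r,
                    contig_id = pieceInfo[[p]]$contig_id,
                    orientation = if (pieceInfo[[p]]$flipped) "-" else "+",
                    stringsAsFactors = FALSE)
            }
        }
    }
    orfTab <- do.call(rbind, orfRows)
    orfs <- OrfSet(genomeId(proteome),
                   orfTab[, c("orf_id", "contig_id", "start", "end",
                              "strand", "truncation")],
                   stats::setNames(orfTab$aa, orfTab$orf_id))
    assembly <- Assembly(genomeId(proteome),
                         Biostrings::DNAStringSet(contigSeqs))
    scaffolds <- ScaffoldMap(if (length(scafRows)) do.call(rbind, scafRows)
                             else data.frame(scaffold_id = character(),
                                             rank = integer(),
                                             contig_id = character(),
                                             orientation = character()))
    truth <- list(fragments = do.call(rbind, fragRows),
                  adjacencies = if (length(adjRows)) do.call(rbind, adjRows)
                      else data.frame(gene_id = character(),
                                      fragment_1 = character(),
                                      fragment_2 = character(),
                                      scaffolded = logical()),
                  paralogs = paralogMap,
                  dropped = unique(droppedGenes))
    list(orfs = orfs, assembly = assembly, scaffolds = scaffolds,
         truth = truth)
}

#' Build a complete synthetic fixture
#'
#' Convenience wrapper: generates the clean proteome, fragments it into a
#' draft genome with truth, and derives a diverged complete reference
#' proteome.
#'
#' @param config a [fixtureConfig()].
#' @param genomeId target genome id.
#' @param referenceId reference genome id.
#' @return list with `target` (fragmented [OrfSet-class]), `assembly`,
#'   `scaffolds`, `truth`, `reference` (complete diverged [OrfSet-class])
#'   and `clean` (the unfragmented proteome).
#' @export
buildFixture <- function(config, genomeId = "target",
                         referenceId = "ref") {
    clean <- generateProteome(config, genomeId)
    frag <- fragmentGenome(clean, config)
    reference <- mutateProteome(clean, config$reference_divergence,
                                seed = config$seed + 2L,
                                genomeId = referenceId)
    c(frag, list(reference = reference, clean = clean))
}

#' Write a fixture bundle to files
#'
#' Emits the fragmented proteome as caller-header protein FASTA, the contig
#' FASTA, the scaffold TSV, a truth TSV, the reference proteome FASTA and,
#' optionally, a precomputed fragment-to-reference hit table produced by
#' [alignProteomes()]. Re-reading the files reproduces the in-memory
#' bundle.
#'
#' @param bundle fixture list from [buildFixture()].
#' @param dir output directory (created if needed).
#' @param hits also write `hits_target_vs_ref.tsv`.
#' @return named character vector of the written paths.
#' @export
emitFixture <- function(bundle, dir, hits = FALSE) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
        proteins = file.path(dir, "target_proteins.faa"),
        contigs = file.path(dir, "target_contigs.fna"),
        scaffolds = file.path(dir, "target_scaffolds.tsv"),
        truth = file.path(dir, "truth_fragments.tsv"),
        reference = file.path(dir, "reference_proteins.faa"))
    writeProteins(bundle$orfs, paths[["proteins"]])
    writeContigs(bundle$assembly, paths[["contigs"]])
    writeScaffoldMap(bundle$scaffolds, paths[["scaffolds"]])
    utils::write.table(bundle$truth$fragments, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeProteins(bundle$reference, paths[["reference"]])
    if (hits) {
        hp <- file.path(dir, "hits_target_vs_ref.tsv")
        fragIds <- names(which(isPartial(bundle$orfs)))
        writeHits(alignProteomes(bundle$orfs, bundle$reference,
                                 queryIds = fragIds), hp)
        paths <- c(paths, hits = hp)
    }
    paths
}
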