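test_that("fixtures are deterministic in the seed and sensitive to it", {
    cfg <- fixtureConfig(seed = 21, n_genes = 30, break_rate = 1)
    a <- buildFixture(cfg)
    b <- buildFixture(cfg)
    expect_identical(orfTable(a$orfs), orfTable(b$orfs))
    expect_identical(as.character(orfSequences(a$orfs)),
                     as.character(orfSequences(b$orfs)))
    expect_identical(scaffoldTable(a$scaffolds), scaffoldTable(b$scaffolds))
    expect_identical(a$truth, b$truth)
    expect_identical(as.character(orfSequences(a$reference)),
                     as.character(orfSequences(b$reference)))
    other <- buildFixture(fixtureConfig(seed = 22, n_genes = 30,
                                        break_rate = 1))
    expect_false(identical(as.character(orfSequences(a$clean)),
                           as.character(orfSequences(other$clean))))
})

test_that("the clean proteome honours gene count and length range", {
    cfg <- fixtureConfig(seed = 5, n_genes = 40,
                         gene_length_range = c(80, 120))
    clean <- generateProteome(cfg)
    expect_identical(length(orfSequences(clean)), 40L)
    lens <- orfLengths(clean)
    expect_true(all(lens >= 80 & lens <= 120))
    expect_true(all(truncation(clean) == "NONE"))
    expect_true(all(strsplit(paste(as.character(orfSequences(clean)),
                                   collapse = ""), "")[[1]] %in%
                    fragLink:::AA20))
})

test_that("mutated divergence matches its binomial expectation", {
    cfg <- fixtureConfig(seed = 6, n_genes = 20,
                         gene_length_range = c(200, 400))
    clean <- generateProteome(cfg)
    for (d in c(0, 0.05, 0.2)) {
        mut <- mutateProteome(clean, d, seed = 7, genomeId = "m")
        a <- strsplit(paste(as.character(orfSequences(clean)),
                            collapse = ""), "")[[1]]
        b <- strsplit(paste(as.character(orfSequences(mut)),
                            collapse = ""), "")[[1]]
        nDiff <- sum(a != b)
        N <- length(a)
        expect_lte(abs(nDiff - N * d), 3 * sqrt(N * d * (1 - d)) + 1e-9)
    }
    expect_identical(unname(as.character(orfSequences(
        mutateProteome(clean, 0, seed = 8, genomeId = "m")))),
        unname(as.character(orfSequences(clean))))
})

test_that("fragmentation conserves residues and encodes truncation truly", {
    cfg <- fixtureConfig(seed = 9, n_genes = 40, break_rate = 1.5,
                         min_fragment_aa = 30)
    fx <- buildFixture(cfg)
    clean <- fx$clean
    fr <- fx$truth$fragments
    ## every gene's pieces (kept plus dropped) sum to its full length
    pieceSum <- tapply(fr$piece_length_aa, fr$gene_id, sum)
    lens <- orfLengths(clean)
    expect_equal(as.integer(pieceSum[names(lens)]), unname(lens))
    ## kept pieces carry the right truncation state for their position
    tr <- truncation(fx$orfs)
    nPieces <- tapply(fr$piece_index, fr$gene_id, max)
    kept <- fr[fr$kept, ]
    for (i in seq_len(nrow(kept))) {
        p <- kept$piece_index[i]
        np <- nPieces[[kept$gene_id[i]]]
        want <- if (np == 1L) "NONE"
                else if (p == 1L) "THREE_PRIME"
                else if (p == np) "FIVE_PRIME" else "BOTH"
        expect_identical(unname(tr[kept$fragment_id[i]]), want)
    }
    ## fragment sequences are verbatim substrings of the parent gene
    seqs <- as.character(orfSequences(fx$orfs))
    cleanSeqs <- as.character(orfSequences(clean))
    genic <- kept[kept$gene_id %in% names(cleanSeqs), ]
    off <- tapply(fr$piece_length_aa, fr$gene_id, cumsum)
    for (i in seq_len(nrow(genic))) {
        g <- genic$gene_id[i]
        e <- off[[g]][genic$piece_index[i]]
        s <- e - genic$piece_length_aa[i] + 1L
        expect_identical(unname(seqs[genic$fragment_id[i]]),
                         substr(cleanSeqs[[g]], s, e))
    }
})

test_that("a zero break rate yields an unfragmented genome", {
    fx <- buildFixture(fixtureConfig(seed = 10, n_genes = 15,
                                     break_rate = 0))
    expect_identical(sum(isPartial(fx$orfs)), 0L)
    expect_identical(nrow(fx$truth$adjacencies), 0L)
    expect_identical(nrow(scaffoldTable(fx$scaffolds)), 0L)
})

test_that("translating each ORF's contig interval recovers its protein", {
    fx <- buildFixture(fixtureConfig(seed = 12, n_genes = 20,
                                     break_rate = 1))
    tb <- orfTable(fx$orfs)
    ctg <- contigs(fx$assembly)
    for (i in seq_len(nrow(tb))) {
        nt <- Biostrings::subseq(ctg[[tb$contig_id[i]]],
                                 tb$start[i], tb$end[i])
        if (tb$strand[i] == -1L) nt <- Biostrings::reverseComplement(nt)
        aa <- as.character(Biostrings::translate(nt, no.init.codon = TRUE))
        aa <- sub("\\*$", "", aa)
        expect_identical(aa,
                         as.character(orfSequences(fx$orfs)[[tb$orf_id[i]]]))
    }
})

test_that("planted scaffold adjacencies classify TRUE, flips included", {
    fx <- buildFixture(fixtureConfig(seed = 14, n_genes = 60,
                                     break_rate = 1.2))
    adj <- fx$truth$adjacencies
    adj <- adj[adj$scaffolded, ]
    expect_gt(nrow(adj), 10)
    cls <- vapply(seq_len(nrow(adj)), function(i)
        classifyPair(adj$fragment_1[i], adj$fragment_2[i],
                     fx$orfs, fx$scaffolds), "")
    expect_true(all(cls == "TRUE"))
    ## some stored contigs should actually be flipped at this size
    expect_gt(sum(scaffoldTable(fx$scaffolds)$orientation == "-"), 0)
})

test_that("emitted files reproduce the in-memory fixture", {
    cfg <- fixtureConfig(seed = 16, n_genes = 15, break_rate = 1,
                         reference_divergence = 0)
    fx <- buildFixture(cfg)
    dir <- tempfile("fixdir")
    paths <- emitFixture(fx, dir, hits = TRUE)
    expect_true(all(file.exists(paths)))
    back <- readProteins(paths[["proteins"]], "caller-header",
                         genomeId = "target")
    expect_identical(orfTable(back), orfTable(fx$orfs))
    asm <- readContigs(paths[["contigs"]], genomeId = "target")
    expect_identical(as.character(contigs(asm)),
                     as.character(contigs(fx$assembly)))
    sm <- readScaffoldMap(paths[["scaffolds"]], "tsv")
    expect_identical(scaffoldTable(sm), scaffoldTable(fx$scaffolds))
    tr <- utils::read.delim(paths[["truth"]], stringsAsFactors = FALSE)
    expect_identical(tr$gene_id, fx$truth$fragments$gene_id)
    expect_identical(tr$kept, fx$truth$fragments$kept)
    ## with zero divergence, every emitted hit is an exact match
    h <- readHits(paths[["hits"]])
    expect_gt(nrow(h), 0)
    expect_true(all(h$pident[h$sseqid == sub("_.*", "",
                                             sub("ctg_", "", h$qseqid))]
                    == 100))
})

test_that("fixture AAI tracks the configured reference divergence", {
    cfg <- fixtureConfig(seed = 18, n_genes = 15, break_rate = 0,
                         gene_length_range = c(150, 300),
                         reference_divergence = 0.10)
    fx <- buildFixture(cfg)
    ab <- alignProteomes(fx$orfs, fx$reference)
    ba <- alignProteomes(fx$reference, fx$orfs)
    bbh <- bidirectionalBestHits(bestHitPerQuery(ab), bestHitPerQuery(ba))
    r <- computeAai(bbh, fx$orfs, fx$reference)
    expect_identical(r$n_pairs, 15L)
    expect_gt(r$aai, 85)
    expect_lt(r$aai, 95)
})

test_that("end to end: fragments relink with high recall and no false joins", {
    cfg <- fixtureConfig(seed = 19, n_genes = 80, break_rate = 1,
                         reference_divergence = 0.10)
    fx <- buildFixture(cfg)
    fragIds <- names(which(isPartial(fx$orfs)))
    hits <- alignProteomes(fx$orfs, fx$reference, queryIds = fragIds)
    res <- linkAgainstReferences(fx$orfs, list(fx$reference), list(hits))
    expect_gte(linkageRecall(res$sets, fx$truth), 0.9)
    expect_lte(truthFalseRate(res$sets, fx$truth), 0.02)
    ev <- evaluateSets(res$sets, fx$orfs, fx$scaffolds, length(fragIds))
    expect_identical(ev$n_false, 0L)
})
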