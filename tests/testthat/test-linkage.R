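emptyHits <- function() {
    h <- hitRow("x", "y")
    h[0, ]
}

test_that("candidate placements enforce completeness, identity, coverage", {
    frag <- makeOrfs("g", c("f1", "f2", "f3"),
                     c("THREE_PRIME", "FIVE_PRIME", "BOTH"),
                     vapply(rep(100, 3), randomAa, ""))
    ref <- makeOrfs("ref", c("R1", "R2"), c("NONE", "FIVE_PRIME"),
                    vapply(rep(300, 2), randomAa, ""))
    hits <- rbind(
        hitRow("f1", "R1", pident = 95, len = 100, qstart = 1, qend = 100,
               sstart = 1, send = 100),
        hitRow("f2", "R2", pident = 95, len = 100),       # ref is a fragment
        hitRow("f3", "R1", pident = 20, len = 100),       # identity too low
        hitRow("f2", "R1", pident = 90, len = 50, qstart = 1, qend = 50,
               sstart = 201, send = 250))                 # 50% coverage
    pl <- candidatePlacements(frag, hits, ref)
    expect_identical(pl$fragment_id, "f1")
    expect_identical(pl$reference_protein_id, "R1")
    expect_equal(pl$frag_coverage, 1)

    ## highest-bitscore hit wins per (fragment, reference) pair
    hits2 <- rbind(hitRow("f1", "R1", pident = 80, len = 100, bitscore = 150,
                          sstart = 1, send = 100),
                   hitRow("f1", "R1", pident = 95, len = 100, bitscore = 400,
                          sstart = 101, send = 200))
    pl2 <- candidatePlacements(frag, hits2, ref)
    expect_identical(nrow(pl2), 1L)
    expect_equal(pl2$pident, 95)

    ## complete query ORFs are not fragments and never placed
    comp <- makeOrfs("g", "c1", "NONE", randomAa(100))
    expect_identical(nrow(candidatePlacements(
        comp, hitRow("c1", "R1"), ref)), 0L)
})

test_that("two complementary fragments assemble into one set", {
    pl <- rbind(placementRow("fA", s_start = 1, s_end = 150,
                             truncation = "THREE_PRIME", pident = 100),
                placementRow("fB", s_start = 151, s_end = 300,
                             truncation = "FIVE_PRIME", pident = 100))
    sets <- assembleSetsForReference(pl, genomeId = "g")
    expect_identical(nrow(sets), 2L)
    expect_identical(sets$fragment_id, c("fA", "fB"))
    expect_identical(sets$member_rank, 1:2)
    expect_equal(unique(sets$mean_identity), 100)
})

test_that("a triple split with an internal BOTH piece assembles fully", {
    pl <- rbind(placementRow("f1", s_start = 1, s_end = 100,
                             truncation = "THREE_PRIME", pident = 98),
                placementRow("f2", s_start = 101, s_end = 200,
                             truncation = "BOTH", pident = 97),
                placementRow("f3", s_start = 201, s_end = 300,
                             truncation = "FIVE_PRIME", pident = 96))
    sets <- assembleSetsForReference(pl, genomeId = "g")
    expect_identical(sort(unique(sets$set_id)), unique(sets$set_id))
    expect_identical(nrow(sets), 3L)
    expect_identical(sets$fragment_id, c("f1", "f2", "f3"))
})

test_that("co-covering fragments (paralog bait) are never joined", {
    pl <- rbind(placementRow("p1", s_start = 1, s_end = 200, pident = 95),
                placementRow("p2", s_start = 1, s_end = 200, pident = 94))
    expect_identical(nrow(assembleSetsForReference(pl, genomeId = "g")), 0L)
    ## a small overlap within the allowance is fine
    pl2 <- rbind(placementRow("p1", s_start = 1, s_end = 155,
                              truncation = "THREE_PRIME", pident = 95),
                 placementRow("p2", s_start = 150, s_end = 300,
                              truncation = "FIVE_PRIME", pident = 94))
    expect_identical(nrow(assembleSetsForReference(pl2, genomeId = "g")), 2L)
})

test_that("identity spread, truncation budget and end order gate membership", {
    ## spread: 95 vs 50 exceeds the default 40-point allowance
    pl <- rbind(placementRow("a", s_start = 1, s_end = 100,
                             truncation = "THREE_PRIME", pident = 95),
                placementRow("b", s_start = 151, s_end = 250,
                             truncation = "FIVE_PRIME", pident = 50))
    expect_identical(nrow(assembleSetsForReference(pl, genomeId = "g")), 0L)

    ## budget: only two single-end-truncated members allowed per set
    pl <- rbind(placementRow("a", s_start = 1, s_end = 90,
                             truncation = "THREE_PRIME", pident = 99),
                placementRow("b", s_start = 101, s_end = 190,
                             truncation = "FIVE_PRIME", pident = 98),
                placementRow("c", s_start = 201, s_end = 290,
                             truncation = "FIVE_PRIME", pident = 97))
    loose <- LinkageParams(enforceEndOrder = FALSE)
    sets <- assembleSetsForReference(pl, loose, genomeId = "g")
    expect_identical(sort(sets$fragment_id), c("a", "b"))

    ## end order: a stop-bearing (5'-truncated) member cannot sit mid-set
    sets2 <- assembleSetsForReference(pl, genomeId = "g")
    expect_identical(sort(sets2$fragment_id), c("a", "b"))
    pl3 <- rbind(placementRow("a", s_start = 1, s_end = 90,
                              truncation = "THREE_PRIME", pident = 99),
                 placementRow("b", s_start = 101, s_end = 190,
                              truncation = "FIVE_PRIME", pident = 98),
                 placementRow("c", s_start = 201, s_end = 290,
                              truncation = "BOTH", pident = 97))
    sets3 <- assembleSetsForReference(pl3, genomeId = "g")
    expect_identical(sort(sets3$fragment_id), c("a", "b"))
    sets4 <- assembleSetsForReference(pl3, loose, genomeId = "g")
    expect_identical(sort(sets4$fragment_id), c("a", "b", "c"))
})

test_that("conflict resolution keeps the higher mean identity globally", {
    mkset <- function(id, frags, ident, ref = "R1", refg = "ref") {
        data.frame(set_id = id, genome_id = "g", fragment_id = frags,
                   member_rank = seq_along(frags), identity = ident,
                   ref_start = seq_along(frags) * 100L - 99L,
                   ref_end = seq_along(frags) * 100L,
                   reference_protein_id = ref, reference_genome_id = refg,
                   mean_identity = mean(ident), stringsAsFactors = FALSE)
    }
    disjoint <- rbind(mkset("s1", c("f1", "f2"), c(90, 90)),
                      mkset("s2", c("f3", "f4"), c(80, 80)))
    expect_identical(nSets(resolveConflicts(disjoint)), 2L)

    conflict <- rbind(mkset("s1", c("f1", "f2"), c(85, 85)),
                      mkset("s2", c("f2", "f3"), c(92, 92), ref = "R2"))
    kept <- setTable(resolveConflicts(conflict))
    expect_identical(unique(kept$set_id), "s2")

    tie <- rbind(mkset("s1", c("f1", "f2"), c(90, 90)),
                 mkset("s2", c("f2", "f3", "f4"), c(90, 90, 90), ref = "R2"))
    expect_identical(unique(setTable(resolveConflicts(tie))$set_id), "s2")
})

# A two-genome scenario with a split planted in genome A: gene split into an
# N-terminal (stop-missing) and C-terminal (start-missing) fragment, with a
# complete homolog in genome B.
plantSplit <- function(seedval, alsoInB = FALSE) {
    set.seed(seedval)
    gene <- randomAa(200)
    aFrags <- makeOrfs("A", c("a_f1", "a_f2", "a_c1"),
                       c("THREE_PRIME", "FIVE_PRIME", "NONE"),
                       c(substr(gene, 1, 100), substr(gene, 101, 200),
                         randomAa(150)))
    bTrunc <- if (alsoInB) c("NONE", "THREE_PRIME", "FIVE_PRIME")
              else c("NONE", "NONE", "NONE")
    gene2 <- randomAa(180)
    bSeqs <- if (alsoInB)
        c(gene, substr(gene2, 1, 90), substr(gene2, 91, 180))
    else c(gene, randomAa(90), randomAa(90))
    bOrfs <- makeOrfs("B", c("b_g", "b_x1", "b_x2"), bTrunc, bSeqs)
    if (alsoInB) {
        ## genome A carries the complete homolog of B's split gene
        tbA <- orfTable(aFrags)
        aFrags <- makeOrfs("A", c(tbA$orf_id, "a_g2"),
                           c(tbA$truncation, "NONE"),
                           c(as.character(orfSequences(aFrags)), gene2))
    }
    list(A = aFrags, B = bOrfs,
         ab = alignProteomes(aFrags, bOrfs),
         ba = alignProteomes(bOrfs, aFrags))
}

test_that("reciprocal linkage finds planted splits in the right genome", {
    sc <- plantSplit(401)
    res <- linkFragments(sc$A, sc$B, sc$ab, sc$ba)
    expect_identical(nSets(res$sets_a), 1L)
    expect_identical(sort(linkedIds(res$sets_a)), c("a_f1", "a_f2"))
    expect_identical(nSets(res$sets_b), 0L)

    sc2 <- plantSplit(402, alsoInB = TRUE)
    res2 <- linkFragments(sc2$A, sc2$B, sc2$ab, sc2$ba)
    expect_identical(sort(linkedIds(res2$sets_a)), c("a_f1", "a_f2"))
    expect_identical(sort(linkedIds(res2$sets_b)), c("b_x1", "b_x2"))

    empty <- makeOrfs("C", "c1", "NONE", randomAa(100))
    res3 <- linkFragments(sc$B, empty, emptyHits(), emptyHits())
    expect_identical(nSets(res3$sets_a), 0L)
    expect_identical(nSets(res3$sets_b), 0L)
    expect_error(linkFragments(sc$A, sc$A, sc$ab, sc$ba), "collision")
})

test_that("multi-reference linkage accumulates and replaces by identity", {
    set.seed(411)
    geneX <- randomAa(200)
    geneY <- randomAa(200)
    target <- makeOrfs("t",
                       c("x1", "x2", "y1", "y2"),
                       c("THREE_PRIME", "FIVE_PRIME",
                         "THREE_PRIME", "FIVE_PRIME"),
                       c(substr(geneX, 1, 100), substr(geneX, 101, 200),
                         substr(geneY, 1, 100), substr(geneY, 101, 200)))
    ## ref1 carries only gene X (diverged); ref2 carries both, undiverged
    refXdiv <- makeOrfs("r1", "rX", "NONE", as.character(orfSequences(
        mutateProteome(makeOrfs("tmp", "rX", "NONE", geneX), 0.15,
                       seed = 1, genomeId = "r1"))))
    ref2 <- makeOrfs("r2", c("rX", "rY"), c("NONE", "NONE"),
                     c(geneX, geneY))
    h1 <- alignProteomes(target, refXdiv)
    h2 <- alignProteomes(target, ref2)

    one <- linkAgainstReferences(target, list(refXdiv), list(h1))
    direct <- linkFragments(target, refXdiv, h1, emptyHits())
    expect_identical(setTable(one$sets), setTable(direct$sets_a))
    expect_identical(sort(linkedIds(one$sets)), c("x1", "x2"))

    both <- linkAgainstReferences(target, list(refXdiv, ref2),
                                  list(h1, h2))
    expect_identical(both$contributions$n_cumulative, c(2L, 4L))
    expect_true(all(diff(both$contributions$n_cumulative) >= 0))
    ## the X set was replaced by the higher-identity ref2 anchor,
    ## leaving the linked fragments unchanged
    xset <- setTable(both$sets)
    xset <- xset[xset$fragment_id %in% c("x1", "x2"), ]
    expect_identical(unique(xset$reference_genome_id), "r2")
    expect_identical(sort(linkedIds(both$sets)), c("x1", "x2", "y1", "y2"))
})

test_that("merging sets shrinks the inventory by set size minus one", {
    orfs <- makeOrfs("g", sprintf("o%d", 1:10),
                     c(rep("NONE", 8), "THREE_PRIME", "FIVE_PRIME"),
                     vapply(rep(50, 10), randomAa, ""))
    tb <- data.frame(set_id = "s1", genome_id = "g",
                     fragment_id = c("o9", "o10"), member_rank = 1:2,
                     identity = c(95, 95), ref_start = c(1L, 51L),
                     ref_end = c(50L, 100L), reference_protein_id = "R",
                     reference_genome_id = "ref", mean_identity = 95,
                     stringsAsFactors = FALSE)
    inv <- mergeInventory(orfs, FragmentSets(tb))
    expect_identical(nrow(inv), 9L)
    expect_identical(inv$member_ids[inv$unit_id == "s1"], "o9,o10")
    expect_identical(nrow(mergeInventory(orfs, FragmentSets())), 10L)
    twice <- rbind(tb, within(tb, set_id <- "s2"))
    expect_error(mergeInventory(orfs, FragmentSets(twice)), "overlapping")
})

test_that("emitted sets respect all caps and are order-deterministic", {
    for (seedval in c(501, 502)) {
        cfg <- fixtureConfig(seed = seedval, n_genes = 50, break_rate = 1,
                             paralog_count = 4)
        fx <- buildFixture(cfg)
        fragIds <- names(which(isPartial(fx$orfs)))
        hits <- alignProteomes(fx$orfs, fx$reference, queryIds = fragIds)
        res <- linkAgainstReferences(fx$orfs, list(fx$reference),
                                     list(hits))
        tb <- setTable(res$sets)
        trunc <- truncation(fx$orfs)
        for (s in split(tb, tb$set_id)) {
            expect_lte(sum(trunc[s$fragment_id] %in%
                           c("FIVE_PRIME", "THREE_PRIME")), 2)
            expect_lte(max(s$identity) - min(s$identity), 40)
            n <- nrow(s)
            ov <- outer(seq_len(n), seq_len(n), function(i, j)
                pmax(0, pmin(s$ref_end[i], s$ref_end[j]) -
                        pmax(s$ref_start[i], s$ref_start[j]) + 1))
            diag(ov) <- 0
            expect_lte(max(ov), 10)
        }
        ## shuffling the hit table must not change the outcome
        set.seed(1)
        shuffled <- hits[sample(nrow(hits)), ]
        res2 <- linkAgainstReferences(fx$orfs, list(fx$reference),
                                      list(shuffled))
        expect_identical(setTable(res2$sets), tb)
    }
})

test_that("raising the identity threshold never links more fragments", {
    cfg <- fixtureConfig(seed = 503, n_genes = 60, break_rate = 1,
                         reference_divergence = 0.2)
    fx <- buildFixture(cfg)
    fragIds <- names(which(isPartial(fx$orfs)))
    hits <- alignProteomes(fx$orfs, fx$reference, queryIds = fragIds)
    linked <- vapply(c(30, 50, 70, 90), function(thr) {
        res <- linkAgainstReferences(fx$orfs, list(fx$reference), list(hits),
                                     LinkageParams(minIdentityPct = thr))
        length(linkedIds(res$sets))
    }, 0L)
    expect_true(all(diff(linked) <= 0))
})
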