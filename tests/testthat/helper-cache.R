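# The standard synthetic study conditions: 1,000 genes, Poisson(0.5) breaks,
# 10% reference divergence, 30-aa caller minimum, full scaffold coverage.
# Built lazily and shared across test files within one run.
defaultFixtureRun <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        cfg <- fixtureConfig(seed = 11, n_genes = 1000, break_rate = 0.5,
                             min_fragment_aa = 30,
                             reference_divergence = 0.10,
                             scaffold_fraction = 1.0)
        fx <- buildFixture(cfg)
        fragIds <- names(which(isPartial(fx$orfs)))
        hits <- alignProteomes(fx$orfs, fx$reference, queryIds = fragIds)
        res <- linkAgainstReferences(fx$orfs, list(fx$reference), list(hits))
        ev <- evaluateSets(res$sets, fx$orfs, fx$scaffolds, length(fragIds))
        cache <<- list(cfg = cfg, fx = fx, fragIds = fragIds, hits = hits,
                       res = res, ev = ev)
        cache
    }
})

# Recall of planted adjacent fragment pairs: fraction of truth-adjacent kept
# pairs whose two members ended up in the same emitted set.
linkageRecall <- function(sets, truth) {
    adj <- truth$adjacencies
    if (nrow(adj) == 0L) return(NaN)
    tb <- setTable(sets)
    setOf <- tapply(tb$set_id, tb$fragment_id, `[`, 1L)
    s1 <- setOf[adj$fragment_1]
    s2 <- setOf[adj$fragment_2]
    mean(!is.na(s1) & !is.na(s2) & s1 == s2)
}

# Fraction of emitted within-set consecutive pairs joining fragments of
# different genes (truth-based false links).
truthFalseRate <- function(sets, truth) {
    tb <- setTable(sets)
    if (nrow(tb) == 0L) return(0)
    geneOf <- stats::setNames(truth$fragments$gene_id,
                              truth$fragments$fragment_id)
    bad <- 0L; total <- 0L
    for (s in split(tb, tb$set_id)) {
        s <- s[order(s$member_rank), ]
        g <- geneOf[s$fragment_id]
        total <- total + nrow(s) - 1L
        bad <- bad + sum(g[-1L] != g[-length(g)])
    }
    bad / max(1L, total)
}
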