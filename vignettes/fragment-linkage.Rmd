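---
title: "Homology-based linkage of gene fragments in draft genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based linkage of gene fragments in draft genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragLink)
```

## The problem

Draft bacterial genomes are collections of contigs, and genes that happen
to span a contig boundary are predicted as two or more *ORF fragments*:
partial genes truncated at a contig end. Fragmentation has two corrosive
effects on downstream analysis. First, one gene is counted several times,
inflating gene inventories and annotation tallies. Second, each fragment
carries only part of the protein, weakening homology searches and
domain-based annotation. The mitigation implemented here follows the
strategy of Klassen & Currie (*BMC Genomics* 2012, 13:14): place a
genome's ORF fragments onto complete homologous proteins from related
genomes, and link fragments that tile the same reference protein into a
single *fragment set* representing one gene.

`fragLink` implements that pipeline end to end:

1. **Survey** — parse gene-caller output (Prodigal-style `partial=`
   flags), classify each ORF's truncation state, and compute assembly
   statistics (N50, %GC deviation, % partial ORFs).
2. **Homology** — Smith–Waterman protein alignment (BLOSUM62, affine
   gaps), best-hit tables, bidirectional best hits, average amino-acid
   identity (AAI), and neighbor-joining trees from AAI distances.
3. **Linkage** — the core contribution: assemble fragment sets on
   complete reference homologs under explicit thresholds, reciprocally
   in both genomes, over any number of reference proteomes.
4. **Validation** — classify linked pairs against scaffold adjacency as
   TRUE / FALSE / UNKNOWN, and sweep thresholds over a grid.
5. **Annotation impact** — annotation rates before and after merging
   fragment sets, category profiles of partial versus complete ORFs, and
   quality-versus-annotation correlations.
6. **Synthetic fixtures** — a generator that fragments a known proteome
   and keeps the ground truth, so recall and false-link rates are
   measurable.

## Truncation model

Truncation is strand-relative. A fragment missing its start codon is
5'-truncated (`FIVE_PRIME`), one missing its stop codon is 3'-truncated
(`THREE_PRIME`), and an internal piece is truncated at both ends
(`BOTH`). Prodigal's `partial=XY` flags are *genomic*: `X` marks the
contig's left edge, `Y` the right. For a plus-strand gene the left edge
is the 5' side; for a minus-strand gene it is the 3' side.
`readProteins()` performs this conversion and records the genomic
coordinates and strand of every ORF.

## The linkage algorithm

Fragments of one genome are aligned against the *complete* proteins of a
reference proteome. A placement is a candidate when:

* **(i) identity** — percent identity ≥ `minIdentityPct` (default 30);
* **(ii) overlap** — the alignment covers ≥ `minOverlapFrac` (default
  0.7) of the *fragment's* length, so short fragments must be explained
  almost entirely by the reference.

Sets are then assembled greedily per reference protein, seeding with the
highest-identity placement and admitting further fragments only if:

* **(iii) identity spread** — every member's identity is within
  `maxIdentitySpreadPct` (default 40) points of the seed, rejecting
  mixtures of a true homolog and a distant paralog;
* **(iv) tiling** — members overlap each other on the reference by at
  most `maxFragmentOverlapAa` residues (default 10): fragments of one
  gene should tile, while paralogs co-cover;
* **budget** — at most `maxSingleEndTruncated` (default 2)
  single-end-truncated members per set, since one gene has one start
  and one stop; internal `BOTH` pieces are unlimited;
* **end order** (`enforceEndOrder`, default `TRUE`) — when ordered along
  the reference, a 3'-truncated (start-bearing) member may only sit
  leftmost and a 5'-truncated (stop-bearing) member only rightmost.

On point (iii), the source publication words the criterion as a bound on
the identity *difference* among members of a set; we implement it as a
maximum spread relative to the seed placement, with the published value
(40 percentage points) as the default. The two readings coincide for
two-member sets, which dominate in practice.

Linkage is reciprocal (each genome's fragments are placed on the other's
complete proteins) and accumulates over many references:
`linkAgainstReferences()` processes references in order, keeps every
candidate set, and resolves conflicts globally — when one fragment is
claimed by two sets, the set with the higher mean identity wins (ties:
more members, then lexicographic identifiers). A set built on a closer
reference therefore *replaces* one built earlier on a more distant
reference, and `contributions` records how many fragments each reference
added. `mergeInventory()` finally collapses each set into a single
inventory unit.

## Scaffold validation

When scaffold data exist (mate pairs ordered the contigs), a linked pair
can be checked: the two fragments must sit on distinct contigs that are
consecutive in one scaffold, and — in the default `strict` mode — each
fragment's truncated side must face the inter-contig gap after applying
the scaffold's contig orientations. `evaluateSets()` aggregates at the
fragment level (a fragment is falsely linked if *any* of its junctions
fails) and reports percentages of the genome's partial-ORF total.
Fragments on unplaced contigs are `UNKNOWN` and excluded from the
false-positive denominator. `gridSearch()` repeats linkage plus
validation over threshold grids.

## Numerical choices

* Alignment is `Biostrings::pairwiseAlignment()` with BLOSUM62, gap
  open 11, gap extend 1 (BLAST-like conventions); percent identity is
  matches over alignment columns. Full pairwise alignment of proteomes
  is avoided with a shared 6-mer prescreen (`alignProteomes()`), which
  aligns each query only against the subjects sharing words with it.
* AAI follows the common operational definition: bidirectional best
  hits between complete proteins, both directions ≥ 30% identity with
  alignments covering ≥ 70% of *both* sequences, pair identity the mean
  of the two directions, AAI the unweighted mean over pairs. Distance is
  `100 − AAI`; trees come from `ape::nj()` with negative branch lengths
  clamped to zero.
* N50 uses the "at least half the assembly" convention.
* Printed percentages are rounded half away from zero to one decimal
  (`roundHalfUp()`), matching how genome tables are conventionally
  reported; full-precision values are always available alongside.
* Pearson correlations use `stats::cor.test()` (two-sided t test).

## The synthetic fixture

`buildFixture()` creates a measurable analogue of a draft genome:
random proteins (uniform residues, 100–600 aa), per-gene Poisson breaks
(`break_rate`), pieces below `min_fragment_aa` dropped as typical
gene-caller minimums, reverse translation with uniform codon choice,
flanks on non-broken contig sides, minus-strand genes, occasional
stored-contig flips recorded as `-` orientations in the scaffold, a
diverged complete reference proteome (`reference_divergence`), and
optional near-identical paralog decoys as false-link bait. The `truth`
slot records every piece's parent gene and the truly adjacent kept
pairs, so recall and false-link rates can be computed exactly.

Limits worth keeping in mind: uniform residue composition has no
low-complexity or repeat structure, divergence is substitution-only (no
indels), and each fragmented gene gets its own scaffold. Real genomes
are harder in all three respects, which is why the thresholds default to
the published, conservatively validated values rather than anything
tuned on the fixture.

```{r example, eval = FALSE}
cfg <- fixtureConfig(seed = 1, n_genes = 1000, break_rate = 0.5,
                     reference_divergence = 0.10)
fx <- buildFixture(cfg)
fragIds <- names(which(isPartial(fx$orfs)))
hits <- alignProteomes(fx$orfs, fx$reference, queryIds = fragIds)
res <- linkAgainstReferences(fx$orfs, list(fx$reference), list(hits))
evaluateSets(res$sets, fx$orfs, fx$scaffolds, length(fragIds))
```

## Problem sizes

A 1,000-gene fixture (about 1,400 ORFs, 800 fragments) aligns and links
in roughly two minutes on one CPU. For real proteomes (2,000–10,000
proteins per genome, several references) the intended route is to
supply externally computed hit tables (BLAST/DIAMOND `-outfmt 6`) via
the `hitTables` arguments or the CLI's `--hits` flags; the internal
aligner is exact but not built for all-versus-all scans of that size.

## Reproducing the published false-positive bound at full scale

The original validation linked fragments across dozens of draft
genome projects and bounded the false-link rate below 2% using
scaffold adjacency. The equivalent full-scale recipe with this package:

1. Download the draft assemblies' contigs, scaffolds (AGP) and
   predicted proteomes for the genome panel of interest.
2. Run the gene caller (Prodigal) to obtain `partial=` flags; read with
   `readProteins()`.
3. Compute all-versus-all hit tables with an external aligner and read
   them with `readHits()`.
4. For each target genome, run `linkAgainstReferences()` with the
   remaining genomes as references, then `evaluateSets()` against the
   AGP scaffolds (`readScaffoldMap(..., "agp")`).
5. Pool `n_false` over genomes and divide by pooled judged fragments.

This is a multi-CPU-hour computation and is not part of the test suite;
the suite verifies the same bound on the synthetic fixture, where truth
is exact.

## Limitations

* Linkage requires a complete homolog in some reference: genes absent
  from all references, or fragmented in every genome, cannot be linked.
* Paralog families more similar than the identity-spread threshold can
  still produce false links; the scaffold check is the safety net.
* The aligner reports raw Smith–Waterman scores, not e-values; hit
  tables carry a placeholder e-value of 0 and ranking uses bitscore.
* Sequence-based validation (e.g. re-assembling the joined gene) is out
  of scope; validation is purely positional.
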