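---
title: "Quantifying gene block evolution with event distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene block evolution with event distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoblockr)
```

## The problem and the model

Bacterial genomes keep functionally related genes physically clustered:
gene blocks, and, when the genes are co-transcribed to a polycistronic
mRNA, operons. The clustering is conserved across species, but rarely
perfectly: blocks split apart, lose genes, gain duplicate copies. This
package treats those changes as countable *events*, with the gene --
not the nucleotide -- as the atomic unit of change, and measures how
conserved a block is by how few events separate its realizations in
different taxa.

Everything is anchored to a **reference taxon** whose operons are known
from experiment (for enterobacteria, typically *E. coli* K-12 with its
RegulonDB annotation). The core definitions:

* **Neighboring genes**: at most 500 bp apart (intergenic gap
  `start(next) − end(prev) − 1` on 1-based inclusive coordinates) *and*
  on the same strand. Overlapping genes (gap ≤ 0) are neighboring. A
  gene moving to the other strand therefore severs the relation no
  matter how close it remains, which is how strand reversals surface as
  splits.
* **Gene block**: two or more neighboring ORFs.
* **Homologs**: BLAST e-value ≤ 1e-10, inclusively. The threshold is
  deliberately strict -- it trades false-negative homologs for almost no
  false positives, so an apparent deletion may occasionally be a
  diverged gene rather than a lost one.
* **Orthoblock**: for a reference block and a target genome, the
  selected homologs that include at least two neighboring genes. A
  genome with homologs scattered as singletons has *no* orthoblock, and
  contributes no pairwise comparisons -- treating it as distance zero
  would fake perfect conservation.

## Ortholog selection by genomic context

A reference gene often has several homologs in a target genome. Rather
than best-reciprocal-hit (which assumes the ortholog is always the most
similar copy), selection uses synteny. Candidate homologs are grouped
into neighbor blocks, and a subset of blocks is chosen to optimize,
lexicographically:

1. **most distinct reference genes represented inside blocks**,
2. **fewest duplicate labels** (selected genes beyond one per
   reference gene),
3. **fewest blocks**.

Ties are broken toward the leftmost blocks in genome coordinates, so
the result is deterministic under any permutation of the inputs. The
three canonical situations: between groups `(abcd)` and `(abc)` the
four-gene block wins (adding `(abc)` would only add duplicates);
between `(abcd)` alone and `((abc),(de))` the two-block choice wins
because it represents five reference genes instead of four; between
`((abc),(de))` and `((abcd),(de))` the former wins because it carries
no duplicate `d`.

Chosen blocks are taken whole: a duplicated copy *inside* a chosen
block is kept, because within-block duplications are exactly what the
duplication distance must see. The duplication-minimizing criterion
arbitrates among alternative block sets, not within a block. When a
candidate gene is homologous to several reference genes, labels are
assigned by maximum bipartite matching (one label per gene -- a single
target gene never carries two labels); a gene left unmatched keeps its
alphabetically first candidate label and counts as a duplicate.

With at most `exhaustive_limit = 12` candidate genes the search over
block subsets is exhaustive, so the lexicographic optimum is
guaranteed (the test suite checks this against an independent
brute-force enumeration of block subsets and explicit label
assignments). Above that, a greedy search seeds from the largest
block, adds blocks while the objective improves, and prunes blocks
whose removal loses nothing. Twelve keeps the exhaustive guarantee for
every realistic operon-sized instance while bounding the subset
enumeration at 2^6 blocks.

## Event distances

For two taxa *i*, *j* that both have the orthoblock, with per-gene copy
counts `c_i(g)`, `c_j(g)` over the reference genes:

* **Split distance** `d_s = |B_i − B_j|`, the absolute difference in
  neighbor-block counts.
* **Deletion distance** `d_d = |{g : exactly one of c_i(g), c_j(g) is
  0}|`, the symmetric difference of presence sets. Genes absent from
  both taxa are ignored even when present in the reference.
* **Duplication distance** `d_u = Σ_g [max(c) − max(1, min(c))]` over
  genes with `max(c_i(g), c_j(g)) ≥ 2`. The formula generalizes the
  two canonical cases -- copies 1 vs 2 cost one duplication; copies 0
  vs 2 cost one duplication *and* one deletion, the most parsimonious
  history through a single-copy ancestor -- and never double-charges
  copy-number differences to deletions.

All three are symmetric with zero self-distance; split (an absolute
difference of a function) and deletion (a symmetric-difference metric)
also satisfy the triangle inequality. A pair in which either taxon
lacks the orthoblock is *undefined* and excluded from matrices.

Conservation is ranked by the cumulative number of events per genome
pair: `score = Σ_pairs (d_s + d_d + d_u) / n_pairs`, ascending (most
conserved first). The unnormalized sum is available via
`normalize = FALSE`.

## Phylomatrices

For one block and one event type *v*, the phylomatrix entry is the
z-score `M_ij = (d_v(i,j) − x̄) / σ`, with mean and standard deviation
taken over the `n_p` unordered pairs of taxa sharing the orthoblock
(diagonal excluded). σ is the *population* SD over those pairs --
the pairs are the entire population being displayed, not a sample --
with `sd_type = "sample"` available. Two numerical conventions keep
degenerate panels well defined: when σ = 0 (a uniformly conserved
panel) every entry is 0, not NaN; and normalization is per (block,
event) panel, never pooled across blocks. The same participating-taxa
set is used for all three event types of a block.

Axes follow the left-to-right leaf order of the supplied tree; labels
must match exactly (no fuzzy matching -- a mismatch is an error listing
the missing taxa). Taxa lacking the orthoblock are rendered in a
reserved third color (green) distinct from the blue (conserved, low
z-score) to red (divergent) diverging scale, and every image gets a
bit-exact TSV twin so rendering never hides values.

## The simulator

The measurement method needs data with known answers; real genomes
never come with ground truth. `simulate_blocks()` evolves an intact
block along a tree: per branch, each event type fires a
Poisson-distributed number of times with mean `rate × branch length`,
and targets are chosen uniformly among eligible gene copies or cut
points. Splits relocate a contiguous block suffix to a locus 10 kb
away -- 20 times the 500-bp threshold, so the neighboring relation is
guaranteed severed; strand reversals do the same and flip the strand.
Deletions remove one gene copy; duplications insert an adjacent copy.
Leaf genomes are serialized with 900-bp genes and 50-bp within-block
gaps (typical bacterial scales; the gap is comfortably under 500 so
undisturbed blocks stay intact), and every descendant copy is linked
to its reference gene at a synthetic e-value of 1e-50. The event
counts are Poisson and placement uniform as a deliberate modeling
choice: the measurement method is event-count-based, so any
count-correct generative process exercises it.

`injected_events` bypasses the Poisson draws and places an exact event
list on named branches; `sample_noninteracting_events()` draws
deletion/duplication events on distinct genes, the configuration in
which the inferred deletion and duplication matrices equal the
ground-truth path sums exactly. A deletion may shrink a block below
two genes; the orthoblock then ceases to exist for that leaf, which
deliberately exercises the absent-orthoblock pathway.

What the simulator does *not* emulate: sequence-level divergence (so
no genuine borderline e-values or false-negative homologs),
horizontal transfer, rearrangements within blocks, gene fusion or
fission, plasmids, or multi-contig assemblies. Passing recovery tests
therefore shows the *measurement* machinery is correct, not that the
strict homology threshold is well calibrated for diverged real
genomes.

## Known limitations

* The recovery guarantee is per event type. Mixed histories can
  *overcount*: a duplication above the most recent common ancestor
  followed by deletion of one copy in one lineage leaves copy counts
  2 vs 1, which the single-copy-ancestor parsimony rule charges as a
  duplication on the path even though the path carries a deletion.
  The inferred-≤-path-sum bound asserted by the property tests
  accordingly holds within deletion-only, duplication-only and
  split-only histories.
* Split distance saturates: once a block fully dissolves in one taxon
  the orthoblock disappears and the pair stops being compared, so
  heavily shattered blocks are compared over fewer pairs.
* The 500-bp rule is applied within contigs only; blocks never span
  contig boundaries.
* Whether a census of "orthoblocks in at least nine other genomes"
  passes depends on the genome set supplied; the filter is off by
  default in `run_pipeline()` so small studies see all their blocks,
  and on request via `apply_filters = TRUE` with thresholds
  `min_genes = 5`, `min_orthoblock_taxa = 9`.

## Problem sizes used in the test suite

The package's own validation runs at desk scale: 6-leaf trees,
blocks of 5--9 genes, 100 seeded replicates of the non-interacting
recovery check, 1000 random orthoblock triples for the metric
properties, and 30 random instances (5--9 candidate genes) for the
exhaustive-search agreement -- sizes chosen so the whole suite runs in
well under a minute while every code path, including degenerate ones
(empty genomes, absent orthoblocks, σ = 0 panels), is exercised.
```{r example}
ref <- reference_block("demo", letters[1:7], "ref")
A <- orthoblock_from_layout(ref, "A", list(c("a","b","c"), c("d","e","f","g")))
B <- orthoblock_from_layout(ref, "B", list(c("a","b","c"), c("d","e"), c("f","g")))
split_distance(A, B)
```
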