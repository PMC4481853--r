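# orthoblockr

Event-based analysis of gene block and operon evolution in bacteria.

Bacterial genomes cluster functionally related genes into gene blocks
and operons, and the clustering is conserved between species — but not
perfectly. `orthoblockr` quantifies that conservation by treating
changes in block structure as countable events, with the **gene** as
the atomic unit of change. For every pair of taxa sharing an
orthologous gene block ("orthoblock"), it counts three event types
relative to a curated reference operon set:

- **splits** `d_s(i,j) = |B_i − B_j|`, the absolute difference in the
  number of neighbor blocks the homologs form (a strand reversal
  severs the neighboring relation and so registers as a split);
- **deletions** `d_d(i,j)`, the number of reference genes present in
  exactly one of the two orthoblocks (symmetric difference of
  presence sets);
- **duplications** `d_u(i,j) = Σ_g max(c_i, c_j) − max(1, min(c_i, c_j))`
  over genes with at least two copies in one taxon, i.e. the most
  parsimonious duplication count through a single-copy ancestor.

Two genes are *neighboring* when ≤ 500 bp apart on the same strand;
*homologs* are BLAST hits at e-value ≤ 1e-10 (inclusive); an
*orthoblock* exists in a genome when at least two neighboring homologs
of the reference block are found there. Orthologs are selected by
genomic context, not best-reciprocal-hit: among candidate homolog
groupings the package maximizes the number of distinct reference genes
recovered in blocks, then minimizes duplicate copies, then the number
of blocks. Pairwise distances are summarized as conservation rankings
(events per genome pair) and as **phylomatrices** — species × species
heatmaps of z-normalized distances, `M_ij = (d_v(i,j) − x̄)/σ`, axes
ordered by a phylogeny, blue = conserved, red = divergent, green = no
data.

The package is aimed at comparative genomicists studying operon
formation and decay: it consumes standard GFF3 (or a plain gene-table
TSV), BLAST tabular output (outfmt 6), a reference operon list, and a
Newick tree. A forward simulator of gene block evolution provides
synthetic data with ground-truth event logs, so the whole measurement
chain is testable without downloading genomes.

## Worked example

The canonical split-distance situation: a 7-gene reference block
`(abcdefg)` whose homologs form two blocks in genome A and three in
genome B.

```r
library(orthoblockr)

ref <- reference_block("atp_like", letters[1:7], "ref")
A <- orthoblock_from_layout(ref, "A", list(c("a","b","c"), c("d","e","f","g")))
B <- orthoblock_from_layout(ref, "B", list(c("a","b","c"), c("d","e"), c("f","g")))
A
#> Orthoblock 'atp_like' in genome 'A': 2 block(s)
#>   (a b c)  [a_1, b_1, c_1]
#>   (d e f g)  [d_1, e_1, f_1, g_1]
split_distance(A, B)
#> [1] 1
```

A's homologs form 2 blocks, B's form 3, so one split event separates
them. An end-to-end run on simulated data — six leaf genomes evolved
from a 6-gene block under split/deletion/duplication events, then
measured back:

```r
sim <- simulate_blocks("((A:1,B:1):1,((C:1,D:1):1,(E:1,F:1):1):1);",
                       n_genes = 6,
                       rates = c(split = 0.3, deletion = 0.3, duplication = 0.2),
                       seed = 42)
dir <- tempfile(); write_simulation(sim, dir)
res <- run_pipeline(run_config(
  annotations_dir = file.path(dir, "annotations"),
  blocks_file     = file.path(dir, "blocks.tsv"),
  hits_file       = file.path(dir, "hits.tsv"),
  tree_file       = file.path(dir, "tree.nwk"),
  out_dir         = tempfile()))
res$ranking
#>   block_name n_pairs total_events    score
#> 1   simblock      15           76 5.066667
round(res$phylomatrices[["simblock_deletion"]]$values, 2)
#>       A     B     C     D     E     F
#> A -2.80 -2.80  0.56  0.56  1.40 -0.28
#> B -2.80 -2.80  0.56  0.56  1.40 -0.28
#> C  0.56  0.56 -2.80 -1.12 -0.28 -0.28
#> ...
```

The ranking says this block accumulated on average ~5.1 events per
genome pair (a poorly conserved block at these rates); in the deletion
phylomatrix the sister taxa A and B (z = −2.8 between them, the
minimum) kept identical gene content while pairs straddling deeper
branches are redder. The pipeline writes `orthoblocks.tsv`,
`distances.tsv`, `ranking.tsv`, `census.tsv`, per-(block, event)
phylomatrix TSVs (and optional PNG heatmaps), and a `manifest.json`
recording inputs, parameters and per-stage counts.

A thin command-line wrapper lives at `inst/cli/gene-block-events.R`
(subcommands `simulate` and `run`).

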