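# Fixture builders and independent oracles shared across test files.

# Compact annotation builder: genes = list of c(gene_id, contig, start,
# end, strand)
ann_from_genes <- function(genome_id, genes) {
  rows <- lapply(genes, function(g) {
    data.frame(genome_id = genome_id, contig_id = g[[2]],
               gene_id = g[[1]], start = as.integer(g[[3]]),
               end = as.integer(g[[4]]), strand = g[[5]],
               stringsAsFactors = FALSE)
  })
  genome_annotation(do.call(rbind, rows))
}

# Hits table builder: rows = list of c(query, subject, genome, evalue)
hits_from_rows <- function(rows) {
  if (length(rows) == 0L) {
    h <- data.frame(query_gene_id = character(),
                    subject_gene_id = character(),
                    subject_genome_id = character(),
                    evalue = numeric(), bitscore = numeric(),
                    stringsAsFactors = FALSE)
  } else {
    h <- do.call(rbind, lapply(rows, function(r) {
      data.frame(query_gene_id = r[[1]], subject_gene_id = r[[2]],
                 subject_genome_id = r[[3]],
                 evalue = as.numeric(r[[4]]), bitscore = 100,
                 stringsAsFactors = FALSE)
    }))
  }
  class(h) <- c("homology_hits", "data.frame")
  h
}

write_blast_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

blast_row <- function(q, s, evalue, bitscore = 100) {
  paste(q, s, "99.0", "300", "1", "0", "1", "300", "1", "300",
        format(evalue), format(bitscore), sep = "\t")
}

# ---- independent oracle for ortholog selection -----------------------
# Independent re-derivation of the selection objective: neighbor blocks
# are grouped with a simple quadratic scan, and the optimum is found by
# enumerating every block subset and every explicit label assignment
# (no matching algorithm involved).
oracle_neighbor_blocks <- function(ann, candidates, max_gap) {
  rows <- ann[ann$gene_id %in% candidates, , drop = FALSE]
  out <- list()
  for (contig in unique(rows$contig_id)) {
    for (strand in c("+", "-")) {
      g <- rows[rows$contig_id == contig & rows$strand == strand, ,
                drop = FALSE]
      if (nrow(g) == 0L) next
      g <- g[order(g$start), , drop = FALSE]
      run <- g$gene_id[1L]
      for (i in seq_len(nrow(g))[-1L]) {
        if (g$start[i] - g$end[i - 1L] - 1L <= max_gap) {
          run <- c(run, g$gene_id[i])
        } else {
          if (length(run) >= 2L) out[[length(out) + 1L]] <- run
          run <- g$gene_id[i]
        }
      }
      if (length(run) >= 2L) out[[length(out) + 1L]] <- run
    }
  }
  out
}

# Best achievable objective tuple (distinct labels, -duplicates,
# -block count) over all block subsets and label assignments.
oracle_best_tuple <- function(ann, label_sets, max_gap) {
  blocks <- oracle_neighbor_blocks(ann, names(label_sets), max_gap)
  if (length(blocks) == 0L) return(NULL)
  best <- NULL
  n_blocks <- length(blocks)
  for (mask in seq_len(2^n_blocks - 1L)) {
    subset <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n_blocks) - 1L))
                    != 0L)
    genes <- unlist(blocks[subset])
    sets <- label_sets[genes]
    grids <- do.call(expand.grid,
                     c(lapply(sets, identity),
                       list(stringsAsFactors = FALSE)))
    for (r in seq_len(nrow(grids))) {
      assignment <- unlist(grids[r, , drop = FALSE], use.names = FALSE)
      tup <- c(length(unique(assignment)),
               -(length(genes) - length(unique(assignment))),
               -length(subset))
      if (is.null(best) || tuple_gt_oracle(tup, best)) best <- tup
    }
  }
  best
}

tuple_gt_oracle <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] > b[k]) return(TRUE)
    if (a[k] < b[k]) return(FALSE)
  }
  FALSE
}

# Objective tuple realized by a returned orthoblock
realized_tuple <- function(ob) {
  c(length(unique(ob$labeling)),
    -(length(ob$labeling) - length(unique(ob$labeling))),
    -length(ob$blocks))
}

# Random small selection instance; returns list(ann, hits, block, map)
random_selection_instance <- function(n_ref = 5L, n_cand = 7L,
                                      max_gap = 500L) {
  ref <- reference_block("rnd", letters[seq_len(n_ref)], "ref")
  gene_ids <- sprintf("t%02d", seq_len(n_cand))
  contigs <- sample(c("c1", "c1", "c2"), n_cand, replace = TRUE)
  strands <- sample(c("+", "+", "-"), n_cand, replace = TRUE)
  rows <- list()
  cursor <- c(c1 = 1L, c2 = 1L)
  for (i in seq_len(n_cand)) {
    ct <- contigs[i]
    gap <- sample(c(10L, 100L, 400L, 800L, 2000L), 1L)
    start <- cursor[[ct]] + gap
    rows[[i]] <- c(gene_ids[i], ct, start, start + 299L, strands[i])
    cursor[[ct]] <- start + 300L
  }
  ann <- ann_from_genes("T", rows)
  hit_rows <- list()
  for (i in seq_len(n_cand)) {
    labs <- sample(ref$gene_ids, sample(1:2, 1L, prob = c(0.7, 0.3)))
    for (lab in labs) {
      hit_rows[[length(hit_rows) + 1L]] <- c(lab, gene_ids[i], "T", 1e-30)
    }
  }
  hits <- hits_from_rows(hit_rows)
  map <- build_homolog_map(hits, ref, "T")
  list(ann = ann, hits = hits, block = ref, map = map)
}

# Random orthoblock over a fixed reference block (for metric properties)
random_orthoblock <- function(block, genome_id) {
  labs <- block$gene_ids
  n_loci <- sample(1:3, 1L)
  layout <- list()
  for (k in seq_len(n_loci)) {
    size <- sample(2:4, 1L)
    layout[[k]] <- sample(labs, size, replace = TRUE)
  }
  orthoblock_from_layout(block, genome_id, layout)
}

# Run the measurement chain (homology -> orthoblock -> events) on a
# simulation, in memory, and return the per-event distance matrices over
# the leaves (ordered as tree tip labels).
infer_event_matrices <- function(sim) {
  leaves <- sim$tree$tip.label
  obs <- lapply(stats::setNames(nm = leaves), function(gid) {
    hm <- build_homolog_map(sim$hits, sim$block, gid)
    select_orthologs(hm, sim$annotations[[gid]], sim$block)
  })
  lapply(stats::setNames(nm = c("split", "deletion", "duplication")),
         function(ev) {
           m <- all_pairs_distances(obs, sim$block, ev)
           full <- matrix(NA_real_, length(leaves), length(leaves),
                          dimnames = list(leaves, leaves))
           full[rownames(m), colnames(m)] <- m
           full
         })
}
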