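test_that("neighboring rule: 500 bp joins, 501 severs, strands sever", {
  # gap = start(next) - end(prev) - 1
  ann500 <- ann_from_genes("G", list(c("x", "c1", 1, 900, "+"),
                                     c("y", "c1", 1401, 2300, "+")))
  nb <- find_neighbor_blocks(ann500, c("x", "y"))
  expect_length(nb$blocks, 1L)
  expect_equal(nb$blocks[[1L]]$gene_ids, c("x", "y"))

  ann501 <- ann_from_genes("G", list(c("x", "c1", 1, 900, "+"),
                                     c("y", "c1", 1402, 2300, "+")))
  nb <- find_neighbor_blocks(ann501, c("x", "y"))
  expect_length(nb$blocks, 0L)
  expect_equal(sort(nb$singletons), c("x", "y"))

  ann_rev <- ann_from_genes("G", list(c("x", "c1", 1, 900, "+"),
                                      c("y", "c1", 911, 1800, "-")))
  nb <- find_neighbor_blocks(ann_rev, c("x", "y"))
  expect_length(nb$blocks, 0L)
})

test_that("overlapping genes are neighboring; contigs are never spanned", {
  ann <- ann_from_genes("G", list(c("x", "c1", 1, 900, "+"),
                                  c("y", "c1", 850, 1700, "+"),
                                  c("z", "c2", 1710, 2500, "+")))
  nb <- find_neighbor_blocks(ann, c("x", "y", "z"))
  expect_length(nb$blocks, 1L)
  expect_equal(nb$blocks[[1L]]$gene_ids, c("x", "y"))
  expect_equal(nb$singletons, "z")
})

test_that("every returned block satisfies the gap and strand invariants", {
  set.seed(7)
  for (rep in 1:20) {
    inst <- random_selection_instance()
    nb <- find_neighbor_blocks(inst$ann, inst$ann$gene_id)
    for (b in nb$blocks) {
      rows <- inst$ann[match(b$gene_ids, inst$ann$gene_id), ]
      expect_true(all(rows$contig_id == b$contig_id))
      expect_true(all(rows$strand == b$strand))
      if (nrow(rows) > 1L) {
        gaps <- rows$start[-1L] - rows$end[-nrow(rows)] - 1L
        expect_true(all(gaps <= 500L))
      }
    }
  }
})

ref6 <- reference_block("ex", c("a", "b", "c", "d", "e", "f"), "ref")

test_that("selection prefers the block covering more reference genes", {
  ob <- orthoblock_from_layout(ref6, "T",
                               list(c("a", "b", "c", "d"),
                                    c("a", "b", "c")))
  expect_length(ob$blocks, 1L)
  expect_setequal(unname(ob$labeling), c("a", "b", "c", "d"))
})

test_that("selection recovers more genes in more blocks over fewer in one", {
  ob <- orthoblock_from_layout(ref6, "T",
                               list(c("a", "b", "c", "d"),
                                    c("a", "b", "c"),
                                    c("d", "e")))
  expect_length(ob$blocks, 2L)
  labs <- lapply(ob$blocks, function(b) unname(ob$labeling[b$gene_ids]))
  expect_setequal(unlist(labs), c("a", "b", "c", "d", "e"))
  expect_equal(sum(duplicated(unlist(labs))), 0L)
})

test_that("selection minimizes duplications at equal gene recovery", {
  ob <- orthoblock_from_layout(ref6, "T",
                               list(c("a", "b", "c"),
                                    c("d", "e"),
                                    c("a", "b", "c", "d")))
  expect_length(ob$blocks, 2L)
  sizes <- sort(vapply(ob$blocks, function(b) length(b$gene_ids),
                       integer(1L)))
  expect_equal(sizes, c(2L, 3L))
  expect_equal(anyDuplicated(unname(ob$labeling)), 0L)
})

test_that("no orthoblock exists when no two homologs are neighboring", {
  ref <- reference_block("blk", c("a", "b"), "ref")
  ann <- ann_from_genes("T", list(c("t1", "c1", 1, 900, "+"),
                                  c("t2", "c1", 50000, 50900, "+")))
  hits <- hits_from_rows(list(c("a", "t1", "T", 1e-50),
                              c("b", "t2", "T", 1e-50)))
  map <- build_homolog_map(hits, ref, "T")
  expect_null(select_orthologs(map, ann, ref))
})

test_that("selection is deterministic under input permutation", {
  set.seed(11)
  for (rep in 1:10) {
    inst <- random_selection_instance()
    ob1 <- select_orthologs(inst$map, inst$ann, inst$block)
    perm <- sample(nrow(inst$hits))
    map2 <- build_homolog_map(inst$hits[perm, ], inst$block, "T")
    ann2 <- inst$ann[sample(nrow(inst$ann)), ]
    ann2 <- genome_annotation(ann2)
    ob2 <- select_orthologs(map2, ann2, inst$block)
    expect_equal(is.null(ob1), is.null(ob2))
    if (!is.null(ob1)) {
      expect_equal(ob1$labeling[order(names(ob1$labeling))],
                   ob2$labeling[order(names(ob2$labeling))])
      expect_equal(length(ob1$blocks), length(ob2$blocks))
    }
  }
})

test_that("selection achieves the brute-force optimum on small instances", {
  set.seed(23)
  checked <- 0L
  for (rep in 1:25) {
    inst <- random_selection_instance(n_ref = 5L, n_cand = 7L)
    candidates <- sort(unique(unlist(inst$map)))
    label_sets <- lapply(stats::setNames(nm = candidates), function(g) {
      inst$block$gene_ids[vapply(inst$block$gene_ids, function(r)
        g %in% inst$map[[r]], logical(1L))]
    })
    best <- oracle_best_tuple(inst$ann, label_sets, 500L)
    ob <- select_orthologs(inst$map, inst$ann, inst$block)
    if (is.null(best)) {
      expect_null(ob)
    } else {
      expect_equal(realized_tuple(ob), best)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 5L)
})

test_that("orthoblock census counts non-reference genomes only", {
  # 5 target genomes; block detectable (two neighboring homologs) in 3
  ref <- reference_block("blk", c("a", "b", "c"), "ref")
  mk_ann <- function(gid, together) {
    if (together) {
      ann_from_genes(gid, list(c("t1", "c1", 1, 900, "+"),
                               c("t2", "c1", 950, 1850, "+")))
    } else {
      ann_from_genes(gid, list(c("t1", "c1", 1, 900, "+"),
                               c("t2", "c1", 90000, 90900, "+")))
    }
  }
  genomes <- list(G1 = mk_ann("G1", TRUE), G2 = mk_ann("G2", TRUE),
                  G3 = mk_ann("G3", FALSE), G4 = mk_ann("G4", TRUE),
                  G5 = mk_ann("G5", FALSE))
  rows <- list()
  for (g in names(genomes)) {
    rows[[length(rows) + 1L]] <- c("a", "t1", g, 1e-50)
    rows[[length(rows) + 1L]] <- c("b", "t2", g, 1e-50)
  }
  hits <- hits_from_rows(rows)
  census <- orthoblock_census(list(ref), genomes, hits)
  expect_equal(census[["blk"]], 3L)
})
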