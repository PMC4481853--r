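tree6 <- "((A:1,B:1):1,((C:1,D:1):1,(E:1,F:1):1):1);"

test_that("zero rates propagate the intact block to every leaf", {
  sim <- simulate_blocks(tree6, n_genes = 6L, seed = 1L)
  expect_equal(nrow(sim$truth$log), 0L)
  for (gid in sim$tree$tip.label) {
    ann <- sim$annotations[[gid]]
    expect_equal(nrow(ann), 6L)
    expect_equal(ann$name, sim$block$gene_ids)
    expect_true(all(ann$strand == "+"))
  }
  for (ev in c("split", "deletion", "duplication")) {
    expect_true(all(expected_distances(sim$truth, ev) == 0L))
  }
  # and the measured matrices agree
  inferred <- infer_event_matrices(sim)
  for (ev in names(inferred)) {
    expect_true(all(inferred[[ev]][lower.tri(inferred[[ev]])] == 0))
  }
})

test_that("a fixed seed makes simulation outputs byte-identical", {
  d1 <- tempfile("sim1")
  d2 <- tempfile("sim2")
  rates <- c(split = 0.3, deletion = 0.3, duplication = 0.2,
             strand_reversal = 0.1)
  write_simulation(simulate_blocks(tree6, 8L, rates, seed = 99L), d1)
  write_simulation(simulate_blocks(tree6, 8L, rates, seed = 99L), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 3L)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("expected distances are tree path sums of logged events", {
  # single deletion on the branch above the (A,B) clade of ((A,B),C)
  sim <- simulate_blocks("((A:1,B:1)ab:1,C:2);", n_genes = 4L,
                         injected_events = data.frame(
                           branch = "5", type = "deletion", gene = "g02",
                           stringsAsFactors = FALSE))
  m <- expected_distances(sim$truth, "deletion")
  expect_equal(m["A", "B"], 0L)
  expect_equal(m["A", "C"], 1L)
  expect_equal(m["B", "C"], 1L)
  # additivity: two events of one type on disjoint branches
  sim2 <- simulate_blocks("((A:1,B:1):1,C:2);", n_genes = 6L,
                          injected_events = data.frame(
                            branch = c("A", "C"), type = "deletion",
                            gene = c("g01", "g04"),
                            stringsAsFactors = FALSE))
  m2 <- expected_distances(sim2$truth, "deletion")
  expect_equal(m2["A", "C"], 2L)
  expect_equal(m2["A", "B"], 1L)
  expect_equal(m2["B", "C"], 1L)
})

test_that("one forced deletion is recovered exactly across the tree", {
  sim <- simulate_blocks(tree6, n_genes = 5L,
                         injected_events = data.frame(
                           branch = "A", type = "deletion", gene = "g03",
                           stringsAsFactors = FALSE))
  inferred <- infer_event_matrices(sim)
  truth <- expected_distances(sim$truth, "deletion")
  off <- lower.tri(truth)
  expect_equal(inferred$deletion[off], as.numeric(truth[off]))
  # pairs straddling the A branch score exactly 1
  expect_equal(inferred$deletion["A", "B"], 1)
  expect_equal(inferred$deletion["C", "D"], 0)
})

test_that("a strand reversal registers as a split", {
  sim <- simulate_blocks("((A:1,B:1):1,C:2);", n_genes = 4L,
                         injected_events = data.frame(
                           branch = "A", type = "strand_reversal",
                           gene = "g02", stringsAsFactors = FALSE))
  inferred <- infer_event_matrices(sim)
  truth <- expected_distances(sim$truth, "split")
  expect_equal(truth["A", "B"], 1L)
  expect_equal(inferred$split["A", "B"], 1)
  expect_equal(inferred$split["B", "C"], 0)
})

test_that("non-interacting deletions/duplications are recovered exactly", {
  set.seed(17)
  for (rep in 1:10) {
    events <- sample_noninteracting_events(ape::read.tree(text = tree6),
                                           n_genes = 8L, n_events = 4L)
    sim <- simulate_blocks(tree6, n_genes = 8L,
                           injected_events = events)
    inferred <- infer_event_matrices(sim)
    for (ev in c("deletion", "duplication")) {
      truth <- expected_distances(sim$truth, ev)
      off <- lower.tri(truth)
      expect_equal(inferred[[ev]][off], as.numeric(truth[off]))
    }
  }
})

test_that("interacting events of one type can hide, but never invent, events", {
  # within one event type, repeated events on the same gene or block can
  # cancel out in the pairwise comparison (e.g. parallel deletions of
  # the same gene), so the inferred distance is at most the path sum.
  # Mixed histories do not obey this bound: an ancestral duplication
  # later deleted in one lineage looks like an extra duplication under
  # the single-copy-ancestor parsimony rule.
  configs <- list(deletion = c(deletion = 0.8),
                  duplication = c(duplication = 0.8),
                  split = c(split = 0.5, strand_reversal = 0.3))
  for (ev in names(configs)) {
    for (seed in 1:8) {
      sim <- simulate_blocks(tree6, n_genes = 6L,
                             rates = configs[[ev]], seed = 400L + seed)
      obs_exist <- vapply(sim$tree$tip.label, function(gid) {
        hm <- build_homolog_map(sim$hits, sim$block, gid)
        !is.null(select_orthologs(hm, sim$annotations[[gid]], sim$block))
      }, logical(1L))
      if (sum(obs_exist) < 2L) next
      inferred <- infer_event_matrices(sim)
      truth <- expected_distances(sim$truth, ev)
      off <- lower.tri(truth)
      ok <- !is.na(inferred[[ev]][off])
      expect_true(all(inferred[[ev]][off][ok] <=
                        as.numeric(truth[off][ok])))
    }
  }
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulate_blocks(tree6, n_genes = 1L), "at least 2 genes")
  expect_error(simulate_blocks("(onlyone);", n_genes = 4L), "2 leaves")
  expect_error(simulate_blocks(tree6, rates = c(deletion = -1)), ">= 0")
})
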