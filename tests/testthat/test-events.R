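ref7 <- reference_block("split_ex", letters[1:7], "ref")
ref5 <- reference_block("dup_ex", letters[1:5], "ref")

test_that("split distance is the absolute difference in block counts", {
  A <- orthoblock_from_layout(ref7, "A", list(c("a", "b", "c"),
                                              c("d", "e", "f", "g")))
  B <- orthoblock_from_layout(ref7, "B", list(c("a", "b", "c"),
                                              c("d", "e"), c("f", "g")))
  expect_equal(split_distance(A, B), 1L)
  expect_equal(split_distance(B, A), 1L)
  expect_equal(split_distance(A, A), 0L)
})

test_that("duplication and deletion distances follow the parsimony rule", {
  A <- orthoblock_from_layout(ref5, "A", list(c("a", "b", "d")))
  B <- orthoblock_from_layout(ref5, "B",
                              list(c("a", "b", "b", "c", "c")))
  contrib <- duplication_contributions(A, B, ref5)
  expect_equal(contrib[["b"]], 1L)  # 1 vs 2 copies
  expect_equal(contrib[["c"]], 1L)  # 0 vs 2 copies: ancestor held one
  expect_equal(contrib[["a"]], 0L)
  expect_equal(duplication_distance(A, B, ref5), 2L)
  # c present only in B -> one deletion; d present only in A -> one more
  pres_A <- copy_profile(A, ref5) >= 1L
  pres_B <- copy_profile(B, ref5) >= 1L
  expect_true(xor(pres_A[["c"]], pres_B[["c"]]))
  expect_equal(deletion_distance(A, B, ref5), 2L)
  # e absent from both taxa has no bearing on the distance
  expect_false(pres_A[["e"]] || pres_B[["e"]])
})

test_that("deletion distance is the symmetric difference of presence", {
  refab <- reference_block("sd", letters[1:4], "ref")
  i <- orthoblock_from_layout(refab, "I", list(c("a", "b")))
  j <- orthoblock_from_layout(refab, "J", list(c("c", "d")))
  expect_equal(deletion_distance(i, j, refab), 4L)
  expect_equal(deletion_distance(i, i, refab), 0L)
})

test_that("distances on absent orthoblocks are signalled, not zero", {
  A <- orthoblock_from_layout(ref5, "A", list(c("a", "b")))
  expect_error(split_distance(A, NULL), "absent")
  expect_error(deletion_distance(NULL, A, ref5), "absent")
})

test_that("event distances are symmetric metrics with zero self-distance", {
  set.seed(31)
  obs <- lapply(1:40, function(i)
    random_orthoblock(ref5, sprintf("G%02d", i)))
  for (rep in 1:200) {
    idx <- sample(40L, 3L)
    x <- obs[[idx[1L]]]; y <- obs[[idx[2L]]]; z <- obs[[idx[3L]]]
    expect_equal(split_distance(x, y), split_distance(y, x))
    expect_equal(deletion_distance(x, y, ref5),
                 deletion_distance(y, x, ref5))
    expect_equal(duplication_distance(x, y, ref5),
                 duplication_distance(y, x, ref5))
    expect_equal(split_distance(x, x), 0L)
    expect_equal(deletion_distance(x, x, ref5), 0L)
    expect_equal(duplication_distance(x, x, ref5), 0L)
    # triangle inequality for split (|f(i)-f(j)|) and deletion
    # (symmetric-difference metric)
    expect_lte(split_distance(x, z),
               split_distance(x, y) + split_distance(y, z))
    expect_lte(deletion_distance(x, z, ref5),
               deletion_distance(x, y, ref5) +
                 deletion_distance(y, z, ref5))
  }
})

test_that("all-pairs matrices cover exactly the taxa with the orthoblock", {
  A <- orthoblock_from_layout(ref5, "A", list(c("a", "b", "c")))
  B <- orthoblock_from_layout(ref5, "B", list(c("a", "b", "c")))
  obs <- list(A = A, B = B, C = NULL)
  m <- all_pairs_distances(obs, ref5, "deletion")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(attr(m, "absent_taxa"), "C")
  expect_true(all(m == 0))
  expect_equal(diag(m), c(A = 0, B = 0))
  expect_error(all_pairs_distances(list(A = A, C = NULL), ref5, "split"),
               "insufficient taxa")
})

test_that("conservation ranking normalizes per genome pair and sorts", {
  refc <- reference_block("cons", letters[1:5], "ref")
  intact <- function(g) orthoblock_from_layout(
    refc, g, list(c("a", "b", "c", "d", "e")))
  broken <- function(g, layout) orthoblock_from_layout(refc, g, layout)
  # block "steady": 3 identical taxa -> 3 pairs, all zero -> score 0
  steady <- list(X = intact("X"), Y = intact("Y"), Z = intact("Z"))
  # block "shaky": X intact; Y split in two; Z lost d and e
  shaky <- list(
    X = broken("X", list(c("a", "b", "c", "d", "e"))),
    Y = broken("Y", list(c("a", "b", "c"), c("d", "e"))),
    Z = broken("Z", list(c("a", "b", "c"))))
  blocks <- list(reference_block("steady", letters[1:5], "ref"),
                 reference_block("shaky", letters[1:5], "ref"))
  # hand-computed: pairs XY (split 1), XZ (del 2), YZ (split 1 + del 2)
  tab <- pairwise_event_table(list(steady = steady, shaky = shaky),
                              blocks)
  rank <- conservation_rank(tab)
  expect_equal(rank$block_name, c("steady", "shaky"))
  expect_equal(rank$score, c(0, 6 / 3))
  expect_equal(rank$total_events, c(0, 6))
  raw <- conservation_rank(tab, normalize = FALSE)
  expect_equal(raw$score, raw$total_events)
  # invariant to block input order
  tab2 <- pairwise_event_table(list(shaky = shaky, steady = steady),
                               rev(blocks))
  expect_equal(conservation_rank(tab2), rank)
})

test_that("blocks with fewer than two orthoblock taxa are excluded with warning", {
  refc <- reference_block("lonely", letters[1:3], "ref")
  only <- list(X = orthoblock_from_layout(refc, "X",
                                          list(c("a", "b", "c"))),
               Y = NULL)
  expect_warning(
    tab <- pairwise_event_table(list(lonely = only), list(refc)),
    "fewer than 2")
  expect_equal(nrow(tab), 0L)
})
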