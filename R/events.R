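#' Per-reference-gene copy counts of an orthoblock
#'
#' For each gene of the reference block, counts how many selected target
#' genes inside the orthoblock carry that reference label. A count of 0
#' means the gene is absent from all of that taxon's blocks.
#'
#' @param ob an `orthoblock`.
#' @param block the [reference_block()] (fixes the gene universe and
#'   order).
#' @return Named integer vector over `block$gene_ids`.
#' @export
copy_profile <- function(ob, block) {
  stopifnot(inherits(ob, "orthoblock"))
  counts <- table(factor(ob$labeling, levels = block$gene_ids))
  stats::setNames(as.integer(counts), block$gene_ids)
}

check_pair <- function(ob_i, ob_j) {
  if (is.null(ob_i) || is.null(ob_j)) {
    stop("event distance undefined: orthoblock absent in one of the taxa")
  }
  stopifnot(inherits(ob_i, "orthoblock"), inherits(ob_j, "orthoblock"))
  if (ob_i$block_name != ob_j$block_name) {
    stop("orthoblocks belong to different reference blocks: ",
         ob_i$block_name, " vs ", ob_j$block_name)
  }
}

#' Split distance between two orthoblocks
#'
#' The absolute difference in the number of neighbor blocks the selected
#' homologs form in the two taxa. Strand reversals and relocations both
#' raise the block count, so they register here.
#'
#' @param ob_i,ob_j `orthoblock` objects for the same reference block.
#'   Passing `NULL` (absent orthoblock) is an error: the pair carries no
#'   information and must be excluded, not scored 0.
#' @return Non-negative integer.
#' @export
split_distance <- function(ob_i, ob_j) {
  check_pair(ob_i, ob_j)
  abs(length(ob_i$blocks) - length(ob_j$blocks))
}

#' Duplication distance between two orthoblocks
#'
#' Per reference gene with copy counts (c_i, c_j) in the two orthoblocks,
#' the number of duplications under the most parsimonious single-copy
#' ancestor is `max(c_i, c_j) - max(1, min(c_i, c_j))` when
#' `max(c_i, c_j) >= 2`, else 0; the distance is the sum over genes.
#' Thus 1 vs 2 copies costs one duplication, and 0 vs 2 copies also costs
#' one duplication (plus one deletion, charged by [deletion_distance()]).
#' Duplications are only tallied inside gene blocks, which holds by
#' construction: copy profiles count block members only.
#'
#' @inheritParams split_distance
#' @param block the [reference_block()].
#' @return Non-negative integer.
#' @export
duplication_distance <- function(ob_i, ob_j, block) {
  sum(duplication_contributions(ob_i, ob_j, block))
}

#' Per-gene duplication contributions
#'
#' @inheritParams duplication_distance
#' @return Named integer vector over the reference genes.
#' @export
duplication_contributions <- function(ob_i, ob_j, block) {
  check_pair(ob_i, ob_j)
  ci <- copy_profile(ob_i, block)
  cj <- copy_profile(ob_j, block)
  hi <- pmax(ci, cj)
  lo <- pmin(ci, cj)
  ifelse(hi >= 2L, hi - pmax(1L, lo), 0L)
}

#' Deletion distance between two orthoblocks
#'
#' The number of reference genes present (copy count >= 1) in exactly one
#' of the two orthoblocks -- the symmetric difference of their presence
#' sets. Genes absent from both taxa have no bearing on the distance,
#' even when present in the reference; copy-number differences above one
#' are charged to duplications, never double-counted here.
#'
#' @inheritParams duplication_distance
#' @return Non-negative integer.
#' @export
deletion_distance <- function(ob_i, ob_j, block) {
  check_pair(ob_i, ob_j)
  pi <- copy_profile(ob_i, block) >= 1L
  pj <- copy_profile(ob_j, block) >= 1L
  sum(xor(pi, pj))
}

#' All three event distances for one pair of taxa
#'
#' @inheritParams duplication_distance
#' @return Data frame with one row: block_name, taxon_i, taxon_j, d_s,
#'   d_d, d_u.
#' @export
event_distances <- function(ob_i, ob_j, block) {
  check_pair(ob_i, ob_j)
  data.frame(block_name = ob_i$block_name,
             taxon_i = ob_i$genome_id, taxon_j = ob_j$genome_id,
             d_s = split_distance(ob_i, ob_j),
             d_d = deletion_distance(ob_i, ob_j, block),
             d_u = duplication_distance(ob_i, ob_j, block),
             stringsAsFactors = FALSE)
}

#' All-pairs distance matrix for one reference block and event type
#'
#' Builds the symmetric matrix of pairwise distances over exactly the
#' taxa that possess the orthoblock; taxa lacking it are flagged in the
#' `absent_taxa` attribute (the no-data state of the phylomatrix) rather
#' than given fake zero distances.
#'
#' @param orthoblocks named list, genome id -> `orthoblock` or `NULL`.
#' @param block the [reference_block()].
#' @param event one of `"split"`, `"deletion"`, `"duplication"`.
#' @return Symmetric numeric matrix with zero diagonal and attributes
#'   `absent_taxa`, `event` and `block_name`.
#' @export
all_pairs_distances <- function(orthoblocks, block,
                                event = c("split", "deletion",
                                          "duplication")) {
  event <- match.arg(event)
  present <- names(orthoblocks)[!vapply(orthoblocks, is.null, logical(1L))]
  absent <- setdiff(names(orthoblocks), present)
  if (length(present) < 2L) {
    stop("insufficient taxa: fewer than 2 taxa possess orthoblock '",
         block$block_name, "'")
  }
  n <- length(present)
  m <- matrix(0, n, n, dimnames = list(present, present))
  fn <- switch(event,
               split = function(i, j) split_distance(i, j),
               deletion = function(i, j) deletion_distance(i, j, block),
               duplication = function(i, j) duplication_distance(i, j, block))
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      d <- fn(orthoblocks[[present[a]]], orthoblocks[[present[b]]])
      m[a, b] <- d
      m[b, a] <- d
    }
  }
  structure(m, absent_taxa = absent, event = event,
            block_name = block$block_name)
}

#' Long-format pairwise event table over many blocks
#'
#' @param orthoblock_sets nested list from [build_orthoblocks()].
#' @param blocks list of [reference_block()] objects.
#' @return Data frame with columns block_name, taxon_i, taxon_j, event,
#'   distance (one row per unordered taxon pair and event type; blocks
#'   with fewer than two orthoblock taxa contribute no rows).
#' @export
pairwise_event_table <- function(orthoblock_sets, blocks) {
  rows <- list()
  for (b in blocks) {
    obs <- orthoblock_sets[[b$block_name]]
    present <- names(obs)[!vapply(obs, is.null, logical(1L))]
    if (length(present) < 2L) {
      warning("block '", b$block_name,
              "' has orthoblocks in fewer than 2 taxa; excluded",
              call. = FALSE)
      next
    }
    for (a in seq_len(length(present) - 1L)) {
      for (z in seq((a + 1L), length(present))) {
        ed <- event_distances(obs[[present[a]]], obs[[present[z]]], b)
        rows[[length(rows) + 1L]] <- data.frame(
          block_name = b$block_name,
          taxon_i = present[a], taxon_j = present[z],
          event = c("split", "deletion", "duplication"),
          distance = c(ed$d_s, ed$d_d, ed$d_u),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(block_name = character(), taxon_i = character(),
                      taxon_j = character(), event = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank reference blocks by evolutionary conservation
#'
#' The conservation score of a block is the cumulative number of events
#' (splits + deletions + duplications) over all taxon pairs possessing
#' the orthoblock, divided (by default) by the number of such pairs --
#' events per genome pair. Blocks are returned most conserved first
#' (ascending score).
#'
#' @param distances long-format table from [pairwise_event_table()].
#' @param normalize divide the cumulative event count by the number of
#'   taxon pairs (default `TRUE`); set `FALSE` for the raw sum.
#' @return Data frame with columns block_name, n_pairs, total_events,
#'   score, sorted ascending by score (ties by block name). Blocks with
#'   fewer than one compared pair are excluded with a warning upstream
#'   (they never enter `distances`).
#' @export
conservation_rank <- function(distances, normalize = TRUE) {
  if (nrow(distances) == 0L) {
    return(data.frame(block_name = character(), n_pairs = integer(),
                      total_events = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  pair_key <- paste(distances$block_name, distances$taxon_i,
                    distances$taxon_j, sep = "\r")
  totals <- tapply(distances$distance, distances$block_name, sum)
  n_pairs <- tapply(pair_key, distances$block_name,
                    function(k) length(unique(k)))
  blocks <- names(totals)
  score <- as.numeric(totals)
  if (normalize) score <- score / as.numeric(n_pairs)
  out <- data.frame(block_name = blocks,
                    n_pairs = as.integer(n_pairs),
                    total_events = as.numeric(totals),
                    score = score, stringsAsFactors = FALSE)
  out <- out[order(out$score, out$block_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
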