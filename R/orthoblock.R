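#' Find neighboring-gene blocks among candidate genes
#'
#' Two genes are neighboring when they lie on the same contig and strand
#' and are at most `max_gap` nucleotides apart; the intergenic gap between
#' consecutive genes is `start(next) - end(prev) - 1` on 1-based inclusive
#' coordinates, so overlapping genes (gap <= 0) are neighboring. A
#' neighbor block is a maximal run of two or more candidates under this
#' relation; candidates that end up alone are returned as singletons (they
#' cannot form blocks but matter for diagnostics). A strand reversal
#' severs neighborhood regardless of distance, which is how reversals are
#' registered as splits downstream.
#'
#' @param annotation a [genome_annotation()].
#' @param candidate_genes character vector of gene ids to consider.
#' @param max_gap maximum intergenic gap in nucleotides (default 500).
#' @return List with `blocks` (list of `neighbor_block` objects ordered by
#'   contig and start) and `singletons` (character vector of gene ids).
#' @export
find_neighbor_blocks <- function(annotation, candidate_genes,
                                 max_gap = 500L) {
  rows <- annotation[annotation$gene_id %in% candidate_genes, , drop = FALSE]
  blocks <- list()
  singletons <- character()
  if (nrow(rows) == 0L) {
    return(list(blocks = blocks, singletons = singletons))
  }
  groups <- split(seq_len(nrow(rows)),
                  paste(rows$contig_id, rows$strand, sep = "\r"))
  for (idx in groups) {
    g <- rows[idx, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    n <- nrow(g)
    run_start <- 1L
    flush <- function(i0, i1) {
      if (i1 > i0) {
        blocks[[length(blocks) + 1L]] <<- structure(list(
          genome_id = g$genome_id[1L],
          contig_id = g$contig_id[1L],
          gene_ids = g$gene_id[i0:i1],
          strand = g$strand[1L],
          start = g$start[i0],
          end = g$end[i1]), class = "neighbor_block")
      } else {
        singletons <<- c(singletons, g$gene_id[i0])
      }
    }
    if (n == 1L) {
      flush(1L, 1L)
      next
    }
    for (i in seq_len(n - 1L)) {
      gap <- g$start[i + 1L] - g$end[i] - 1L
      if (gap > max_gap) {
        flush(run_start, i)
        run_start <- i + 1L
      }
    }
    flush(run_start, n)
  }
  ord <- order(vapply(blocks, `[[`, character(1L), "contig_id"),
               vapply(blocks, `[[`, integer(1L), "start"))
  list(blocks = blocks[ord], singletons = sort(singletons))
}

#' @export
print.neighbor_block <- function(x, ...) {
  cat(sprintf("Neighbor block %s:%d-%d (%s): %s\n", x$contig_id, x$start,
              x$end, x$strand, paste(x$gene_ids, collapse = ", ")))
  invisible(x)
}

# label_sets: named list, target gene -> character vector of candidate
# reference labels. Returns the size of a maximum bipartite matching
# between genes and labels (= the largest number of distinct reference
# genes that can be represented without a gene carrying two labels).
match_genes_to_labels <- function(genes, label_sets) {
  if (length(genes) == 0L) {
    return(list(size = 0L, assignment = character()))
  }
  sets <- label_sets[genes]
  if (all(lengths(sets) == 1L)) {
    lab <- vapply(sets, `[[`, character(1L), 1L)
    names(lab) <- genes
    first <- !duplicated(lab)
    return(list(size = sum(first), assignment = lab))
  }
  labels <- sort(unique(unlist(sets)))
  nG <- length(genes)
  nL <- length(labels)
  edges <- integer()
  for (i in seq_len(nG)) {
    for (l in match(sets[[i]], labels)) {
      edges <- c(edges, i, nG + l)
    }
  }
  gr <- igraph::make_bipartite_graph(c(rep(FALSE, nG), rep(TRUE, nL)),
                                     edges, directed = FALSE)
  m <- igraph::max_bipartite_match(gr)
  matched <- m$matching[seq_len(nG)]
  assignment <- character(nG)
  names(assignment) <- genes
  for (i in seq_len(nG)) {
    if (!is.na(matched[i])) {
      assignment[i] <- labels[as.integer(matched[i]) - nG]
    } else {
      # unmatched gene: it duplicates some label; pick its alphabetically
      # first candidate label (deterministic)
      assignment[i] <- sort(sets[[i]])[1L]
    }
  }
  list(size = m$matching_size, assignment = assignment)
}

# Lexicographic objective for a set of neighbor blocks:
# (1) maximize distinct reference genes represented, (2) minimize
# duplicate labels, (3) minimize number of blocks.
score_block_subset <- function(blocks, subset, label_sets) {
  genes <- unlist(lapply(blocks[subset], `[[`, "gene_ids"))
  m <- match_genes_to_labels(genes, label_sets)
  c(m$size, -(length(genes) - m$size), -length(subset))
}

tuple_gt <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] > b[k]) return(TRUE)
    if (a[k] < b[k]) return(FALSE)
  }
  FALSE
}

#' Select orthologs for one reference block in one target genome
#'
#' Among the candidate homologs of a reference block's genes, selects the
#' genes that constitute the orthoblock using genomic context. Candidates
#' are first grouped into neighbor blocks ([find_neighbor_blocks()]);
#' a subset of those blocks is then chosen to optimise, lexicographically:
#' (1) the number of distinct reference genes represented inside blocks
#' (maximised), (2) the number of duplicate labels, i.e. selected genes
#' beyond one per reference gene (minimised), and (3) the number of blocks
#' (minimised). Ties are broken deterministically in favour of the
#' leftmost blocks (contig, then start coordinate). Chosen blocks are
#' taken whole -- duplicate gene copies inside a chosen block are kept,
#' which is what the duplication distance later counts.
#'
#' With at most `exhaustive_limit` candidate genes all block subsets are
#' scored, guaranteeing the lexicographic optimum; above that a greedy
#' search seeds from the largest block, adds blocks while the objective
#' improves, and prunes blocks whose removal does not lose labels.
#'
#' Each selected gene carries exactly one reference label; with ambiguous
#' homology the assignment maximising distinct labels is found by maximum
#' bipartite matching.
#'
#' @param homolog_map a [build_homolog_map()] result.
#' @param annotation the target [genome_annotation()].
#' @param block the [reference_block()].
#' @param max_gap neighboring-gene gap threshold (default 500).
#' @param exhaustive_limit candidate-gene count up to which the block
#'   subset search is exhaustive (default 12).
#' @return An object of class `orthoblock`, or `NULL` when no two labeled
#'   homologs are neighboring (the orthoblock does not exist for this
#'   genome). The object has fields `block_name`, `genome_id`, `blocks`
#'   (list of `neighbor_block`), `labeling` (named character, selected
#'   target gene id -> reference gene id) and `singletons` (candidate
#'   homologs outside any block, excluded from the orthoblock).
#' @export
select_orthologs <- function(homolog_map, annotation, block,
                             max_gap = 500L, exhaustive_limit = 12L) {
  stopifnot(inherits(homolog_map, "homolog_map"))
  candidates <- sort(unique(unlist(homolog_map)))
  candidates <- intersect(candidates, annotation$gene_id)
  if (length(candidates) == 0L) return(NULL)
  label_sets <- lapply(candidates, function(g) {
    block$gene_ids[vapply(block$gene_ids,
                          function(r) g %in% homolog_map[[r]], logical(1L))]
  })
  names(label_sets) <- candidates
  nb <- find_neighbor_blocks(annotation, candidates, max_gap)
  if (length(nb$blocks) == 0L) return(NULL)
  B <- length(nb$blocks)
  if (length(candidates) <= exhaustive_limit) {
    best <- NULL
    best_tuple <- NULL
    for (mask in seq_len(2^B - 1L)) {
      subset <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(B) - 1L)) != 0L)
      tup <- score_block_subset(nb$blocks, subset, label_sets)
      if (is.null(best_tuple) || tuple_gt(tup, best_tuple)) {
        best <- subset
        best_tuple <- tup
      }
      # ties: masks are enumerated so that lower block indices (leftmost
      # coordinates) are reached first with fewer blocks; keep the first
    }
    subset <- best
  } else {
    sizes <- vapply(nb$blocks, function(b) length(b$gene_ids), integer(1L))
    seed <- order(-sizes, seq_len(B))[1L]
    subset <- seed
    tup <- score_block_subset(nb$blocks, subset, label_sets)
    repeat {
      improved <- FALSE
      for (b in setdiff(seq_len(B), subset)) {
        cand <- sort(c(subset, b))
        t2 <- score_block_subset(nb$blocks, cand, label_sets)
        if (tuple_gt(t2, tup)) {
          subset <- cand
          tup <- t2
          improved <- TRUE
        }
      }
      for (b in subset) {
        if (length(subset) == 1L) break
        cand <- setdiff(subset, b)
        t2 <- score_block_subset(nb$blocks, cand, label_sets)
        if (tuple_gt(t2, tup)) {
          subset <- cand
          tup <- t2
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  chosen <- nb$blocks[sort(subset)]
  genes <- unlist(lapply(chosen, `[[`, "gene_ids"))
  labeling <- match_genes_to_labels(genes, label_sets)$assignment
  structure(list(block_name = block$block_name,
                 genome_id = attr(homolog_map, "genome_id"),
                 blocks = chosen,
                 labeling = labeling,
                 singletons = nb$singletons),
            class = "orthoblock")
}

#' @export
print.orthoblock <- function(x, ...) {
  cat(sprintf("Orthoblock '%s' in genome '%s': %d block(s)\n",
              x$block_name, x$genome_id, length(x$blocks)))
  for (b in x$blocks) {
    cat("  (", paste(x$labeling[b$gene_ids], collapse = " "), ")  [",
        paste(b$gene_ids, collapse = ", "), "]\n", sep = "")
  }
  if (length(x$singletons) > 0L) {
    cat("  singleton homologs (excluded): ",
        paste(x$singletons, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Assemble orthoblocks for many blocks and genomes
#'
#' Convenience driver: for every reference block and every target genome,
#' builds the homolog map and runs ortholog selection.
#'
#' @param blocks list of [reference_block()] objects.
#' @param annotations named list of [genome_annotation()] objects
#'   (names are genome ids).
#' @param hits a `homology_hits` data frame.
#' @param max_gap,max_evalue,exhaustive_limit passed through.
#' @return Nested named list: `result[[block_name]][[genome_id]]` is an
#'   `orthoblock` or `NULL`.
#' @export
build_orthoblocks <- function(blocks, annotations, hits, max_gap = 500L,
                              max_evalue = 1e-10, exhaustive_limit = 12L) {
  out <- list()
  for (b in blocks) {
    per_genome <- list()
    for (gid in names(annotations)) {
      hm <- build_homolog_map(hits, b, gid, max_evalue)
      per_genome[gid] <- list(select_orthologs(hm, annotations[[gid]], b,
                                               max_gap, exhaustive_limit))
    }
    out[[b$block_name]] <- per_genome
  }
  out
}

#' Count genomes holding an orthoblock, per reference block
#'
#' The census feeds the operon selection filter ("orthoblocks in at least
#' nine other genomes"): the reference genome itself is excluded from the
#' count.
#'
#' @param blocks list of [reference_block()] objects.
#' @param annotations named list of target [genome_annotation()] objects.
#' @param hits a `homology_hits` data frame.
#' @param max_gap,max_evalue passed to orthoblock assembly.
#' @return Named integer vector, block_name -> number of non-reference
#'   genomes with an orthoblock.
#' @export
orthoblock_census <- function(blocks, annotations, hits, max_gap = 500L,
                              max_evalue = 1e-10) {
  obs <- build_orthoblocks(blocks, annotations, hits, max_gap, max_evalue)
  counts <- vapply(blocks, function(b) {
    per_genome <- obs[[b$block_name]]
    per_genome <- per_genome[names(per_genome) != b$reference_genome_id]
    sum(!vapply(per_genome, is.null, logical(1L)))
  }, integer(1L))
  names(counts) <- vapply(blocks, `[[`, character(1L), "block_name")
  counts
}

#' Tabulate orthoblocks as a long-format report
#'
#' @param orthoblocks nested list from [build_orthoblocks()], or a single
#'   `orthoblock`.
#' @param annotations named list of [genome_annotation()] objects used to
#'   attach coordinates.
#' @return Data frame with columns block_name, genome_id, block_index,
#'   gene_id, reference_label, contig, start, end, strand.
#' @export
orthoblock_table <- function(orthoblocks, annotations) {
  if (inherits(orthoblocks, "orthoblock")) {
    orthoblocks <- stats::setNames(
      list(stats::setNames(list(orthoblocks), orthoblocks$genome_id)),
      orthoblocks$block_name)
  }
  rows <- list()
  for (bn in names(orthoblocks)) {
    for (gid in names(orthoblocks[[bn]])) {
      ob <- orthoblocks[[bn]][[gid]]
      if (is.null(ob)) next
      ann <- annotations[[gid]]
      for (k in seq_along(ob$blocks)) {
        blk <- ob$blocks[[k]]
        idx <- match(blk$gene_ids, ann$gene_id)
        rows[[length(rows) + 1L]] <- data.frame(
          block_name = bn, genome_id = gid, block_index = k,
          gene_id = blk$gene_ids,
          reference_label = unname(ob$labeling[blk$gene_ids]),
          contig = ann$contig_id[idx], start = ann$start[idx],
          end = ann$end[idx], strand = ann$strand[idx],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(block_name = character(), genome_id = character(),
                      block_index = integer(), gene_id = character(),
                      reference_label = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct an orthoblock from a printed block layout
#'
#' Convenience constructor for worked examples: given a reference block
#' and a layout such as `list(c("a","b","c"), c("d","e","f","g"))` --
#' each element one gene block, written in reference labels, repeats
#' denoting duplicate copies -- it synthesises a genome in which those
#' blocks sit at mutually distant loci (within-block gaps of 50 bp,
#' 10 kb between loci), builds the corresponding homolog map, and runs
#' the ordinary ortholog selection. The result is a genuine
#' `orthoblock` produced by the same machinery as real data.
#'
#' @param block the [reference_block()].
#' @param genome_id genome id to assign.
#' @param layout list of character vectors of reference gene labels.
#' @param max_gap neighboring threshold used in selection (default 500).
#' @return An `orthoblock`.
#' @export
orthoblock_from_layout <- function(block, genome_id, layout,
                                   max_gap = 500L) {
  rows <- list()
  hit_rows <- list()
  cursor <- 1L
  counter <- integer()
  for (loc in layout) {
    for (lab in loc) {
      if (!lab %in% block$gene_ids) {
        stop("layout label '", lab, "' is not a gene of block '",
             block$block_name, "'")
      }
      n_prev <- if (lab %in% names(counter)) counter[[lab]] else 0L
      counter[lab] <- n_prev + 1L
      gid <- sprintf("%s_%d", lab, n_prev + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = genome_id, contig_id = "chr1", gene_id = gid,
        start = cursor, end = cursor + 899L, strand = "+",
        stringsAsFactors = FALSE)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        query_gene_id = lab, subject_gene_id = gid,
        subject_genome_id = genome_id, evalue = 1e-50, bitscore = 500,
        stringsAsFactors = FALSE)
      cursor <- cursor + 950L
    }
    cursor <- cursor + 20L * max_gap
  }
  ann <- genome_annotation(do.call(rbind, rows))
  hits <- do.call(rbind, hit_rows)
  class(hits) <- c("homology_hits", "data.frame")
  hm <- build_homolog_map(hits, block, genome_id)
  ob <- select_orthologs(hm, ann, block, max_gap)
  if (is.null(ob)) {
    stop("layout yields no orthoblock (no two neighboring homologs)")
  }
  ob
}
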