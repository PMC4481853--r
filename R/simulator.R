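#' Forward-simulate gene block evolution along a tree
#'
#' Starting from a root genome carrying one intact gene block, evolves
#' the block along each branch of a phylogeny under four event types:
#' \describe{
#'   \item{split}{a contiguous suffix of a block is relocated to a
#'     distant locus (farther than 10x the neighboring-gene threshold),
#'     severing the neighbor relation;}
#'   \item{strand_reversal}{as split, but the relocated suffix also flips
#'     strand -- measured downstream as a split;}
#'   \item{deletion}{one block gene copy is removed;}
#'   \item{duplication}{one block gene copy gains an adjacent copy.}
#' }
#' The number of events of each type on a branch is Poisson with mean
#' `rate * branch_length`; targets are chosen uniformly among eligible
#' gene copies / cut points. Alternatively, `injected_events` places an
#' exact set of events on named branches (Poisson draws are then
#' skipped), which is how ground-truth recovery tests construct
#' non-interacting scenarios.
#'
#' The simulator emits exactly what the measurement pipeline consumes:
#' one annotation per leaf plus the reference genome, a homology table
#' linking every descendant copy to its reference gene (synthetic e-value
#' 1e-50), the reference block definition, and a per-branch ground-truth
#' event log.
#'
#' @param tree phylogeny with branch lengths (`phylo`, Newick string or
#'   file path).
#' @param n_genes number of genes in the reference block (>= 2).
#' @param rates named numeric vector of per-unit-branch-length event
#'   rates; names among `split`, `deletion`, `duplication`,
#'   `strand_reversal` (missing names default to 0).
#' @param gene_length simulated gene length in bp (default 900).
#' @param intergenic_gap within-block intergenic gap in bp (default 50).
#' @param locus_spacing distance between loci in bp (default 10000,
#'   i.e. 20x the 500-bp neighboring threshold).
#' @param seed integer seed; a fixed seed makes outputs byte-identical.
#' @param injected_events optional data frame with columns `branch`
#'   (tip label, or integer child-node id for internal branches), `type`,
#'   and optionally `gene` (reference gene label targeted by
#'   deletion/duplication).
#' @param block_name,reference_genome_id identifiers used in the outputs.
#' @return Object of class `block_simulation`: list with `annotations`
#'   (named list of [genome_annotation()], leaves plus reference),
#'   `hits` (`homology_hits`), `block` ([reference_block()]), `tree`
#'   (`phylo`), `truth` (class `ground_truth`: `$log` data frame with
#'   columns branch, type, detail; `$tree`) and `config`.
#' @export
simulate_blocks <- function(tree, n_genes = 8L,
                            rates = c(split = 0, deletion = 0,
                                      duplication = 0,
                                      strand_reversal = 0),
                            gene_length = 900L, intergenic_gap = 50L,
                            locus_spacing = 10000L, seed = NULL,
                            injected_events = NULL,
                            block_name = "simblock",
                            reference_genome_id = "reference") {
  tree <- as_phylo(tree)
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 leaves")
  if (n_genes < 2L) stop("block must have at least 2 genes")
  full_rates <- c(split = 0, deletion = 0, duplication = 0,
                  strand_reversal = 0)
  full_rates[names(rates)] <- rates
  if (any(full_rates < 0)) stop("event rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("g%02d", seq_len(n_genes))
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  edge <- tree$edge
  elen <- tree$edge.length
  if (is.null(elen)) elen <- rep(1, nrow(edge))

  # genome state: list of loci, each list(labels = chr, strand = "+"/"-")
  states <- vector("list", max(edge))
  states[[root]] <- list(list(labels = labels, strand = "+"))
  log_rows <- list()

  branch_key <- function(child) {
    if (child <= ntip) tree$tip.label[child] else as.character(child)
  }

  apply_event <- function(state, type) {
    # returns list(state, detail) or NULL when no eligible target
    if (type %in% c("deletion", "duplication")) {
      copies <- do.call(rbind, lapply(seq_along(state), function(k) {
        if (length(state[[k]]$labels) == 0L) return(NULL)
        cbind(k, seq_along(state[[k]]$labels))
      }))
      if (is.null(copies) || nrow(copies) == 0L) return(NULL)
      pick <- copies[sample.int(nrow(copies), 1L), ]
      k <- pick[1L]; pos <- pick[2L]
      lab <- state[[k]]$labels[pos]
      if (type == "deletion") {
        state[[k]]$labels <- state[[k]]$labels[-pos]
        if (length(state[[k]]$labels) == 0L) state[[k]] <- NULL
      } else {
        state[[k]]$labels <- append(state[[k]]$labels, lab, after = pos)
      }
      return(list(state = state, detail = lab))
    }
    # split / strand_reversal: need a locus with >= 2 genes
    eligible <- which(vapply(state, function(l) length(l$labels) >= 2L,
                             logical(1L)))
    if (length(eligible) == 0L) return(NULL)
    k <- eligible[sample.int(length(eligible), 1L)]
    len <- length(state[[k]]$labels)
    cut <- sample.int(len - 1L, 1L)
    suffix <- state[[k]]$labels[(cut + 1L):len]
    strand <- state[[k]]$strand
    state[[k]]$labels <- state[[k]]$labels[seq_len(cut)]
    if (type == "strand_reversal") strand <- if (strand == "+") "-" else "+"
    state[[length(state) + 1L]] <- list(labels = suffix, strand = strand)
    list(state = state,
         detail = paste0("after:", state[[k]]$labels[cut]))
  }

  targeted_event <- function(state, type, gene) {
    # deterministic variant used by injected events with a named gene
    if (type %in% c("deletion", "duplication")) {
      for (k in seq_along(state)) {
        pos <- match(gene, state[[k]]$labels)
        if (!is.na(pos)) {
          if (type == "deletion") {
            state[[k]]$labels <- state[[k]]$labels[-pos]
            if (length(state[[k]]$labels) == 0L) state[[k]] <- NULL
          } else {
            state[[k]]$labels <- append(state[[k]]$labels, gene,
                                        after = pos)
          }
          return(list(state = state, detail = gene))
        }
      }
      return(NULL)
    }
    # split at a named gene: cut right after it
    for (k in seq_along(state)) {
      pos <- match(gene, state[[k]]$labels)
      if (!is.na(pos) && pos < length(state[[k]]$labels)) {
        len <- length(state[[k]]$labels)
        suffix <- state[[k]]$labels[(pos + 1L):len]
        strand <- state[[k]]$strand
        state[[k]]$labels <- state[[k]]$labels[seq_len(pos)]
        if (type == "strand_reversal") {
          strand <- if (strand == "+") "-" else "+"
        }
        state[[length(state) + 1L]] <- list(labels = suffix,
                                            strand = strand)
        return(list(state = state, detail = paste0("after:", gene)))
      }
    }
    NULL
  }

  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1L]
    child <- edge[e, 2L]
    state <- states[[parent]]
    if (!is.null(injected_events)) {
      ev <- injected_events[injected_events$branch == branch_key(child), ,
                            drop = FALSE]
      if (nrow(ev) > 0L) {
        for (r in seq_len(nrow(ev))) {
          gene <- if ("gene" %in% names(ev)) ev$gene[r] else NA_character_
          res <- if (!is.na(gene)) {
            targeted_event(state, ev$type[r], gene)
          } else {
            apply_event(state, ev$type[r])
          }
          if (is.null(res)) {
            stop("injected event could not be applied: ", ev$type[r],
                 " on branch ", branch_key(child))
          }
          state <- res$state
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            branch = child, branch_label = branch_key(child),
            type = ev$type[r], detail = res$detail,
            stringsAsFactors = FALSE)
        }
      }
    } else {
      for (type in names(full_rates)) {
        if (full_rates[[type]] == 0) next
        k_events <- stats::rpois(1L, full_rates[[type]] * elen[e])
        for (i in seq_len(k_events)) {
          res <- apply_event(state, type)
          if (is.null(res)) next  # no eligible target; event not applied
          state <- res$state
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            branch = child, branch_label = branch_key(child),
            type = type, detail = res$detail, stringsAsFactors = FALSE)
        }
      }
    }
    states[[child]] <- state
  }

  log <- if (length(log_rows) == 0L) {
    data.frame(branch = integer(), branch_label = character(),
               type = character(), detail = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, log_rows)
  }

  annotations <- list()
  hit_rows <- list()
  for (tip in seq_len(ntip)) {
    gid <- tree$tip.label[tip]
    state <- states[[tip]]
    rows <- list()
    copy_counter <- integer()
    cursor <- 1L
    for (k in seq_along(state)) {
      for (lab in state[[k]]$labels) {
        n_prev <- if (lab %in% names(copy_counter)) copy_counter[[lab]] else 0L
        copy_counter[lab] <- n_prev + 1L
        gene_id <- sprintf("%s_%d", lab, n_prev + 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = gid, contig_id = "chr1", gene_id = gene_id,
          start = cursor, end = cursor + gene_length - 1L,
          strand = state[[k]]$strand, name = lab,
          stringsAsFactors = FALSE)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          query_gene_id = lab,
          subject_gene_id = gene_id,
          subject_genome_id = gid,
          evalue = 1e-50, bitscore = 500,
          stringsAsFactors = FALSE)
        cursor <- cursor + gene_length + intergenic_gap
      }
      cursor <- cursor + locus_spacing
    }
    annotations[[gid]] <- genome_annotation(
      if (length(rows) == 0L) {
        data.frame(genome_id = character(), contig_id = character(),
                   gene_id = character(), start = integer(),
                   end = integer(), strand = character(),
                   stringsAsFactors = FALSE)
      } else {
        do.call(rbind, rows)
      })
  }
  ref_rows <- data.frame(
    genome_id = reference_genome_id, contig_id = "chr1",
    gene_id = labels,
    start = seq(1L, by = gene_length + intergenic_gap,
                length.out = n_genes),
    end = seq(gene_length, by = gene_length + intergenic_gap,
              length.out = n_genes),
    strand = "+", name = labels, stringsAsFactors = FALSE)
  annotations[[reference_genome_id]] <- genome_annotation(ref_rows)
  hits <- if (length(hit_rows) == 0L) empty_hits() else {
    h <- do.call(rbind, hit_rows)
    class(h) <- c("homology_hits", "data.frame")
    h
  }
  structure(list(
    annotations = annotations,
    hits = hits,
    block = reference_block(block_name, labels, reference_genome_id),
    tree = tree,
    truth = structure(list(tree = tree, log = log),
                      class = "ground_truth"),
    config = list(n_genes = n_genes, rates = full_rates,
                  gene_length = gene_length,
                  intergenic_gap = intergenic_gap,
                  locus_spacing = locus_spacing, seed = seed)),
    class = "block_simulation")
}

#' @export
print.block_simulation <- function(x, ...) {
  cat(sprintf(
    "Gene block simulation: %d-gene block '%s' over %d leaves; %d event(s)\n",
    x$config$n_genes, x$block$block_name, ape::Ntip(x$tree),
    nrow(x$truth$log)))
  invisible(x)
}

#' Expected pairwise event-count matrix from a ground-truth log
#'
#' Entry (i, j) is the number of logged events of the given type on the
#' tree path between leaves i and j. Strand reversals are measured as
#' splits by the event model, so `event = "split"` includes them.
#'
#' @param truth `ground_truth` from [simulate_blocks()].
#' @param event one of `"split"`, `"deletion"`, `"duplication"`.
#' @return Symmetric integer matrix over the leaves (zero diagonal).
#' @export
expected_distances <- function(truth, event = c("split", "deletion",
                                                "duplication")) {
  event <- match.arg(event)
  types <- if (event == "split") c("split", "strand_reversal") else event
  tree <- truth$tree
  ntip <- ape::Ntip(tree)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ape::Ntip(tree) + 1L
  path_to_root <- function(node) {
    out <- integer()
    while (node != root) {
      out <- c(out, node)  # edge identified by its child node
      node <- parent[node]
    }
    out
  }
  counts <- table(factor(truth$log$branch[truth$log$type %in% types],
                         levels = seq_len(max(tree$edge))))
  m <- matrix(0L, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(ntip), path_to_root)
  for (i in seq_len(ntip - 1L)) {
    for (j in seq((i + 1L), ntip)) {
      edges <- c(setdiff(paths[[i]], paths[[j]]),
                 setdiff(paths[[j]], paths[[i]]))
      v <- sum(counts[edges])
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Sample a non-interacting injected event set
#'
#' Draws `n_events` deletion/duplication events targeting distinct
#' reference genes on uniformly chosen branches. Because no two events
#' touch the same gene and neither type moves block boundaries, the
#' pipeline-inferred deletion and duplication distance matrices equal the
#' ground-truth path sums exactly -- the configuration used by the
#' simulator-recovery validation.
#'
#' @param tree `phylo` (or Newick) tree.
#' @param n_genes block size.
#' @param n_events number of events (must leave >= 2 genes intact:
#'   `n_events <= n_genes - 2`).
#' @param types event types to sample from.
#' @return Data frame with columns `branch`, `type`, `gene`, suitable for
#'   `injected_events` in [simulate_blocks()].
#' @export
sample_noninteracting_events <- function(tree, n_genes, n_events,
                                         types = c("deletion",
                                                   "duplication")) {
  tree <- as_phylo(tree)
  if (n_events > n_genes - 2L) {
    stop("n_events must be <= n_genes - 2 to keep the block detectable")
  }
  ntip <- ape::Ntip(tree)
  branch_children <- tree$edge[, 2L]
  genes <- sample(sprintf("g%02d", seq_len(n_genes)), n_events)
  children <- branch_children[sample.int(length(branch_children),
                                         n_events, replace = TRUE)]
  data.frame(
    branch = ifelse(children <= ntip, tree$tip.label[children],
                    as.character(children)),
    type = sample(types, n_events, replace = TRUE),
    gene = genes, stringsAsFactors = FALSE)
}

#' Write a simulation to disk in the pipeline's input dialects
#'
#' Emits gene-table TSVs (one per genome, including the reference), a
#' 12-column BLAST-outfmt-6-compatible homology table with composite
#' `genome|gene` subject ids, the reference block TSV, the Newick tree,
#' and the ground-truth log as JSON.
#'
#' @param sim a `block_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "block_simulation"))
  ann_dir <- file.path(dir, "annotations")
  dir.create(ann_dir, recursive = TRUE, showWarnings = FALSE)
  for (gid in names(sim$annotations)) {
    write_gene_table(sim$annotations[[gid]],
                     file.path(ann_dir, paste0(gid, ".tsv")))
  }
  write_reference_blocks(list(sim$block), file.path(dir, "blocks.tsv"))
  h <- sim$hits
  blast <- data.frame(
    qseqid = h$query_gene_id,
    sseqid = paste(h$subject_genome_id, h$subject_gene_id, sep = "|"),
    pident = 100, length = sim$config$gene_length %/% 3L, mismatch = 0,
    gapopen = 0, qstart = 1, qend = sim$config$gene_length %/% 3L,
    sstart = 1, send = sim$config$gene_length %/% 3L,
    evalue = h$evalue, bitscore = h$bitscore, stringsAsFactors = FALSE)
  utils::write.table(blast, file.path(dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(log = sim$truth$log,
         config = sim$config[c("n_genes", "gene_length",
                               "intergenic_gap", "locus_spacing")]),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
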