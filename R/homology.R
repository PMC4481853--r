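#' Parse BLAST tabular output (outfmt 6)
#'
#' Reads the standard 12-column BLAST tabular format (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore) and
#' keeps the columns the event model needs: query id, subject id, e-value
#' and bitscore. Duplicate (query, subject) pairs -- multiple HSPs -- are
#' collapsed to the single best hit: lowest e-value, ties broken by
#' highest bitscore.
#'
#' The subject genome is resolved either through `id_map` (a data frame
#' with columns `seq_id`, `genome_id`) or, by default, from composite
#' subject identifiers of the form `genome|gene` (separator configurable).
#'
#' @param path path to a BLAST outfmt-6 file.
#' @param id_map optional data frame mapping subject sequence ids to genome
#'   ids (columns `seq_id`, `genome_id`).
#' @param composite_sep separator of `genome|gene` composite subject ids.
#' @return A data frame of class `homology_hits` with columns
#'   `query_gene_id`, `subject_gene_id`, `subject_genome_id`, `evalue`,
#'   `bitscore`.
#' @export
parse_blast_tab <- function(path, id_map = NULL, composite_sep = "|") {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols != 12L)
  if (length(bad) > 0L) {
    stop("BLAST tabular line ", bad[1L], " has ", ncols[bad[1L]],
         " columns; expected 12")
  }
  mat <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  suppressWarnings({
    evalue <- as.numeric(mat[, 11L])
    bitscore <- as.numeric(mat[, 12L])
  })
  bad <- which(is.na(evalue))
  if (length(bad) > 0L) {
    stop("non-numeric e-value at BLAST tabular line ", bad[1L])
  }
  bad <- which(is.na(bitscore))
  if (length(bad) > 0L) {
    stop("non-numeric bitscore at BLAST tabular line ", bad[1L])
  }
  subject_raw <- mat[, 2L]
  if (!is.null(id_map)) {
    idx <- match(subject_raw, id_map$seq_id)
    if (anyNA(idx)) {
      stop("subject id(s) absent from id_map: ",
           paste(unique(subject_raw[is.na(idx)]), collapse = ", "))
    }
    genome <- as.character(id_map$genome_id[idx])
    subject <- subject_raw
  } else {
    parts <- strsplit(subject_raw, composite_sep, fixed = TRUE)
    if (any(lengths(parts) < 2L)) {
      stop("subject id(s) are not 'genome", composite_sep,
           "gene' composites and no id_map was given: ",
           paste(utils::head(subject_raw[lengths(parts) < 2L], 3L),
                 collapse = ", "))
    }
    genome <- vapply(parts, `[[`, character(1L), 1L)
    subject <- vapply(parts, function(p)
      paste(p[-1L], collapse = composite_sep), character(1L))
  }
  hits <- data.frame(query_gene_id = mat[, 1L],
                     subject_gene_id = subject,
                     subject_genome_id = genome,
                     evalue = evalue,
                     bitscore = bitscore,
                     stringsAsFactors = FALSE)
  # best HSP per (query, subject-in-genome) pair
  ord <- order(hits$query_gene_id, hits$subject_genome_id,
               hits$subject_gene_id, hits$evalue, -hits$bitscore)
  hits <- hits[ord, , drop = FALSE]
  key <- paste(hits$query_gene_id, hits$subject_genome_id,
               hits$subject_gene_id, sep = "\r")
  hits <- hits[!duplicated(key), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("homology_hits", "data.frame")
  hits
}

empty_hits <- function() {
  hits <- data.frame(query_gene_id = character(),
                     subject_gene_id = character(),
                     subject_genome_id = character(),
                     evalue = numeric(), bitscore = numeric(),
                     stringsAsFactors = FALSE)
  class(hits) <- c("homology_hits", "data.frame")
  hits
}

#' Build the reference-gene to target-homolog map for one block
#'
#' For every gene of a reference block, collects the set of target-genome
#' genes hitting it at `evalue <= max_evalue` (the threshold is inclusive:
#' an e-value of exactly 1e-10 passes). Genes with no passing hit map to
#' the empty set -- absence is data (a candidate deletion), not an error.
#' Hits to genomes other than `target_genome` are ignored, which also
#' drops reference self-hits when the target is a different genome.
#'
#' @param hits a `homology_hits` data frame from [parse_blast_tab()].
#' @param block a [reference_block()].
#' @param target_genome genome id of the target genome.
#' @param max_evalue inclusive e-value threshold (default 1e-10).
#' @return An object of class `homolog_map`: a named list, reference gene
#'   id -> character vector of target gene ids (possibly empty), with
#'   attributes `block_name`, `genome_id` and `evalues` (named numeric
#'   vector keyed `ref\rtarget` used for deterministic tie-breaks).
#' @export
build_homolog_map <- function(hits, block, target_genome,
                              max_evalue = 1e-10) {
  stopifnot(inherits(block, "reference_block"))
  keep <- hits$subject_genome_id == target_genome &
    hits$query_gene_id %in% block$gene_ids &
    hits$evalue <= max_evalue
  hits <- hits[keep, , drop = FALSE]
  map <- lapply(block$gene_ids, function(g) {
    sort(unique(hits$subject_gene_id[hits$query_gene_id == g]))
  })
  names(map) <- block$gene_ids
  ev <- hits$evalue
  names(ev) <- paste(hits$query_gene_id, hits$subject_gene_id, sep = "\r")
  structure(map, block_name = block$block_name, genome_id = target_genome,
            max_evalue = max_evalue, evalues = ev, class = "homolog_map")
}

#' @export
print.homolog_map <- function(x, ...) {
  cat(sprintf("Homolog map: block '%s' in genome '%s' (e-value <= %g)\n",
              attr(x, "block_name"), attr(x, "genome_id"),
              attr(x, "max_evalue")))
  for (g in names(x)) {
    cat(sprintf("  %s -> %s\n", g,
                if (length(x[[g]]) == 0L) "(none)"
                else paste(x[[g]], collapse = ", ")))
  }
  invisible(x)
}
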