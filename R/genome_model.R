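#' Construct a genome annotation
#'
#' A genome annotation is the set of protein-coding gene coordinates of one
#' genome: a data frame with one row per gene and columns `genome_id`,
#' `contig_id`, `gene_id`, `start`, `end`, `strand` and `name`. Coordinates
#' are 1-based inclusive nucleotide positions (the GFF3 convention) and
#' `strand` is `"+"` or `"-"`.
#'
#' @param genes data frame with at least columns `genome_id`, `contig_id`,
#'   `gene_id`, `start`, `end`, `strand`; an optional `name` column holds a
#'   display label.
#' @return An object of class `genome_annotation` (a data frame), sorted by
#'   contig and start coordinate.
#' @export
genome_annotation <- function(genes) {
  required <- c("genome_id", "contig_id", "gene_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!"name" %in% names(genes)) {
    genes$name <- rep(NA_character_, nrow(genes))
  }
  genes <- genes[, c(required, "name")]
  for (col in c("genome_id", "contig_id", "gene_id", "strand", "name")) {
    genes[[col]] <- as.character(genes[[col]])
  }
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (nrow(genes) > 0L) {
    if (anyNA(genes$start) || anyNA(genes$end)) {
      stop("non-numeric start/end coordinate in annotation")
    }
    bad <- genes$end < genes$start | genes$start < 1L
    if (any(bad)) {
      stop("invalid coordinates (end < start or start < 1) for gene(s): ",
           paste(genes$gene_id[bad], collapse = ", "))
    }
    if (!all(genes$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'")
    }
    dup <- genes$gene_id[duplicated(genes$gene_id)]
    if (length(dup) > 0L) {
      stop("duplicated gene_id within genome: ",
           paste(unique(dup), collapse = ", "))
    }
    genes <- genes[order(genes$contig_id, genes$start, genes$end), ,
                   drop = FALSE]
    rownames(genes) <- NULL
  }
  class(genes) <- c("genome_annotation", "data.frame")
  genes
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("Genome annotation '%s': %d genes on %d contig(s)\n",
              if (nrow(x) > 0L) x$genome_id[1L] else "<empty>",
              nrow(x), length(unique(x$contig_id))))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Read gene annotations from GFF3 or a gene table
#'
#' Two dialects are supported. `"gff3"` is standard 9-column GFF3; records
#' whose type is in `feature_types` (by default `gene` and `CDS`, i.e.
#' protein-coding features; RNA genes are excluded) are kept and the gene
#' identifier is taken from the `ID=` (or, failing that, `locus_tag=` or
#' `Name=`) attribute. `"gene-table"` is a headered TSV with columns
#' `genome_id`, `contig_id`, `gene_id`, `start`, `end`, `strand`, `name`.
#' Both dialects carry 1-based inclusive coordinates, which are used as
#' given (no shifting).
#'
#' @param path path to the annotation file.
#' @param format `"gff3"` or `"gene-table"`.
#' @param genome_id genome identifier to assign (gff3 only; defaults to the
#'   file name without extension).
#' @param feature_types GFF3 feature types treated as protein-coding genes.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("gff3", "gene-table"),
                            genome_id = NULL,
                            feature_types = c("gene", "CDS")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gene-table") {
    return(read_gene_table(path))
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  gff <- tryCatch(
    ape::read.gff(path, GFF3 = TRUE),
    error = function(e) stop("failed to parse GFF3 '", path, "': ",
                             conditionMessage(e)),
    warning = function(w) stop("failed to parse GFF3 '", path, "': ",
                               conditionMessage(w))
  )
  gff <- gff[as.character(gff$type) %in% feature_types, , drop = FALSE]
  if (nrow(gff) == 0L) {
    return(genome_annotation(data.frame(
      genome_id = character(), contig_id = character(),
      gene_id = character(), start = integer(), end = integer(),
      strand = character(), stringsAsFactors = FALSE)))
  }
  ids <- gff_attribute(gff$attributes, "ID")
  fallback <- is.na(ids)
  if (any(fallback)) {
    ids[fallback] <- gff_attribute(gff$attributes[fallback], "locus_tag")
  }
  fallback <- is.na(ids)
  if (any(fallback)) {
    ids[fallback] <- gff_attribute(gff$attributes[fallback], "Name")
  }
  if (anyNA(ids)) {
    stop("GFF3 record(s) without ID/locus_tag/Name attribute in ", path)
  }
  names_attr <- gff_attribute(gff$attributes, "Name")
  genome_annotation(data.frame(
    genome_id = genome_id,
    contig_id = as.character(gff$seqid),
    gene_id = ids,
    start = gff$start,
    end = gff$end,
    strand = as.character(gff$strand),
    name = names_attr,
    stringsAsFactors = FALSE))
}

gff_attribute <- function(attributes, key) {
  pattern <- paste0("(^|;)\\s*", key, "=([^;]+)")
  m <- regmatches(attributes, regexec(pattern, attributes))
  vapply(m, function(x) if (length(x) >= 3L) x[3L] else NA_character_,
         character(1L))
}

#' Read a gene-table TSV
#'
#' @param path headered TSV with columns `genome_id`, `contig_id`,
#'   `gene_id`, `start`, `end`, `strand` and optionally `name`.
#' @return A [genome_annotation()].
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  required <- c("genome_id", "contig_id", "gene_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("gene table '", path, "' is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  suppressWarnings({
    start <- as.integer(tab$start)
    end <- as.integer(tab$end)
  })
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("non-numeric coordinate at line ", bad[1L] + 1L, " of ", path)
  }
  tab$start <- start
  tab$end <- end
  genome_annotation(tab)
}

#' Write a genome annotation as a gene-table TSV
#'
#' The gene-table dialect round-trips gene identifiers, coordinates and
#' strand exactly through [read_gene_table()].
#'
#' @param annotation a [genome_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a reference gene block (operon) definition
#'
#' A reference block names an experimentally determined operon in the
#' reference taxon and lists its genes in chromosomal order. A gene block
#' comprises no fewer than two ORFs, so at least two gene identifiers are
#' required.
#'
#' @param block_name block (operon) name.
#' @param gene_ids ordered character vector of reference gene identifiers,
#'   length >= 2.
#' @param reference_genome_id identifier of the reference genome.
#' @return An object of class `reference_block`.
#' @export
reference_block <- function(block_name, gene_ids,
                            reference_genome_id = NA_character_) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) < 2L) {
    stop("reference block '", block_name,
         "' has fewer than 2 genes; a gene block needs at least two ORFs")
  }
  if (anyDuplicated(gene_ids)) {
    stop("reference block '", block_name, "' lists duplicate gene ids")
  }
  structure(list(block_name = as.character(block_name),
                 reference_genome_id = as.character(reference_genome_id),
                 gene_ids = gene_ids),
            class = "reference_block")
}

#' @export
print.reference_block <- function(x, ...) {
  cat(sprintf("Reference block '%s' (%d genes): %s\n", x$block_name,
              length(x$gene_ids), paste(x$gene_ids, collapse = ", ")))
  invisible(x)
}

#' Read reference block definitions
#'
#' TSV dialect: two headered columns, `block_name` and `gene_ids`, the
#' latter a comma-separated ordered list of reference gene identifiers.
#' JSON dialect (`.json` extension): an array of objects with fields
#' `block_name` and `gene_ids`.
#'
#' @param path path to the block definition file.
#' @param reference_genome_id identifier of the reference genome.
#' @param annotation optional reference [genome_annotation()]; when given,
#'   every listed gene id must resolve in it.
#' @return List of [reference_block()] objects, in file order.
#' @export
read_reference_blocks <- function(path, reference_genome_id = NA_character_,
                                  annotation = NULL) {
  if (!file.exists(path)) stop("block file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    blocks <- lapply(recs, function(r) {
      reference_block(r$block_name, unlist(r$gene_ids), reference_genome_id)
    })
  } else {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             colClasses = "character",
                             stringsAsFactors = FALSE, quote = "")
    if (!all(c("block_name", "gene_ids") %in% names(tab))) {
      stop("block file '", path,
           "' must have columns block_name and gene_ids")
    }
    blocks <- lapply(seq_len(nrow(tab)), function(i) {
      ids <- trimws(strsplit(tab$gene_ids[i], ",", fixed = TRUE)[[1L]])
      ids <- ids[nzchar(ids)]
      reference_block(tab$block_name[i], ids, reference_genome_id)
    })
  }
  if (!is.null(annotation)) {
    for (b in blocks) {
      unresolved <- setdiff(b$gene_ids, annotation$gene_id)
      if (length(unresolved) > 0L) {
        stop("block '", b$block_name,
             "' lists gene id(s) absent from the reference annotation: ",
             paste(unresolved, collapse = ", "))
      }
    }
  }
  blocks
}

#' Write reference block definitions as TSV
#'
#' @param blocks list of [reference_block()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_blocks <- function(blocks, path) {
  tab <- data.frame(
    block_name = vapply(blocks, function(b) b$block_name, character(1L)),
    gene_ids = vapply(blocks, function(b) paste(b$gene_ids, collapse = ","),
                      character(1L)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the operon selection filters
#'
#' Retains blocks that (i) comprise at least `min_genes` genes and (ii)
#' have orthoblocks in at least `min_orthoblock_taxa` genomes other than
#' the reference, as counted by [orthoblock_census()]. The defaults (5
#' genes, 9 other genomes) are the curation thresholds used for
#' experimentally determined operons.
#'
#' @param blocks list of [reference_block()] objects.
#' @param census named integer vector or list, block_name -> number of
#'   non-reference genomes with an orthoblock.
#' @param min_genes minimum block length in genes (default 5).
#' @param min_orthoblock_taxa minimum number of other genomes with an
#'   orthoblock (default 9).
#' @return Filtered list of blocks, original order preserved.
#' @export
filter_reference_blocks <- function(blocks, census, min_genes = 5L,
                                    min_orthoblock_taxa = 9L) {
  keep <- vapply(blocks, function(b) {
    if (!b$block_name %in% names(census)) {
      stop("orthoblock census has no entry for block '", b$block_name, "'")
    }
    length(b$gene_ids) >= min_genes &&
      census[[b$block_name]] >= min_orthoblock_taxa
  }, logical(1L))
  blocks[keep]
}
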