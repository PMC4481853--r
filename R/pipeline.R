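#' Assemble a run configuration
#'
#' @param annotations_dir directory of per-genome annotation files
#'   (`.tsv` gene tables and/or `.gff3`).
#' @param blocks_file reference block definition file
#'   ([read_reference_blocks()]).
#' @param hits_file BLAST outfmt-6 homology table
#'   ([parse_blast_tab()]).
#' @param tree_file Newick species tree.
#' @param out_dir output directory.
#' @param reference_genome_id id of the reference genome (excluded from
#'   the orthoblock census).
#' @param max_gap neighboring-gene threshold in bp (default 500).
#' @param max_evalue inclusive homology e-value threshold (default 1e-10).
#' @param min_genes,min_orthoblock_taxa operon selection filters
#'   (defaults 5 and 9); set `apply_filters = FALSE` to analyse every
#'   block regardless.
#' @param apply_filters whether to apply the operon selection filters.
#' @param render_heatmaps also write PNG heatmaps next to the TSV
#'   phylomatrices.
#' @param log_level `"info"` or `"quiet"`.
#' @return List of class `run_config`.
#' @export
run_config <- function(annotations_dir, blocks_file, hits_file, tree_file,
                       out_dir, reference_genome_id = "reference",
                       max_gap = 500L, max_evalue = 1e-10,
                       min_genes = 5L, min_orthoblock_taxa = 9L,
                       apply_filters = FALSE, render_heatmaps = FALSE,
                       log_level = "info") {
  structure(list(annotations_dir = annotations_dir,
                 blocks_file = blocks_file, hits_file = hits_file,
                 tree_file = tree_file, out_dir = out_dir,
                 reference_genome_id = reference_genome_id,
                 max_gap = as.integer(max_gap),
                 max_evalue = as.numeric(max_evalue),
                 min_genes = as.integer(min_genes),
                 min_orthoblock_taxa = as.integer(min_orthoblock_taxa),
                 apply_filters = isTRUE(apply_filters),
                 render_heatmaps = isTRUE(render_heatmaps),
                 log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys are the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

pipeline_log <- function(config, stage, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full orthoblock analysis pipeline
#'
#' Executes, in order: annotation reading, block reading, homology
#' parsing, orthoblock assembly, the orthoblock census (and optionally
#' the operon selection filters), pairwise event distances, the
#' conservation ranking, and per-(block, event) phylomatrices ordered by
#' the species tree. All stages are pure functions of the input files,
#' so re-running an identical configuration reproduces identical
#' outputs. A JSON manifest records inputs, parameters, package version
#' and per-stage record counts.
#'
#' Output files under `out_dir`: `orthoblocks.tsv`, `distances.tsv`,
#' `ranking.tsv`, `census.tsv`, `phylomatrix/<block>_<event>.tsv`
#' (plus `.png` when `render_heatmaps`), and `manifest.json`.
#'
#' @param config a `run_config` (or path to a YAML file).
#' @return Invisibly, a list with the in-memory results: `annotations`,
#'   `blocks`, `hits`, `orthoblocks`, `census`, `distances`, `ranking`,
#'   `phylomatrices`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  # pre-flight: every input must resolve before any computation
  for (p in c(config$annotations_dir, config$blocks_file,
              config$hits_file, config$tree_file)) {
    if (!file.exists(p)) stop("pre-flight: input path does not exist: ", p)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "annotations"
  ann_files <- list.files(config$annotations_dir,
                          pattern = "\\.(tsv|gff3?|gff)$",
                          full.names = TRUE)
  if (length(ann_files) == 0L) {
    stop("stage ", stage, ": no annotation files in ",
         config$annotations_dir)
  }
  annotations <- list()
  for (f in sort(ann_files)) {
    fmt <- if (grepl("\\.tsv$", f)) "gene-table" else "gff3"
    ann <- tryCatch(read_annotation(f, fmt),
                    error = function(e) stop("stage ", stage, ": ",
                                             conditionMessage(e)))
    if (nrow(ann) == 0L) next
    annotations[[ann$genome_id[1L]]] <- ann
  }
  pipeline_log(config, stage, "%d genomes, %d genes total",
               length(annotations),
               sum(vapply(annotations, nrow, integer(1L))))

  stage <- "blocks"
  ref_ann <- annotations[[config$reference_genome_id]]
  blocks <- tryCatch(
    read_reference_blocks(config$blocks_file,
                          config$reference_genome_id, ref_ann),
    error = function(e) stop("stage ", stage, ": ", conditionMessage(e)))
  pipeline_log(config, stage, "%d reference blocks", length(blocks))

  stage <- "homology"
  hits <- tryCatch(parse_blast_tab(config$hits_file),
                   error = function(e) stop("stage ", stage, ": ",
                                            conditionMessage(e)))
  pipeline_log(config, stage, "%d hits kept", nrow(hits))

  stage <- "orthoblocks"
  targets <- annotations[names(annotations) != config$reference_genome_id]
  orthoblocks <- build_orthoblocks(blocks, targets, hits,
                                   config$max_gap, config$max_evalue)
  census <- vapply(blocks, function(b) {
    sum(!vapply(orthoblocks[[b$block_name]], is.null, logical(1L)))
  }, integer(1L))
  names(census) <- vapply(blocks, `[[`, character(1L), "block_name")
  if (config$apply_filters) {
    blocks <- filter_reference_blocks(blocks, census, config$min_genes,
                                      config$min_orthoblock_taxa)
    orthoblocks <- orthoblocks[vapply(blocks, `[[`, character(1L),
                                      "block_name")]
  }
  ob_tab <- orthoblock_table(orthoblocks, targets)
  utils::write.table(ob_tab, file.path(config$out_dir, "orthoblocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(block_name = names(census), n_taxa = as.integer(census)),
    file.path(config$out_dir, "census.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  pipeline_log(config, stage, "%d orthoblocks found over %d blocks",
               sum(!vapply(unlist(orthoblocks, recursive = FALSE),
                           is.null, logical(1L))), length(blocks))

  stage <- "events"
  distances <- suppressWarnings(pairwise_event_table(orthoblocks, blocks))
  utils::write.table(distances, file.path(config$out_dir, "distances.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pipeline_log(config, stage, "%d pairwise comparisons",
               nrow(distances) %/% 3L)

  stage <- "rank"
  ranking <- conservation_rank(distances)
  utils::write.table(ranking, file.path(config$out_dir, "ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stage <- "phylomatrix"
  pm_dir <- file.path(config$out_dir, "phylomatrix")
  dir.create(pm_dir, showWarnings = FALSE)
  tree <- ape::read.tree(config$tree_file)
  phylomatrices <- list()
  for (b in blocks) {
    obs <- orthoblocks[[b$block_name]]
    present <- sum(!vapply(obs, is.null, logical(1L)))
    if (present < 2L) next
    for (event in c("split", "deletion", "duplication")) {
      dm <- all_pairs_distances(obs, b, event)
      pm <- tryCatch(phylomatrix(dm, tree), error = function(e)
        stop("stage ", stage, " (block ", b$block_name, ", ", event,
             "): ", conditionMessage(e)))
      key <- paste0(b$block_name, "_", event)
      phylomatrices[[key]] <- pm
      write_phylomatrix_tsv(pm, file.path(pm_dir, paste0(key, ".tsv")))
      if (config$render_heatmaps) {
        render_phylomatrix(pm, file.path(pm_dir, paste0(key, ".png")),
                           "png")
      }
    }
  }
  pipeline_log(config, stage, "%d phylomatrices", length(phylomatrices))

  manifest <- list(
    inputs = list(annotations_dir = config$annotations_dir,
                  blocks_file = config$blocks_file,
                  hits_file = config$hits_file,
                  tree_file = config$tree_file),
    parameters = config[c("reference_genome_id", "max_gap", "max_evalue",
                          "min_genes", "min_orthoblock_taxa",
                          "apply_filters")],
    software = list(package = "orthoblockr",
                    version = as.character(utils::packageVersion(
                      "orthoblockr"))),
    counts = list(genomes = length(annotations),
                  genes = sum(vapply(annotations, nrow, integer(1L))),
                  blocks = length(blocks),
                  hits = nrow(hits),
                  orthoblocks = sum(!vapply(
                    unlist(orthoblocks, recursive = FALSE), is.null,
                    logical(1L))),
                  pairwise_comparisons = nrow(distances) %/% 3L,
                  phylomatrices = length(phylomatrices)))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(annotations = annotations, blocks = blocks, hits = hits,
                 orthoblocks = orthoblocks, census = census,
                 distances = distances, ranking = ranking,
                 phylomatrices = phylomatrices, manifest = manifest))
}
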