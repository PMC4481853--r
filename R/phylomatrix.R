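#' Z-score normalize a pairwise distance matrix
#'
#' For an event v and the taxa sharing the orthoblock, the normalized
#' matrix entry is `M_ij = (d_v(i,j) - mean) / sd`, where mean and sd are
#' taken over the n_p unordered pairs i < j (the diagonal is excluded
#' from the statistics). By default sd is the population standard
#' deviation over those n_p pairs. When sd is 0 (a fully uniform panel)
#' every entry is defined as 0 rather than NaN, so degenerate
#' fully-conserved blocks render as uniformly conserved.
#'
#' @param distances symmetric numeric distance matrix (as from
#'   [all_pairs_distances()]).
#' @param sd_type `"population"` (divide by n_p; default) or `"sample"`
#'   (divide by n_p - 1).
#' @return Symmetric matrix of z-scores with attributes `mean`, `sd`,
#'   `n_pairs` and any `absent_taxa`/`event`/`block_name` attributes of
#'   the input.
#' @export
zscore_normalize <- function(distances, sd_type = c("population",
                                                    "sample")) {
  sd_type <- match.arg(sd_type)
  n <- nrow(distances)
  if (is.null(n) || n < 2L) {
    stop("z-score normalization needs at least 2 participating taxa")
  }
  vals <- distances[upper.tri(distances)]
  np <- length(vals)
  mu <- mean(vals)
  sigma <- sqrt(sum((vals - mu)^2) /
                  (if (sd_type == "population") np else max(np - 1L, 1L)))
  z <- if (sigma == 0) {
    matrix(0, n, n, dimnames = dimnames(distances))
  } else {
    (distances - mu) / sigma
  }
  attrs <- attributes(distances)
  structure(z, mean = mu, sd = sigma, n_pairs = np,
            absent_taxa = attrs$absent_taxa, event = attrs$event,
            block_name = attrs$block_name)
}

#' Left-to-right leaf order of a phylogeny
#'
#' Returns the tips of a rooted tree in their left-to-right plotting
#' order, restricted to the requested taxa, so that both phylomatrix
#' axes follow the phylogeny. Labels must match exactly; no fuzzy
#' matching is attempted.
#'
#' @param tree an `ape` `phylo` object, a Newick string, or a path to a
#'   Newick file.
#' @param taxa character vector of taxa to keep (default: all tips).
#' @return Character vector of taxa in tree leaf order.
#' @export
order_taxa <- function(tree, taxa = NULL) {
  tree <- as_phylo(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  tips <- tree$edge[, 2L][tree$edge[, 2L] <= ape::Ntip(tree)]
  leaf_order <- tree$tip.label[tips]
  if (is.null(taxa)) return(leaf_order)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0L) {
    stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
  }
  leaf_order[leaf_order %in% taxa]
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, a Newick string, or a file path")
}

#' Build a phylomatrix
#'
#' A phylomatrix is the taxa-by-taxa matrix of z-normalized pairwise
#' event distances for one reference block and one event type, with both
#' axes ordered by the phylogeny. Taxa that lack the orthoblock carry no
#' distances; they are kept in `absent_taxa` and rendered in a reserved
#' no-data color.
#'
#' @param distances distance matrix from [all_pairs_distances()].
#' @param tree phylogeny (see [order_taxa()]).
#' @param sd_type passed to [zscore_normalize()].
#' @return Object of class `phylomatrix`: list with `block_name`, `event`,
#'   `taxa` (tree order), `values` (z-score matrix over participating
#'   taxa, rows/cols in tree order), `absent_taxa`, `mean`, `sd`,
#'   `n_pairs`.
#' @export
phylomatrix <- function(distances, tree, sd_type = "population") {
  z <- zscore_normalize(distances, sd_type)
  participating <- rownames(z)
  absent <- attr(z, "absent_taxa")
  if (is.null(absent)) absent <- character()
  ord_all <- order_taxa(tree, c(participating, absent))
  ord_part <- ord_all[ord_all %in% participating]
  values <- z[ord_part, ord_part, drop = FALSE]
  structure(list(block_name = attr(z, "block_name"),
                 event = attr(z, "event"),
                 taxa = ord_all,
                 values = values,
                 absent_taxa = ord_all[ord_all %in% absent],
                 mean = attr(z, "mean"), sd = attr(z, "sd"),
                 n_pairs = attr(z, "n_pairs")),
            class = "phylomatrix")
}

#' @export
print.phylomatrix <- function(x, ...) {
  cat(sprintf(
    "Phylomatrix: block '%s', event '%s', %d taxa (%d absent); mean %.4g, sd %.4g\n",
    if (is.null(x$block_name)) "?" else x$block_name,
    if (is.null(x$event)) "?" else x$event,
    length(x$taxa), length(x$absent_taxa), x$mean, x$sd))
  invisible(x)
}

#' Write phylomatrix values as TSV (bit-exact)
#'
#' Values are serialized with 17 significant digits so that reading the
#' file back reproduces the doubles exactly. Absent taxa are recorded in
#' a `#absent:` header comment.
#'
#' @param pm a [phylomatrix()] (or a plain numeric matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylomatrix_tsv <- function(pm, path) {
  values <- if (inherits(pm, "phylomatrix")) pm$values else pm
  absent <- if (inherits(pm, "phylomatrix")) pm$absent_taxa else character()
  con <- file(path, "w")
  on.exit(close(con))
  if (length(absent) > 0L) {
    writeLines(paste0("#absent:\t", paste(absent, collapse = "\t")), con)
  }
  writeLines(paste(c("taxon", colnames(values)), collapse = "\t"), con)
  for (i in seq_len(nrow(values))) {
    writeLines(paste(c(rownames(values)[i],
                       sprintf("%.17g", values[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read a phylomatrix TSV written by [write_phylomatrix_tsv()]
#'
#' @param path input path.
#' @return Numeric matrix with dimnames; attribute `absent_taxa` holds
#'   any taxa recorded in the `#absent:` header.
#' @export
read_phylomatrix_tsv <- function(path) {
  lines <- readLines(path)
  absent <- character()
  if (length(lines) > 0L && startsWith(lines[1L], "#absent:")) {
    absent <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
    lines <- lines[-1L]
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  m <- t(vapply(body, function(f) as.numeric(f[-1L]),
                numeric(length(header))))
  rownames(m) <- vapply(body, `[[`, character(1L), 1L)
  colnames(m) <- header
  structure(m, absent_taxa = absent)
}

#' Render a phylomatrix heatmap
#'
#' Draws the taxa-by-taxa z-score matrix with a diverging blue-to-red
#' palette: low z-scores (low distance, high conservation) are blue, high
#' z-scores red. Taxa lacking the orthoblock are drawn in a reserved
#' third color (green by default). Optional clade annotations draw boxes
#' around contiguous runs of taxa sharing a clade. A TSV twin of every
#' image is written alongside so rendering never hides the values.
#'
#' @param pm a [phylomatrix()].
#' @param path output file; extension is replaced to match `format`.
#' @param format `"tsv"`, `"png"` or `"svg"`.
#' @param clades optional data frame with columns `taxon_id`,
#'   `clade_name`.
#' @param absent_color color for no-data taxa.
#' @param zlim symmetric color range; defaults to the data range.
#' @return Path of the written file, invisibly.
#' @export
render_phylomatrix <- function(pm, path, format = c("tsv", "png", "svg"),
                               clades = NULL, absent_color = "green3",
                               zlim = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(pm, "phylomatrix"))
  if (format == "tsv") {
    return(invisible(write_phylomatrix_tsv(pm, path)))
  }
  tsv_twin <- sub("\\.[^.]*$", ".tsv", path)
  write_phylomatrix_tsv(pm, tsv_twin)
  taxa <- pm$taxa
  n <- length(taxa)
  full <- matrix(NA_real_, n, n, dimnames = list(taxa, taxa))
  part <- rownames(pm$values)
  full[part, part] <- pm$values
  if (is.null(zlim)) {
    r <- range(pm$values, finite = TRUE)
    if (!all(is.finite(r)) || diff(r) == 0) r <- c(-1, 1)
    zlim <- r
  }
  if (format == "png") {
    grDevices::png(path, width = 200 + 28 * n, height = 160 + 28 * n,
                   res = 96)
  } else {
    grDevices::svg(path, width = (200 + 28 * n) / 96,
                   height = (160 + 28 * n) / 96)
  }
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101L)
  op <- graphics::par(mar = c(1, 8, 8, 2))
  on.exit(graphics::par(op), add = TRUE)
  # row 1 at the top: flip rows for image()
  img <- t(full[rev(seq_len(n)), , drop = FALSE])
  graphics::image(x = seq_len(n), y = seq_len(n), z = img, zlim = zlim,
                  col = pal, axes = FALSE, xlab = "", ylab = "")
  # absent taxa: whole row/column in the reserved color
  absent_idx <- which(taxa %in% pm$absent_taxa)
  for (k in absent_idx) {
    graphics::rect(0.5, n - k + 0.5, n + 0.5, n - k + 1.5,
                   col = absent_color, border = NA)
    graphics::rect(k - 0.5, 0.5, k + 0.5, n + 0.5,
                   col = absent_color, border = NA)
  }
  graphics::axis(3, at = seq_len(n), labels = taxa, las = 2, tick = FALSE,
                 cex.axis = 0.7)
  graphics::axis(2, at = rev(seq_len(n)), labels = taxa, las = 2,
                 tick = FALSE, cex.axis = 0.7)
  graphics::box()
  if (!is.null(clades)) {
    cl <- clades$clade_name[match(taxa, clades$taxon_id)]
    run <- rle(ifelse(is.na(cl), "", cl))
    pos <- cumsum(run$lengths)
    from <- c(1L, utils::head(pos, -1L) + 1L)
    for (k in seq_along(run$values)) {
      if (!nzchar(run$values[k])) next
      graphics::rect(from[k] - 0.5, n - pos[k] + 0.5,
                     pos[k] + 0.5, n - from[k] + 1.5,
                     border = "black", lwd = 2)
    }
  }
  graphics::mtext(sprintf("%s — %s (z-score)",
                          if (is.null(pm$block_name)) "" else pm$block_name,
                          if (is.null(pm$event)) "" else pm$event),
                  side = 3, line = 6, cex = 0.9)
  invisible(path)
}
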