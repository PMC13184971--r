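#' Read and write genomes-by-samples abundance tables
#'
#' Tab-separated, first column `genome_id`, one numeric column per sample.
#'
#' @param path file path.
#' @param normalize divide each column by its sum after reading.
#' @return `read_abundance_table`: a numeric matrix with genome rownames.
#' @export
read_abundance_table <- function(path, normalize = FALSE) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) stopf("empty abundance table")
  ids <- as.character(tab[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stopf("duplicate genome id in abundance table: %s",
                         paste(dup, collapse = ", "))
  body <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(body)) stopf("non-numeric cells in abundance table")
  if (any(body < 0)) stopf("negative abundance values")
  rownames(body) <- ids
  if (normalize) body <- sweep(body, 2L, colSums(body), "/")
  body
}

#' @rdname read_abundance_table
#' @param abundances genomes-by-samples matrix.
#' @export
write_abundance_table <- function(abundances, path) {
  df <- data.frame(genome_id = rownames(abundances), abundances,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a newick tree for use with an abundance table
#'
#' Missing branch lengths default to zero with a warning; tips absent from
#' `taxa` are pruned with a warning; `taxa` entries absent from the tree
#' raise an error naming the offending ids.
#'
#' @param path newick file path.
#' @param taxa optional character vector of required tip ids.
#' @return an `ape::phylo`.
#' @export
read_tree <- function(path, taxa = NULL) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) stopf("could not parse newick file '%s'", path)
  if (is.null(tree$edge.length)) {
    warnf("tree has no branch lengths; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warnf("missing branch lengths; defaulting to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, tree$tip.label)
    if (length(missing)) {
      stopf("taxa absent from the tree: %s", paste(utils::head(missing, 10L), collapse = ", "))
    }
    extra <- setdiff(tree$tip.label, taxa)
    if (length(extra)) {
      warnf("pruning %d tree tips absent from the table", length(extra))
      tree <- ape::drop.tip(tree, extra)
    }
  }
  tree
}

#' Read / write sample metadata
#'
#' @param path file path.
#' @return data.frame with at least `sample_id`, `stream`, `environment`.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "stream", "environment")
  if (!all(need %in% names(md))) {
    stopf("metadata needs columns %s", paste(need, collapse = ", "))
  }
  md
}

#' @rdname read_metadata
#' @param metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write genome annotations
#'
#' Two-column TSV (`genome_id`, `identifier`), one row per identifier.
#'
#' @param path file path.
#' @return named list of identifier vectors.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "identifier") %in% names(tab))) {
    stopf("annotation file needs columns genome_id, identifier")
  }
  split(tab$identifier, factor(tab$genome_id, levels = unique(tab$genome_id)))
}

#' @rdname read_annotations
#' @param annotations named list of identifier vectors.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(genome_id = rep(names(annotations), lengths(annotations)),
                   identifier = unlist(annotations, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write consensus-allele tables
#'
#' Long-format TSV with columns `genome_id`, `position` (0-based),
#' `sample_id`, `allele`, `covered` (0/1); uncovered rows may be omitted.
#'
#' @param path file path.
#' @return named list (by genome) of positions-by-samples character
#'   matrices with `NA` at uncovered sites.
#' @export
read_alleles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "position", "sample_id", "allele", "covered")
  if (!all(need %in% names(tab))) {
    stopf("allele file needs columns %s", paste(need, collapse = ", "))
  }
  tab$allele[tab$covered == 0] <- NA_character_
  lapply(split(tab, tab$genome_id), function(g) {
    pos <- sort(unique(g$position))
    samples <- unique(g$sample_id)
    m <- matrix(NA_character_, length(pos), length(samples),
                dimnames = list(NULL, samples))
    m[cbind(match(g$position, pos), match(g$sample_id, samples))] <- g$allele
    attr(m, "positions") <- pos
    m
  })
}

#' @rdname read_alleles
#' @param alleles named list of allele matrices.
#' @export
write_alleles <- function(alleles, path) {
  rows <- lapply(names(alleles), function(g) {
    m <- alleles[[g]]
    pos <- attr(m, "positions") %||% (seq_len(nrow(m)) - 1L)
    data.frame(genome_id = g,
               position = rep(pos, times = ncol(m)),
               sample_id = rep(colnames(m), each = nrow(m)),
               allele = ifelse(is.na(as.vector(m)), "N", as.vector(m)),
               covered = as.integer(!is.na(as.vector(m))),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a dataset bundle to a directory of plain-text files
#'
#' Emits `abundances.tsv`, `metadata.tsv`, `tree.nwk`, `annotations.tsv`,
#' `catalogue.tsv`, `pathways.tsv`, `alleles.tsv` and `truth.tsv`.
#'
#' @param bundle a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance_table(bundle$abundances, file.path(dir, "abundances.tsv"))
  write_metadata(bundle$metadata, file.path(dir, "metadata.tsv"))
  writeLines(bundle$tree_newick, file.path(dir, "tree.nwk"))
  write_annotations(bundle$catalogue$annotations, file.path(dir, "annotations.tsv"))
  utils::write.table(bundle$catalogue$genomes, file.path(dir, "catalogue.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_pathway_db(bundle$pathways, file.path(dir, "pathways.tsv"))
  write_alleles(bundle$alleles, file.path(dir, "alleles.tsv"))
  tr <- bundle$truth
  utils::write.table(
    data.frame(genome_id = tr$genome_id,
               true_fraction = unname(tr$true_fraction[tr$genome_id]),
               true_environment = unname(tr$true_environment[tr$genome_id]),
               true_completion_prob = unname(tr$true_completion_prob[tr$genome_id]),
               stringsAsFactors = FALSE),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
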