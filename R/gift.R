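#' Score a step expression against a genome's identifier set
#'
#' Scoring rules: an `IDENT` node scores 1 when the identifier is present and
#' 0 otherwise; `ALL_OF` scores the arithmetic mean of its children, so a
#' step requiring two identifiers is complete (1) with both present,
#' half-complete (0.5) with one, and empty (0) with neither; `ANY_OF` scores
#' the maximum of its children (the best alternative route counts).
#'
#' @param expr a step expression (see [parse_step_expression()]).
#' @param present character vector of identifiers carried by the genome.
#' @return a value in \[0, 1\].
#' @export
#' @examples
#' score_expression(parse_step_expression("K00001 K00002"), "K00001") # 0.5
score_expression <- function(expr, present) {
  validate_expression(expr)
  score_expression_ <- function(e) {
    switch(e$kind,
      IDENT = as.numeric(e$id %in% present),
      ALL_OF = mean(vapply(e$children, score_expression_, 0)),
      ANY_OF = max(vapply(e$children, score_expression_, 0))
    )
  }
  score_expression_(expr)
}

#' Distill one genome's annotations into pathway-completeness traits
#'
#' The genome-inferred functional trait (GIFT) of a pathway is the arithmetic
#' mean of its step scores, a value in \[0, 1\] where 0 means no required
#' gene is present and 1 means the genome can complete every step. A pathway
#' consisting of a single identifier yields a binary trait.
#'
#' @param annotations character vector of identifiers carried by the genome.
#' @param db a [pathway_db()].
#' @return named numeric vector, one GIFT per pathway element.
#' @export
distill_genome <- function(annotations, db) {
  stopifnot(inherits(db, "pathway_db"))
  vapply(db$steps, function(steps) {
    mean(vapply(steps, score_expression, 0, present = annotations))
  }, 0)
}

#' Distill a genome catalogue into a genomes-by-elements GIFT matrix
#'
#' @param catalogue a [genome_catalogue()] or a named list of identifier sets
#'   (one character vector per genome).
#' @param db a [pathway_db()].
#' @return numeric matrix (genomes x elements) with a `"level"` attribute of
#'   `"element"`.
#' @export
distill_catalogue <- function(catalogue, db) {
  annotations <- if (inherits(catalogue, "genome_catalogue")) {
    catalogue$annotations
  } else {
    catalogue
  }
  if (is.null(names(annotations)) || anyDuplicated(names(annotations))) {
    stopf("catalogue must have unique genome ids")
  }
  out <- t(vapply(annotations, distill_genome, numeric(nrow(db$table)), db = db))
  dimnames(out) <- list(names(annotations), db$table$element_id)
  attr(out, "level") <- "element"
  out
}

#' Aggregate element-level GIFTs up the pathway hierarchy
#'
#' Function values are unweighted means of their member elements; domain
#' values are unweighted means of their member functions.
#'
#' @param gifts element-level matrix from [distill_catalogue()] (rows are
#'   genomes or samples).
#' @param db the [pathway_db()] defining the element-to-function-to-domain
#'   hierarchy.
#' @param level `"function"` or `"domain"`.
#' @return aggregated matrix with matching `"level"` attribute.
#' @export
aggregate_hierarchy <- function(gifts, db, level = c("function", "domain")) {
  level <- match.arg(level)
  if (!identical(attr(gifts, "level") %||% "element", "element")) {
    stopf("aggregate_hierarchy expects an element-level matrix")
  }
  map <- db$table[match(colnames(gifts), db$table$element_id), ]
  if (anyNA(map$element_id)) stopf("gift columns not found in pathway database")
  group_mean <- function(mat, groups) {
    g <- factor(groups, levels = unique(groups))
    out <- t(apply(mat, 1L, function(row) tapply(row, g, mean)))
    # apply() drops to a vector for single-row input
    if (nrow(mat) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(mat), levels(g)))
    out
  }
  fun_mat <- group_mean(gifts, map$function_id)
  if (level == "function") {
    attr(fun_mat, "level") <- "function"
    return(fun_mat)
  }
  fun_domain <- map$domain_id[match(colnames(fun_mat), map$function_id)]
  dom_mat <- group_mean(fun_mat, fun_domain)
  attr(dom_mat, "level") <- "domain"
  dom_mat
}

#' Community-weighted trait profiles
#'
#' Weights each genome's trait vector by its relative abundance in the
#' sample, over the genomes detected in that sample (weights renormalized to
#' sum to one). With `restrict`, the profile is computed over a genome subset
#' (e.g. one microbiome fraction), weights renormalized within the subset;
#' samples where no restricted genome is detected yield `NA`, not zero.
#'
#' @param gifts genomes-by-traits matrix.
#' @param abundances genomes-by-samples relative abundance matrix.
#' @param restrict optional character vector of genome ids.
#' @return samples-by-traits matrix; the `"level"` attribute of `gifts` is
#'   carried over.
#' @export
community_weighted <- function(gifts, abundances, restrict = NULL) {
  if (!all(rownames(abundances) %in% rownames(gifts))) {
    stopf("abundance table contains genomes missing from the GIFT matrix")
  }
  if (!is.null(restrict)) {
    if (length(restrict) == 0L) stopf("empty restriction set")
    restrict <- intersect(restrict, rownames(abundances))
    if (length(restrict) == 0L) stopf("restriction set shares no genomes with the abundance table")
    abundances <- abundances[restrict, , drop = FALSE]
  }
  g <- gifts[rownames(abundances), , drop = FALSE]
  out <- matrix(NA_real_, ncol(abundances), ncol(gifts),
                dimnames = list(colnames(abundances), colnames(gifts)))
  for (s in seq_len(ncol(abundances))) {
    w <- abundances[, s]
    keep <- w > 0
    if (!any(keep)) next  # no member detected: stays NA
    w <- w[keep] / sum(w[keep])
    out[s, ] <- colSums(g[keep, , drop = FALSE] * w)
  }
  attr(out, "level") <- attr(gifts, "level")
  out
}

#' Metabolic capacity index
#'
#' The mean across all traits of a profile — by convention computed on
#' function-level traits.
#'
#' @param traits numeric vector (or a matrix, averaged row-wise).
#' @return a value in \[0, 1\] (or one per row).
#' @export
metabolic_capacity_index <- function(traits) {
  if (is.matrix(traits)) {
    if (ncol(traits) == 0L) stopf("empty trait matrix")
    return(rowMeans(traits))
  }
  if (length(traits) == 0L) stopf("empty trait vector")
  mean(traits)
}

#' Per-genome metabolic capacity index from an element-level GIFT matrix
#'
#' @param gifts element-level genomes-by-elements matrix.
#' @param db the [pathway_db()].
#' @return named numeric vector of function-level MCI per genome.
#' @export
genome_mci <- function(gifts, db) {
  metabolic_capacity_index(aggregate_hierarchy(gifts, db, "function"))
}
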