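#' Hill-number diversity of order q
#'
#' The effective number of taxa: `(sum p_i^q)^(1/(1-q))` for `q != 1`, the
#' exponential of Shannon entropy at `q = 1` (continuous limit), and the
#' count of taxa with positive abundance at `q = 0`.
#'
#' @param p relative abundance vector; non-negative, summing to 1 within
#'   1e-9 (renormalized when `renormalize = TRUE`).
#' @param q diversity order, `q >= 0`.
#' @param renormalize divide by `sum(p)` instead of erroring on drift.
#' @return effective number of taxa (>= 1 for valid input).
#' @export
#' @examples
#' hill_number(rep(0.25, 4), q = 1) # 4
hill_number <- function(p, q, renormalize = FALSE) {
  p <- check_abundance_vector(p, renormalize)
  if (!is.numeric(q) || length(q) != 1L || q < 0) stopf("`q` must be a single value >= 0")
  p <- p[p > 0]
  if (q == 0) return(length(p))
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

check_abundance_vector <- function(p, renormalize = FALSE, tol = 1e-9) {
  if (!is.numeric(p) || length(p) == 0L) stopf("abundance vector must be numeric and nonempty")
  if (any(p < 0)) stopf("abundances must be non-negative")
  s <- sum(p)
  if (s == 0) stopf("all-zero abundance vector")
  if (abs(s - 1) > tol) {
    if (renormalize) p <- p / s
    else stopf("abundances must sum to 1 (got %.12f); use renormalize = TRUE", s)
  }
  p
}

# per-branch descendant abundance a_b and length L_b for a set of abundance
# vectors (tips x communities); returns list(L, A) with A branches x communities
branch_abundances <- function(tree, p) {
  if (!inherits(tree, "phylo")) stopf("`tree` must be an ape phylo object")
  p <- as.matrix(p)
  if (is.null(rownames(p))) stopf("abundance vectors must carry tip names")
  missing <- setdiff(rownames(p)[rowSums(p) > 0], tree$tip.label)
  if (length(missing)) {
    stopf("taxa with positive abundance absent from the tree: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  n_tip <- length(tree$tip.label)
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  node_ab <- matrix(0, n_tip + tree$Nnode, ncol(p))
  idx <- match(tree$tip.label, rownames(p))
  found <- !is.na(idx)
  node_ab[which(found), ] <- p[idx[found], , drop = FALSE]
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    node_ab[edges[k, 1L], ] <- node_ab[edges[k, 1L], ] + node_ab[edges[k, 2L], ]
  }
  # branch b subtends the child node of edge b
  A <- node_ab[tree$edge[, 2L], , drop = FALSE]
  list(L = tree$edge.length, A = A)
}

#' Phylogenetic Hill diversity at q = 1
#'
#' The mean-effective-diversity form: `exp(-sum_b (L_b a_b / T) log a_b)`,
#' where `a_b` is the summed relative abundance of the taxa descending from
#' branch `b`, `L_b` its length, and `T = sum_b L_b a_b` the abundance-
#' weighted mean tree depth. On a star tree with unit branches this equals
#' the neutral q = 1 Hill number.
#'
#' @param p relative abundance vector named by tree tips.
#' @param tree an `ape::phylo` with branch lengths.
#' @inheritParams hill_number
#' @return effective diversity (>= 1).
#' @export
phylo_hill_q1 <- function(p, tree, renormalize = FALSE) {
  p <- check_abundance_vector(p, renormalize)
  ba <- branch_abundances(tree, matrix(p, dimnames = list(names(p), NULL)))
  a <- ba$A[, 1L]
  keep <- a > 0
  tbar <- sum(ba$L[keep] * a[keep])
  if (tbar <= 0) stopf("zero total tree depth over the occupied tips")
  exp(-sum(ba$L[keep] * a[keep] / tbar * log(a[keep])))
}

#' Jaccard-type turnover dissimilarity at q = 1
#'
#' Decomposes the diversity of a pair of equally weighted communities into
#' gamma (the q = 1 Hill number of the half-weight pooled community) and
#' alpha (the effective within-community diversity of the pair); the beta
#' component `gamma / alpha` lies in \[1, 2\] and the turnover dissimilarity
#' is `log(beta) / log(2)`, in \[0, 1\] — 0 for identical compositions, 1
#' for fully disjoint ones. At q = 1 the Jaccard- and Sorensen-type
#' overlap-based dissimilarities coincide. With a tree, the same
#' decomposition is applied to phylogenetic Hill numbers (branch-abundance
#' form, depth normalized by the pooled community's mean depth).
#'
#' @param p1,p2 relative abundance vectors over aligned taxon ids.
#' @param tree optional `ape::phylo` for the phylogenetic version.
#' @inheritParams hill_number
#' @return dissimilarity in \[0, 1\].
#' @export
turnover_q1 <- function(p1, p2, tree = NULL, renormalize = FALSE) {
  if (length(p1) != length(p2)) stopf("abundance vectors differ in length")
  if (!is.null(names(p1)) && !is.null(names(p2)) && !identical(names(p1), names(p2))) {
    stopf("abundance vectors have mismatched taxon ids")
  }
  p1 <- check_abundance_vector(p1, renormalize)
  p2 <- check_abundance_vector(p2, renormalize)
  if (is.null(tree)) {
    pooled <- (p1 + p2) / 2
    gamma <- hill_number(pooled, 1)
    half <- c(p1, p2) / 2
    half <- half[half > 0]
    alpha <- exp(-sum(half * log(half))) / 2
  } else {
    P <- cbind(p1, p2)
    if (is.null(rownames(P))) rownames(P) <- names(p1)
    ba <- branch_abundances(tree, P)
    abar <- rowMeans(ba$A)
    keep <- abar > 0
    tbar <- sum(ba$L[keep] * abar[keep])
    if (tbar <= 0) stopf("zero total tree depth")
    gamma <- exp(-sum(ba$L[keep] * abar[keep] / tbar * log(abar[keep])))
    half <- ba$A / 2
    w <- ba$L * half / tbar        # branches x 2
    h <- -sum(w[half > 0] * log(half[half > 0]))
    alpha <- exp(h) / 2
  }
  beta <- gamma / alpha
  beta <- min(max(beta, 1), 2)  # clamp numerical drift at the boundaries
  log(beta) / log(2)
}

#' Pairwise sample dissimilarity matrix
#'
#' @param profiles for the turnover metrics, a genomes-by-samples relative
#'   abundance matrix (columns are renormalized); for `"euclidean"`, a
#'   samples-by-traits profile matrix (e.g. from [community_weighted()]).
#' @param metric one of `"turnover_q1_neutral"`, `"turnover_q1_phylo"`,
#'   `"euclidean"`.
#' @param tree required for `"turnover_q1_phylo"`.
#' @return symmetric dissimilarity matrix with sample ids.
#' @export
distance_matrix <- function(profiles,
                            metric = c("turnover_q1_neutral", "turnover_q1_phylo", "euclidean"),
                            tree = NULL) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    if (nrow(profiles) < 2L) stopf("need at least 2 samples")
    return(as.matrix(stats::dist(profiles)))
  }
  if (ncol(profiles) < 2L) stopf("need at least 2 samples")
  if (metric == "turnover_q1_phylo" && is.null(tree)) stopf("phylogenetic turnover needs a tree")
  n <- ncol(profiles)
  ids <- colnames(profiles) %||% as.character(seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  cols <- lapply(seq_len(n), function(j) {
    v <- profiles[, j]
    names(v) <- rownames(profiles)
    check_abundance_vector(v, renormalize = TRUE)
  })
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      D[i, j] <- D[j, i] <- turnover_q1(cols[[i]], cols[[j]], tree = tree)
    }
  }
  D
}

gower_center <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stopf("distance matrix must be symmetric")
  n <- nrow(D)
  A <- -0.5 * D^2
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centred matrix `-1/2 J D^2 J`.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; axes with negative eigenvalues are reported in `eigenvalues`
#' but excluded from `coordinates`.
#'
#' @param D symmetric dissimilarity matrix.
#' @return list with `coordinates` (samples x positive axes), `eigenvalues`
#'   (all, decreasing), and `trace` (sum of positive eigenvalues).
#' @export
pcoa <- function(D) {
  G <- gower_center(D)
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values), 0) * 1e-9
  pos <- eig$values > tol
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]), sum(pos))
  rownames(coords) <- rownames(as.matrix(D))
  colnames(coords) <- if (ncol(coords)) paste0("PCo", seq_len(ncol(coords))) else character(0)
  list(coordinates = coords, eigenvalues = eig$values, trace = sum(eig$values[pos]))
}

#' Domain-adjusted mapping rate
#'
#' The fraction of reads mapping to the genome catalogue divided by the
#' fraction of the community estimated to be prokaryotic; a value near 1
#' indicates near-complete recovery of the prokaryotic community by the
#' catalogue. Values above 1 (estimation noise) are kept but flagged;
#' a zero prokaryotic fraction yields a missing value.
#'
#' @param mapped_fraction fraction of sequenced bases mapped, in \[0, 1\].
#' @param prokaryotic_fraction estimated prokaryotic fraction, in \[0, 1\].
#' @return data.frame with columns `damr` and `flag`
#'   (`"ok"`, `"gt1"`, `"undefined"`).
#' @export
damr <- function(mapped_fraction, prokaryotic_fraction) {
  if (any(mapped_fraction < 0 | mapped_fraction > 1, na.rm = TRUE) ||
      any(prokaryotic_fraction < 0 | prokaryotic_fraction > 1, na.rm = TRUE)) {
    stopf("fractions must lie in [0, 1]")
  }
  value <- ifelse(prokaryotic_fraction > 0, mapped_fraction / prokaryotic_fraction, NA_real_)
  flag <- ifelse(prokaryotic_fraction == 0, "undefined",
                 ifelse(value > 1, "gt1", "ok"))
  data.frame(damr = value, flag = flag, stringsAsFactors = FALSE)
}
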