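#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based partitioning of the total sum of squares
#' `SS_total = (1/n) sum_{i<j} d_ij^2` among an ordered list of factors,
#' using the Gower-centred inner-product matrix and sequential (Type I)
#' projections, so each term's SS is the reduction achieved after the terms
#' before it. Pseudo-F per term is `(SS_term/df_term)/(SS_res/df_res)` and
#' the permutation p-value uses the `(1 + b)/(1 + B)` estimator (never
#' exactly zero). With `exhaustive = TRUE` all `n!` sample-label permutations
#' are enumerated and p is the proportion of permutations (identity
#' included) whose pseudo-F is at least the observed one.
#'
#' @param D symmetric dissimilarity matrix with sample ids.
#' @param metadata data.frame of sample covariates, rows aligned to `D`
#'   (matched by rownames when present).
#' @param terms character vector of metadata column names, in model order.
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all permutations (requires `n <= 8`).
#' @param strata optional metadata column name; random permutations are then
#'   restricted to shuffling within each stratum.
#' @return data.frame of class `"permanova"`: one row per term plus
#'   `Residual` and `Total`, with columns `df`, `SS`, `R2`, `F`, `p`.
#' @export
permanova <- function(D, metadata, terms, n_perm = 999, seed = NULL,
                      exhaustive = FALSE, strata = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stopf("PERMANOVA needs at least 3 samples")
  metadata <- align_metadata(D, metadata)
  if (!all(terms %in% names(metadata))) {
    stopf("terms not found in metadata: %s",
          paste(setdiff(terms, names(metadata)), collapse = ", "))
  }
  for (tm in terms) {
    v <- metadata[[tm]]
    if (is.character(v) || is.logical(v)) metadata[[tm]] <- factor(v)
    if (is.factor(metadata[[tm]]) && nlevels(droplevels(metadata[[tm]])) < 2L) {
      stopf("factor '%s' has fewer than 2 levels among these samples", tm)
    }
  }
  G <- gower_center(D)
  hats <- cumulative_hats(metadata, terms, n)
  obs <- partition_ss(G, hats)
  if (any(obs$df == 0)) stopf("aliased term (zero df) in the model")

  if (exhaustive) {
    if (n > 8L) stopf("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    Fs <- vapply(seq_len(nrow(perms)), function(k) {
      partition_ss(G[perms[k, ], perms[k, ]], hats)$F
    }, numeric(length(terms)))
    Fs <- matrix(Fs, nrow = length(terms))
    p <- rowMeans(Fs >= obs$F - 1e-12)
  } else {
    if (n_perm < 1L) stopf("n_perm must be >= 1")
    strat <- if (is.null(strata)) NULL else as.factor(metadata[[strata]])
    p <- with_seed(seed, {
      hits <- numeric(length(terms))
      for (b in seq_len(n_perm)) {
        perm <- permute_indices(n, strat)
        fb <- partition_ss(G[perm, perm], hats)$F
        hits <- hits + (fb >= obs$F - 1e-12)
      }
      (1 + hits) / (1 + n_perm)
    })
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(obs$df, obs$df_res, n - 1L),
    SS = c(obs$SS, obs$SS_res, obs$SS_total),
    R2 = c(obs$SS, obs$SS_res, obs$SS_total) / obs$SS_total,
    F = c(obs$F, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE
  )
  class(out) <- c("permanova", "data.frame")
  out
}

align_metadata <- function(D, metadata) {
  metadata <- as.data.frame(metadata)
  ids <- rownames(as.matrix(D))
  if (!is.null(ids) && !is.null(metadata$sample_id) &&
      all(ids %in% metadata$sample_id)) {
    metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  } else if (nrow(metadata) != nrow(as.matrix(D))) {
    stopf("metadata rows do not match the distance matrix samples")
  }
  metadata
}

# hat matrices of the cumulative models intercept, +t1, +t1+t2, ...
cumulative_hats <- function(metadata, terms, n) {
  hats <- vector("list", length(terms) + 1L)
  hats[[1L]] <- matrix(1 / n, n, n)
  ranks <- integer(length(terms) + 1L)
  ranks[1L] <- 1L
  for (k in seq_along(terms)) {
    fm <- stats::as.formula(paste("~", paste(terms[seq_len(k)], collapse = " + ")))
    X <- stats::model.matrix(fm, metadata)
    qx <- qr(X)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    hats[[k + 1L]] <- tcrossprod(Q)
    ranks[k + 1L] <- qx$rank
  }
  list(H = hats, rank = ranks)
}

# sequential SS partition given precomputed hats; G may be permuted
partition_ss <- function(G, hats) {
  m <- length(hats$H) - 1L
  tr <- vapply(hats$H, function(H) sum(H * G), 0)
  SS_total <- sum(diag(G))
  SS <- diff(tr)
  df <- diff(hats$rank)
  df_res <- nrow(G) - hats$rank[m + 1L]
  SS_res <- SS_total - tr[m + 1L]  # tr(H0 G) = 0 for doubly-centred G
  ms_res <- SS_res / df_res
  Fv <- if (ms_res > 1e-12) (SS / df) / ms_res else ifelse(SS / df > 1e-12, Inf, 0)
  list(SS = SS, df = df, F = Fv, SS_res = SS_res, df_res = df_res, SS_total = SS_total)
}

permute_indices <- function(n, strat = NULL) {
  if (is.null(strat)) return(sample.int(n))
  idx <- seq_len(n)
  for (lev in levels(strat)) {
    w <- which(strat == lev)
    idx[w] <- w[sample.int(length(w))]
  }
  idx
}

# all n! permutations of 1..n, built by inserting n into each position of
# every (n-1)-permutation
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pairwise PERMANOVA between factor levels
#'
#' Runs [permanova()] on every pair of levels of `factor_name` (sub-setting
#' the distance matrix) and Holm-adjusts the p-values.
#'
#' @inheritParams permanova
#' @param factor_name metadata column whose levels are compared.
#' @return data.frame with one row per level pair: `R2`, `F`, `p`, `p_adj`.
#' @export
pairwise_permanova <- function(D, metadata, factor_name, n_perm = 999, seed = NULL) {
  D <- as.matrix(D)
  metadata <- align_metadata(D, metadata)
  f <- factor(metadata[[factor_name]])
  levs <- levels(droplevels(f))
  if (length(levs) < 2L) stopf("factor '%s' has fewer than 2 levels", factor_name)
  pairs <- utils::combn(levs, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    keep <- f %in% pairs[, k]
    fit <- permanova(D[keep, keep, drop = FALSE], metadata[keep, , drop = FALSE],
                     terms = factor_name, n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, k))
    data.frame(level_1 = pairs[1L, k], level_2 = pairs[2L, k],
               df = fit$df[1L], R2 = fit$R2[1L], F = fit$F[1L], p = fit$p[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- holm_adjust(out$p)
  out
}

#' Homogeneity of multivariate dispersions
#'
#' Embeds the samples by principal coordinates keeping both the real
#' (positive-eigenvalue) and imaginary (negative-eigenvalue) axes, computes
#' each sample's distance to its group centroid with the negative-eigenvalue
#' correction `sqrt(d_real^2 - d_imag^2)` (clamped at zero), and tests the
#' group effect on those distances with a one-way F statistic whose p-value
#' is obtained by permuting group labels.
#'
#' @inheritParams permanova
#' @param groups grouping vector or metadata column values, one per sample.
#' @return list with `distances` (per sample), `group_means`, `F`, `p`.
#' @export
beta_dispersion <- function(D, groups, n_perm = 999, seed = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- factor(groups)
  if (length(groups) != n) stopf("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2L) stopf("need at least 2 groups")
  if (any(table(groups) < 2L)) stopf("every group needs at least 2 samples")
  G <- gower_center(D)
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- eig$values > tol
  neg <- eig$values < -tol
  Xr <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]), sum(pos))
  Xi <- eig$vectors[, neg, drop = FALSE] %*% diag(sqrt(-eig$values[neg]), sum(neg))
  dists <- numeric(n)
  for (lev in levels(groups)) {
    w <- which(groups == lev)
    cr <- colMeans(Xr[w, , drop = FALSE])
    ci <- colMeans(Xi[w, , drop = FALSE])
    d2 <- rowSums((Xr[w, , drop = FALSE] - rep(cr, each = length(w)))^2) -
          rowSums((Xi[w, , drop = FALSE] - rep(ci, each = length(w)))^2)
    dists[w] <- sqrt(pmax(d2, 0))
  }
  f_stat <- function(d, g) {
    gm <- tapply(d, g, mean)
    nb <- tabulate(g)
    ssb <- sum(nb * (gm - mean(d))^2)
    ssw <- sum((d - gm[as.integer(g)])^2)
    dfb <- nlevels(g) - 1L
    dfw <- length(d) - nlevels(g)
    if (ssw < 1e-14) return(if (ssb > 1e-14) Inf else 0)
    (ssb / dfb) / (ssw / dfw)
  }
  f_obs <- f_stat(dists, groups)
  p <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (f_stat(dists[sample.int(n)], groups) >= f_obs - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
  list(distances = stats::setNames(dists, rownames(D)),
       group_means = tapply(dists, groups, mean),
       F = f_obs, p = p)
}

#' Two-group comparison with assumption-based test selection
#'
#' Chooses a parametric two-sample t-test (pooled variance) when both groups
#' pass a Shapiro-Wilk normality check and an F-test of equal variances at
#' `alpha`; otherwise falls back to the Wilcoxon rank-sum test (mid-rank tie
#' handling, normal approximation for larger samples). The result records
#' which test fired and why.
#'
#' @param values_by_group list of two numeric vectors (named by group), each
#'   with at least 3 observations.
#' @param alpha significance level for the assumption checks (default 0.05).
#' @return list: `test` ("t" or "wilcoxon"), `statistic`, `p`,
#'   `assumptions` (the check p-values), `reason`.
#' @export
compare_alpha <- function(values_by_group, alpha = 0.05) {
  if (!is.list(values_by_group) || length(values_by_group) != 2L) {
    stopf("compare_alpha expects a list of exactly two groups")
  }
  x <- values_by_group[[1L]]; y <- values_by_group[[2L]]
  if (length(x) < 3L || length(y) < 3L) stopf("each group needs at least 3 observations")
  sw <- function(v) {
    if (length(unique(v)) < 3L) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(v)$p.value
  }
  swx <- sw(x); swy <- sw(y)
  vp <- if (stats::var(x) > 0 && stats::var(y) > 0) stats::var.test(x, y)$p.value else 0
  normal_ok <- swx > alpha && swy > alpha
  var_ok <- vp > alpha
  if (normal_ok && var_ok) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    test <- "t"
    reason <- "both groups normal and variances homogeneous"
  } else {
    if (stats::var(c(x, y)) == 0) {
      return(list(test = "wilcoxon", statistic = length(x) * length(y) / 2, p = 1,
                  assumptions = c(shapiro_1 = swx, shapiro_2 = swy, var_F = vp),
                  reason = "all values identical"))
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    test <- "wilcoxon"
    reason <- if (!normal_ok) "non-normal distribution in at least one group"
              else "heterogeneous variances"
  }
  list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
       assumptions = c(shapiro_1 = swx, shapiro_2 = swy, var_F = vp),
       reason = reason)
}

#' Holm (step-down Bonferroni) p-value adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}
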