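# independent brute-force oracles and small fixtures used across tests

# all permutations of 1..n (plain recursion, independent of the package)
oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in oracle_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# single-factor PERMANOVA statistics from the group-sum formulas:
# SS_total = (1/n) sum_{i<j} d_ij^2, SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2
oracle_permanova_stat <- function(D, groups) {
  n <- nrow(D)
  ss_tot <- sum(D[upper.tri(D)]^2) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- D[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ss_a <- ss_tot - ss_w
  df_a <- length(unique(groups)) - 1L
  df_w <- n - length(unique(groups))
  f <- if (ss_w < 1e-14) {
    if (ss_a > 1e-14) Inf else 0
  } else (ss_a / df_a) / (ss_w / df_w)
  list(F = f, R2 = ss_a / ss_tot, SS_total = ss_tot)
}

# exhaustive-permutation p: proportion of all label permutations (identity
# included) whose pseudo-F reaches the observed one
oracle_permanova_p <- function(D, groups) {
  obs <- oracle_permanova_stat(D, groups)$F
  fs <- vapply(oracle_perms(nrow(D)), function(p) {
    oracle_permanova_stat(D[p, p, drop = FALSE], groups)$F
  }, 0)
  mean(fs >= obs - 1e-12)
}

# small two-environment, four-stream metadata
toy_metadata <- function(samples_per_stream = c(2, 2, 2, 2)) {
  envs <- rep(c("envA", "envB"), each = 2)
  streams <- paste0(envs, "_s", rep(1:2, 2))
  n <- sum(samples_per_stream)
  data.frame(
    sample_id = sprintf("t%02d", seq_len(n)),
    stream = rep(streams, times = samples_per_stream),
    environment = rep(envs, times = samples_per_stream),
    stringsAsFactors = FALSE
  )
}

# detection matrix builder: rows named, samples from metadata
toy_detection <- function(metadata, rows) {
  m <- matrix(FALSE, length(rows), nrow(metadata),
              dimnames = list(names(rows), metadata$sample_id))
  for (g in names(rows)) m[g, rows[[g]]] <- TRUE
  m
}

# small fast simulation config for structural tests
small_config <- function(...) {
  sim_config(samples_per_stream = c(3, 3, 3, 3), n_core = 12,
             n_endemic_per_environment = 4, n_marginal = 3,
             pathway_count = 12, steps_per_pathway = 3,
             allele_positions = 200, ...)
}
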