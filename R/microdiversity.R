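#' Population-ANI between two samples of one genome
#'
#' Consensus-allele population ANI: over the sites covered in both samples,
#' the fraction of sites with matching consensus alleles. Microdiversity is
#' `1 - ANI`. When the number of shared covered sites falls below
#' `min_shared` the pair is reported missing rather than zero.
#'
#' @param alleles_i,alleles_j character vectors of consensus alleles at
#'   aligned positions; `NA` marks an uncovered site.
#' @param min_shared minimum shared covered sites (default 50).
#' @return list with `ani`, `microdiversity` and `shared` (site count);
#'   `ani` is `NA` below the threshold.
#' @export
pop_ani_pair <- function(alleles_i, alleles_j, min_shared = 50) {
  if (length(alleles_i) != length(alleles_j)) {
    stopf("allele vectors must be aligned on the same positions")
  }
  both <- !is.na(alleles_i) & !is.na(alleles_j)
  shared <- sum(both)
  if (shared == 0L || shared < min_shared) {
    return(list(ani = NA_real_, microdiversity = NA_real_, shared = shared))
  }
  ani <- mean(alleles_i[both] == alleles_j[both])
  list(ani = ani, microdiversity = 1 - ani, shared = shared)
}

#' Sample-by-sample microdiversity matrix for one genome
#'
#' @param alleles positions-by-samples character matrix of consensus alleles
#'   (`NA` = uncovered), as stored in an allele-table collection.
#' @param min_shared minimum shared covered sites per pair.
#' @return list with `microdiversity` (symmetric samples x samples matrix,
#'   `NA` where too few shared sites), `shared` (site-count matrix) and
#'   `mean` (unweighted mean over defined off-diagonal pairs).
#' @export
microdiversity_matrix <- function(alleles, min_shared = 50) {
  if (!is.matrix(alleles) || ncol(alleles) < 2L) {
    stopf("need an alleles matrix with at least 2 samples")
  }
  n <- ncol(alleles)
  ids <- colnames(alleles) %||% as.character(seq_len(n))
  # vectorized pairwise counts: shared covered sites via crossprod of the
  # coverage indicator, matches via crossprods of per-base indicators
  cov <- !is.na(alleles)
  storage.mode(cov) <- "numeric"
  sh <- crossprod(cov)
  matches <- matrix(0, n, n)
  for (b in unique(alleles[!is.na(alleles)])) {
    ind <- (alleles == b) & !is.na(alleles)
    ind[is.na(ind)] <- FALSE
    storage.mode(ind) <- "numeric"
    matches <- matches + crossprod(ind)
  }
  md <- 1 - matches / sh
  md[sh < max(min_shared, 1)] <- NA_real_
  diag(md) <- 0
  sh <- matrix(as.integer(sh), n, n, dimnames = list(ids, ids))
  dimnames(md) <- list(ids, ids)
  vals <- md[upper.tri(md)]
  list(microdiversity = md, shared = sh,
       mean = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE))
}

# mean of the microdiversity submatrix over a sample-pair class
pair_class_mean <- function(md, samples_a, samples_b) {
  a <- intersect(samples_a, colnames(md))
  b <- intersect(samples_b, colnames(md))
  if (identical(sort(a), sort(b))) {
    sub <- md[a, a, drop = FALSE]
    vals <- sub[upper.tri(sub)]
  } else {
    vals <- as.vector(md[a, b, drop = FALSE])
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) NA_real_ else mean(vals)
}

#' Environment and fraction contrasts of strain microdiversity
#'
#' For every genome with a microdiversity matrix, computes the mean
#' microdiversity over within-environment pairs (one value per environment)
#' and over between-environment pairs, then contrasts environments with
#' Wilcoxon rank-sum tests: within-environment means of core genomes, and
#' genome means of the endemics of each environment. Both the genome-mean
#' version (one value per genome, the primary result) and a pooled-pair
#' version (all sample-pair values pooled across genomes) are reported.
#'
#' @param matrices named list (by genome) of results from
#'   [microdiversity_matrix()] (or bare microdiversity matrices).
#' @param labels data.frame from [classify_fractions()].
#' @param metadata data.frame with `sample_id`, `environment`.
#' @return list: `per_genome` (data.frame of within/between means),
#'   `contrasts` (data.frame of Wilcoxon results, genome-mean and pooled
#'   variants), `environments`.
#' @export
group_microdiversity_compare <- function(matrices, labels, metadata) {
  metadata <- as.data.frame(metadata)
  envs <- sort(unique(metadata$environment))
  if (length(envs) != 2L) stopf("exactly two environments expected")
  samples_env <- lapply(envs, function(e) metadata$sample_id[metadata$environment == e])
  names(samples_env) <- envs

  get_md <- function(x) if (is.list(x) && !is.null(x$microdiversity)) x$microdiversity else x
  per_genome <- do.call(rbind, lapply(names(matrices), function(g) {
    md <- get_md(matrices[[g]])
    lab <- labels[labels$genome_id == g, , drop = FALSE]
    data.frame(
      genome_id = g,
      fraction = if (nrow(lab)) lab$fraction else NA_character_,
      endemic_environment = if (nrow(lab)) lab$environment else NA_character_,
      within_1 = pair_class_mean(md, samples_env[[1L]], samples_env[[1L]]),
      within_2 = pair_class_mean(md, samples_env[[2L]], samples_env[[2L]]),
      between = pair_class_mean(md, samples_env[[1L]], samples_env[[2L]]),
      stringsAsFactors = FALSE
    )
  }))
  names(per_genome)[names(per_genome) == "within_1"] <- paste0("within_", envs[1L])
  names(per_genome)[names(per_genome) == "within_2"] <- paste0("within_", envs[2L])

  pooled_within <- function(genomes, env) {
    unlist(lapply(genomes, function(g) {
      md <- get_md(matrices[[g]])
      a <- intersect(samples_env[[env]], colnames(md))
      sub <- md[a, a, drop = FALSE]
      v <- sub[upper.tri(sub)]
      v[!is.na(v)]
    }), use.names = FALSE)
  }

  wtest <- function(x, y, contrast, unit) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      return(data.frame(contrast = contrast, unit = unit, n_1 = length(x),
                        n_2 = length(y), mean_1 = mean(x), mean_2 = mean(y),
                        W = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    data.frame(contrast = contrast, unit = unit, n_1 = length(x), n_2 = length(y),
               mean_1 = mean(x), mean_2 = mean(y),
               W = unname(ht$statistic), p = ht$p.value, stringsAsFactors = FALSE)
  }

  core <- per_genome[per_genome$fraction %in% "core", , drop = FALSE]
  end1 <- per_genome[per_genome$fraction %in% "endemic" &
                       per_genome$endemic_environment %in% envs[1L], , drop = FALSE]
  end2 <- per_genome[per_genome$fraction %in% "endemic" &
                       per_genome$endemic_environment %in% envs[2L], , drop = FALSE]
  contrasts <- rbind(
    wtest(core[[paste0("within_", envs[1L])]], core[[paste0("within_", envs[2L])]],
          sprintf("core within-%s vs within-%s", envs[1L], envs[2L]), "genome_mean"),
    wtest(end1[[paste0("within_", envs[1L])]], end2[[paste0("within_", envs[2L])]],
          sprintf("endemic %s vs endemic %s", envs[1L], envs[2L]), "genome_mean"),
    wtest(pooled_within(core$genome_id, envs[1L]), pooled_within(core$genome_id, envs[2L]),
          sprintf("core within-%s vs within-%s", envs[1L], envs[2L]), "pooled_pairs"),
    wtest(pooled_within(end1$genome_id, envs[1L]), pooled_within(end2$genome_id, envs[2L]),
          sprintf("endemic %s vs endemic %s", envs[1L], envs[2L]), "pooled_pairs")
  )
  list(per_genome = per_genome, contrasts = contrasts, environments = envs)
}
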