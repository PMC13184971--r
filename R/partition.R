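#' Detection table from a relative abundance table
#'
#' A genome is detected in a sample when its relative abundance exceeds
#' `min_abundance` (default 0, i.e. any positive abundance counts).
#'
#' @param abundances genomes-by-samples relative abundance matrix.
#' @param min_abundance detection threshold (>= 0).
#' @return logical genomes-by-samples matrix.
#' @export
detect_presence <- function(abundances, min_abundance = 0) {
  if (min_abundance < 0) stopf("detection threshold must be non-negative")
  abundances > min_abundance
}

#' Per-environment prevalence of each genome
#'
#' @param detection logical genomes-by-samples matrix.
#' @param metadata data.frame with `sample_id`, `stream`, `environment`.
#' @return genomes-by-environments matrix of detection prevalences (the
#'   fraction of that environment's samples in which the genome is detected).
#' @export
prevalence_by_environment <- function(detection, metadata) {
  metadata <- match_samples(detection, metadata)
  envs <- unique(metadata$environment)
  out <- sapply(envs, function(e) {
    cols <- metadata$environment == e
    rowMeans(detection[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(detection), dimnames = list(rownames(detection), envs))
  out
}

match_samples <- function(detection, metadata) {
  metadata <- as.data.frame(metadata)
  need <- c("sample_id", "stream", "environment")
  if (!all(need %in% names(metadata))) {
    stopf("metadata needs columns %s", paste(need, collapse = ", "))
  }
  ids <- colnames(detection)
  if (is.null(ids) || !all(ids %in% metadata$sample_id)) {
    stopf("detection table samples missing from metadata")
  }
  metadata[match(ids, metadata$sample_id), , drop = FALSE]
}

#' Classify genomes into core, endemic and marginal fractions
#'
#' Prevalence-based partitioning of a genome catalogue, applied in rule
#' order:
#' \enumerate{
#'   \item genomes detected in \emph{all} streams of the study are core;
#'   \item genomes detected in only one environment, in every stream of that
#'     environment, with within-environment prevalence at or above
#'     `prevalence_threshold` (default 20\%) are endemic to that environment;
#'   \item everything else is marginal — the patternless remainder — with
#'     `rule_fired` recording which sub-case applied (single environment at
#'     low prevalence, a single stream, cross-environment but not all
#'     streams, or undetected).
#' }
#'
#' The three published rules are not exhaustive; genomes spanning both
#' environments without reaching all streams default to marginal, or to core
#' under `cross_env_policy = "core"`.
#'
#' @param detection logical genomes-by-samples matrix ([detect_presence()]).
#' @param metadata data.frame with `sample_id`, `stream`, `environment`.
#' @param prevalence_threshold minimum within-environment prevalence for the
#'   endemic rule, in \[0, 1\].
#' @param cross_env_policy label for cross-environment, not-all-streams
#'   genomes: `"marginal"` (default) or `"core"`.
#' @return data.frame with `genome_id`, `fraction`, `environment` (the
#'   endemic environment, NA otherwise), `prevalence` (within the detected
#'   environment(s), max over environments), `rule_fired`.
#' @export
classify_fractions <- function(detection, metadata, prevalence_threshold = 0.20,
                               cross_env_policy = c("marginal", "core")) {
  cross_env_policy <- match.arg(cross_env_policy)
  if (nrow(detection) == 0L) stopf("empty detection table")
  if (prevalence_threshold < 0 || prevalence_threshold > 1) {
    stopf("prevalence threshold must lie in [0, 1]")
  }
  metadata <- match_samples(detection, metadata)
  streams <- unique(metadata$stream)
  env_of_stream <- metadata$environment[match(streams, metadata$stream)]
  prev <- prevalence_by_environment(detection, metadata)

  n <- nrow(detection)
  fraction <- character(n)
  environment <- rep(NA_character_, n)
  rule <- character(n)
  prev_out <- numeric(n)

  for (i in seq_len(n)) {
    det <- detection[i, ]
    streams_det <- unique(metadata$stream[det])
    envs_det <- unique(metadata$environment[det])
    prev_out[i] <- if (length(envs_det)) max(prev[i, envs_det]) else 0
    if (length(streams_det) == 0L) {
      fraction[i] <- "marginal"; rule[i] <- "undetected"
    } else if (setequal(streams_det, streams)) {
      fraction[i] <- "core"; rule[i] <- "all_streams"
    } else if (length(envs_det) == 1L) {
      env_streams <- streams[env_of_stream == envs_det]
      if (setequal(streams_det, env_streams) && prev[i, envs_det] >= prevalence_threshold) {
        fraction[i] <- "endemic"; environment[i] <- envs_det
        rule[i] <- "single_env_all_streams_prevalent"
      } else if (length(streams_det) == 1L) {
        fraction[i] <- "marginal"; rule[i] <- "single_stream"
      } else if (!setequal(streams_det, env_streams)) {
        fraction[i] <- "marginal"; rule[i] <- "single_env_partial_streams"
      } else {
        fraction[i] <- "marginal"; rule[i] <- "single_env_low_prevalence"
      }
    } else {
      fraction[i] <- if (cross_env_policy == "core") "core" else "marginal"
      rule[i] <- "cross_env_partial_streams"
    }
  }
  data.frame(genome_id = rownames(detection) %||% as.character(seq_len(n)),
             fraction = fraction, environment = environment,
             prevalence = prev_out, rule_fired = rule,
             stringsAsFactors = FALSE)
}

#' Summarize the core / endemic / marginal fractions
#'
#' Per fraction: number of genomes, percent of the catalogue (rounded to
#' `digits`), mean cumulative relative abundance across samples, and (when a
#' catalogue / GIFT matrix are supplied) mean genome size and mean metabolic
#' capacity index.
#'
#' @param labels data.frame from [classify_fractions()].
#' @param abundances optional genomes-by-samples relative abundance matrix.
#' @param catalogue optional [genome_catalogue()] (for genome sizes).
#' @param gifts optional element-level GIFT matrix (for MCI).
#' @param db [pathway_db()], required with `gifts`.
#' @param digits rounding of the percent column (default 1).
#' @return data.frame, one row per fraction present.
#' @export
fraction_summary <- function(labels, abundances = NULL, catalogue = NULL,
                             gifts = NULL, db = NULL, digits = 1) {
  fr_levels <- c("core", "endemic", "marginal")
  present <- fr_levels[fr_levels %in% labels$fraction]
  total <- nrow(labels)
  mci <- if (!is.null(gifts)) {
    if (is.null(db)) stopf("`db` is required to compute MCI from gifts")
    genome_mci(gifts, db)
  }
  rows <- lapply(present, function(fr) {
    g <- labels$genome_id[labels$fraction == fr]
    cum_ab <- if (!is.null(abundances)) {
      miss <- setdiff(g, rownames(abundances))
      if (length(miss)) stopf("labelled genomes missing from abundance table: %s",
                              paste(utils::head(miss, 5L), collapse = ", "))
      mean(colSums(abundances[g, , drop = FALSE]))
    } else NA_real_
    size <- if (!is.null(catalogue)) {
      gi <- catalogue$genomes
      mean(gi$size[match(g, gi$genome_id)])
    } else NA_real_
    data.frame(fraction = fr, n_genomes = length(g),
               percent = round(100 * length(g) / total, digits),
               mean_cumulative_abundance = cum_ab,
               mean_genome_size = size,
               mean_mci = if (!is.null(mci)) mean(mci[g]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genome-level contrasts of size and metabolic capacity between fractions
#'
#' Wilcoxon rank-sum tests of genome size and function-level MCI for the
#' fraction contrasts core vs endemic, core vs marginal, and (when both
#' environments host endemics) endemic vs endemic by environment;
#' Holm-adjusted within each metric.
#'
#' @param labels data.frame from [classify_fractions()].
#' @param catalogue [genome_catalogue()] providing genome sizes.
#' @param gifts element-level GIFT matrix.
#' @param db [pathway_db()].
#' @return data.frame: `metric`, `contrast`, `n_1`, `n_2`, `W`, `p`, `p_adj`;
#'   zero rows when fewer than two fractions have >= 2 members.
#' @export
genome_level_comparison <- function(labels, catalogue, gifts, db) {
  sizes <- stats::setNames(catalogue$genomes$size, catalogue$genomes$genome_id)
  mci <- genome_mci(gifts, db)
  groups <- list(
    core = labels$genome_id[labels$fraction == "core"],
    endemic = labels$genome_id[labels$fraction == "endemic"],
    marginal = labels$genome_id[labels$fraction == "marginal"]
  )
  envs <- sort(unique(stats::na.omit(labels$environment)))
  contrasts <- list(c("core", "endemic"), c("core", "marginal"))
  if (length(envs) == 2L) {
    groups[[paste0("endemic_", envs[1L])]] <-
      labels$genome_id[labels$fraction == "endemic" & labels$environment == envs[1L]]
    groups[[paste0("endemic_", envs[2L])]] <-
      labels$genome_id[labels$fraction == "endemic" & labels$environment == envs[2L]]
    contrasts <- c(contrasts, list(paste0("endemic_", envs)))
  }
  run_metric <- function(values, metric) {
    rows <- lapply(contrasts, function(ct) {
      g1 <- groups[[ct[1L]]]; g2 <- groups[[ct[2L]]]
      if (length(g1) < 2L || length(g2) < 2L) return(NULL)
      ht <- suppressWarnings(stats::wilcox.test(values[g1], values[g2], exact = FALSE))
      data.frame(metric = metric, contrast = paste(ct, collapse = " vs "),
                 n_1 = length(g1), n_2 = length(g2),
                 W = unname(ht$statistic), p = ht$p.value,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows)) rows$p_adj <- holm_adjust(rows$p)
    rows
  }
  out <- rbind(run_metric(sizes, "genome_size"), run_metric(mci, "mci"))
  if (is.null(out)) {
    out <- data.frame(metric = character(), contrast = character(),
                      n_1 = integer(), n_2 = integer(), W = numeric(),
                      p = numeric(), p_adj = numeric())
  }
  out
}

#' Fraction-wise functional comparison between environments
#'
#' For each microbiome fraction: builds the community-weighted function-level
#' trait profile restricted to that fraction (weights renormalized within
#' the fraction), tests every trait between environments with Kruskal-Wallis
#' plus Holm adjustment, counts significant traits, and quantifies the
#' overall environmental effect with a PERMANOVA on Euclidean trait
#' distances (`R2` and permutation p). Samples where the fraction is
#' undetected are dropped from that fraction's tests; a fraction entirely
#' absent from one environment is reported as not comparable.
#'
#' @param labels data.frame from [classify_fractions()].
#' @param gifts element-level genomes-by-elements GIFT matrix.
#' @param abundances genomes-by-samples relative abundance matrix.
#' @param metadata data.frame with `sample_id`, `environment`.
#' @param db [pathway_db()].
#' @param n_perm PERMANOVA permutations (default 999).
#' @param seed integer seed.
#' @param sig_level adjusted-p cutoff for counting significant traits.
#' @return list, one entry per fraction: `comparable`, `n_samples`,
#'   `profile` (samples x functions), `trait_tests` (per-trait H, p, p_adj),
#'   `n_significant`, `permanova` (the fitted table), `R2`, `p`.
#' @export
fraction_functional_comparison <- function(labels, gifts, abundances, metadata,
                                           db, n_perm = 999, seed = NULL,
                                           sig_level = 0.05) {
  metadata <- as.data.frame(metadata)
  fun_gifts <- aggregate_hierarchy(gifts, db, "function")
  out <- list()
  for (fr in intersect(c("core", "endemic", "marginal"), unique(labels$fraction))) {
    members <- labels$genome_id[labels$fraction == fr]
    prof <- community_weighted(fun_gifts, abundances, restrict = members)
    ok <- stats::complete.cases(prof)
    env <- metadata$environment[match(rownames(prof), metadata$sample_id)]
    envs_present <- unique(env[ok])
    if (length(envs_present) < 2L || min(table(env[ok])) < 2L) {
      out[[fr]] <- list(comparable = FALSE, n_samples = sum(ok), profile = prof,
                        reason = "fraction not detected in >=2 samples of each environment")
      next
    }
    sub <- prof[ok, , drop = FALSE]
    env_ok <- factor(env[ok])
    tests <- data.frame(
      trait = colnames(sub),
      H = NA_real_, p = NA_real_,
      stringsAsFactors = FALSE
    )
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      if (stats::var(v) < 1e-14) { tests$H[j] <- 0; tests$p[j] <- 1; next }
      kt <- stats::kruskal.test(v, env_ok)
      tests$H[j] <- unname(kt$statistic); tests$p[j] <- kt$p.value
    }
    tests$p_adj <- holm_adjust(tests$p)
    if (max(stats::dist(sub)) < 1e-12) {
      out[[fr]] <- list(comparable = TRUE, n_samples = nrow(sub), profile = prof,
                        trait_tests = tests, n_significant = 0L,
                        permanova = NULL, R2 = NA_real_, p = NA_real_,
                        degenerate = TRUE)
      next
    }
    D <- distance_matrix(sub, "euclidean")
    fit <- permanova(D, data.frame(sample_id = rownames(sub), environment = env_ok),
                     terms = "environment", n_perm = n_perm, seed = seed)
    out[[fr]] <- list(comparable = TRUE, n_samples = nrow(sub), profile = prof,
                      trait_tests = tests,
                      n_significant = sum(tests$p_adj < sig_level),
                      permanova = fit, R2 = fit$R2[1L], p = fit$p[1L])
  }
  out
}
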