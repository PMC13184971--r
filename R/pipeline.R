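#' Run the full analysis pipeline on a dataset directory or bundle
#'
#' Executes the study's analysis flow end to end: trait distillation and
#' community weighting; alpha diversity (richness, neutral q = 1,
#' phylogenetic q = 1) with assumption-based environment tests; beta
#' diversity (neutral and phylogenetic q = 1 turnover) with PERMANOVA and
#' dispersion tests; prevalence partitioning into core / endemic / marginal
#' with fraction summaries, genome-level and fraction-wise functional
#' comparisons; strain microdiversity contrasts; and the per-sample
#' domain-adjusted mapping rate. Results are written as TSV files plus a
#' run manifest and a plain-text summary. A missing alleles component skips
#' the microdiversity stage with a warning; other stages still run.
#'
#' @param input a `dataset_bundle` from [generate_dataset()] or a directory
#'   written by [write_dataset()].
#' @param out_dir output directory for result files (created; NULL skips
#'   writing).
#' @param prevalence_threshold endemic rule threshold (default 0.20).
#' @param min_abundance detection threshold (default 0).
#' @param n_perm permutations for PERMANOVA / dispersion tests.
#' @param min_shared minimum shared covered sites per microdiversity pair.
#' @param seed integer seed for all permutation streams.
#' @return list with `alpha`, `alpha_tests`, `beta` (distance matrices,
#'   PERMANOVA and dispersion fits), `gifts`, `community`, `mci_tests`,
#'   `labels`, `summary`, `genome_tests`, `fraction_functional`,
#'   `microdiversity`, `damr`, invisibly also written under `out_dir`.
#' @export
run_pipeline <- function(input, out_dir = NULL, prevalence_threshold = 0.20,
                         min_abundance = 0, n_perm = 999, min_shared = 50,
                         seed = 1) {
  if (inherits(input, "dataset_bundle")) {
    abundances <- input$abundances
    metadata <- input$metadata
    tree <- input$tree
    pathways <- input$pathways
    catalogue <- input$catalogue
    alleles <- input$alleles
  } else {
    dir <- input
    stage <- function(f) file.path(dir, f)
    abundances <- read_abundance_table(stage("abundances.tsv"))
    metadata <- read_metadata(stage("metadata.tsv"))
    tree <- read_tree(stage("tree.nwk"), taxa = rownames(abundances))
    pathways <- read_pathway_db(stage("pathways.tsv"))
    genomes <- utils::read.delim(stage("catalogue.tsv"), stringsAsFactors = FALSE)
    catalogue <- genome_catalogue(genomes, read_annotations(stage("annotations.tsv")))
    alleles <- if (file.exists(stage("alleles.tsv"))) read_alleles(stage("alleles.tsv")) else NULL
  }
  env <- factor(metadata$environment)
  envs <- levels(env)

  ## functional distillation
  gifts <- distill_catalogue(catalogue, pathways)
  fun_gifts <- aggregate_hierarchy(gifts, pathways, "function")
  community <- community_weighted(fun_gifts, abundances)
  mci <- metabolic_capacity_index(community)
  mci_test <- compare_alpha(split(mci, env))

  ## alpha diversity
  alpha <- data.frame(
    sample_id = colnames(abundances),
    richness = apply(abundances, 2L, hill_number, q = 0, renormalize = TRUE),
    neutral_q1 = apply(abundances, 2L, hill_number, q = 1, renormalize = TRUE),
    phylo_q1 = apply(abundances, 2L, function(p) {
      phylo_hill_q1(stats::setNames(p, rownames(abundances)), tree, renormalize = TRUE)
    }),
    stringsAsFactors = FALSE
  )
  alpha_tests <- lapply(c(richness = "richness", neutral_q1 = "neutral_q1",
                          phylo_q1 = "phylo_q1"),
                        function(m) compare_alpha(split(alpha[[m]], env)))

  ## beta diversity
  D_neutral <- distance_matrix(abundances, "turnover_q1_neutral")
  D_phylo <- distance_matrix(abundances, "turnover_q1_phylo", tree = tree)
  perm_neutral <- permanova(D_neutral, metadata, terms = c("environment", "stream"),
                            n_perm = n_perm, seed = derive_seed(seed, 11))
  perm_phylo <- permanova(D_phylo, metadata, terms = c("environment", "stream"),
                          n_perm = n_perm, seed = derive_seed(seed, 12))
  disp_neutral <- beta_dispersion(D_neutral, env, n_perm = n_perm,
                                  seed = derive_seed(seed, 13))

  ## partitioning
  detection <- detect_presence(abundances, min_abundance)
  labels <- classify_fractions(detection, metadata, prevalence_threshold)
  summary_tab <- fraction_summary(labels, abundances, catalogue, gifts, pathways)
  genome_tests <- genome_level_comparison(labels, catalogue, gifts, pathways)
  fraction_fun <- fraction_functional_comparison(labels, gifts, abundances,
                                                 metadata, pathways,
                                                 n_perm = n_perm,
                                                 seed = derive_seed(seed, 14))

  ## microdiversity
  micro <- NULL
  if (!is.null(alleles) && length(alleles)) {
    matrices <- lapply(alleles, microdiversity_matrix, min_shared = min_shared)
    micro <- group_microdiversity_compare(matrices, labels, metadata)
  } else {
    warnf("no allele tables available; microdiversity stage skipped")
  }

  ## genome recovery
  damr_tab <- cbind(metadata[, "sample_id", drop = FALSE],
                    damr(metadata$mapped_bases / metadata$sequenced_bases,
                         metadata$prokaryotic_fraction))

  results <- list(alpha = alpha, alpha_tests = alpha_tests,
                  beta = list(neutral = D_neutral, phylo = D_phylo,
                              permanova_neutral = perm_neutral,
                              permanova_phylo = perm_phylo,
                              dispersion_neutral = disp_neutral),
                  gifts = gifts, community = community,
                  mci = mci, mci_test = mci_test,
                  labels = labels, summary = summary_tab,
                  genome_tests = genome_tests,
                  fraction_functional = fraction_fun,
                  microdiversity = micro, damr = damr_tab,
                  seed = seed)

  if (!is.null(out_dir)) write_pipeline_results(results, out_dir, n_perm)
  invisible(results)
}

write_pipeline_results <- function(results, out_dir, n_perm) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.table(x, file.path(out_dir, f), sep = "\t",
                                         quote = FALSE, row.names = FALSE)
  w(results$alpha, "alpha_diversity.tsv")
  w(results$beta$permanova_neutral, "permanova_neutral.tsv")
  w(results$beta$permanova_phylo, "permanova_phylo.tsv")
  w(results$labels, "fraction_labels.tsv")
  w(results$summary, "fraction_summary.tsv")
  w(results$genome_tests, "genome_level_tests.tsv")
  w(results$damr, "damr.tsv")
  frx <- results$fraction_functional
  fr_rows <- do.call(rbind, lapply(names(frx), function(fr) {
    x <- frx[[fr]]
    data.frame(fraction = fr, comparable = isTRUE(x$comparable),
               n_samples = x$n_samples %||% NA,
               n_significant_traits = x$n_significant %||% NA,
               R2 = x$R2 %||% NA, p = x$p %||% NA, stringsAsFactors = FALSE)
  }))
  w(fr_rows, "fraction_functional.tsv")
  if (!is.null(results$microdiversity)) {
    w(results$microdiversity$per_genome, "microdiversity_per_genome.tsv")
    w(results$microdiversity$contrasts, "microdiversity_contrasts.tsv")
  }
  manifest <- c(
    sprintf("package: magtraits %s", as.character(utils::packageVersion("magtraits"))),
    sprintf("R: %s", R.version.string),
    sprintf("seed: %d", results$seed),
    sprintf("n_perm: %d", n_perm),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  summary_lines <- c(
    sprintf("samples: %d; genomes: %d", nrow(results$alpha), nrow(results$labels)),
    sprintf("fractions: %s",
            paste(sprintf("%s %d (%.1f%%)", results$summary$fraction,
                          results$summary$n_genomes, results$summary$percent),
                  collapse = ", ")),
    sprintf("beta PERMANOVA (neutral) environment: R2 = %.3f, p = %.3f",
            results$beta$permanova_neutral$R2[1], results$beta$permanova_neutral$p[1])
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
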