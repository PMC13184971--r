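#' Simulation configuration for a two-environment stream study
#'
#' Defines the ground-truth structure of a synthetic genome-resolved
#' microbiome dataset: two environments with two replicated streams each and
#' an unbalanced sample layout (default 8+7 subalpine, 7+9 montane — 31
#' animals), a dominant core fraction carrying ~87\% of relative abundance,
#' environment-exclusive endemic genomes detected well above the 20\%
#' prevalence rule, sparse marginal genomes, a pathway-completion advantage
#' for the endemics of the `high_environment`, and higher within-environment
#' allele divergence in that same environment.
#'
#' @param n_environments number of environments (the analysis assumes 2).
#' @param streams_per_environment replicated streams per environment.
#' @param samples_per_stream integer vector, one entry per stream in
#'   environment order; sum is the number of animals.
#' @param n_core,n_endemic_per_environment,n_marginal genome counts.
#' @param core_mass_target expected fraction of per-sample abundance carried
#'   by core genomes.
#' @param endemic_prevalence within-environment per-sample detection
#'   probability of endemic genomes.
#' @param marginal_prevalence same for marginal genomes (single environment).
#' @param pathway_count,steps_per_pathway synthetic pathway database shape.
#' @param completion_prob named list: probability that a required identifier
#'   is present, for `core`, `endemic_high` (endemics of
#'   `high_environment`), `endemic_low`, `marginal`.
#' @param allele_positions consensus-allele sites per genome.
#' @param divergence_rate named numeric (by environment): per-site
#'   substitution probability between a sample and its environment's
#'   ancestral sequence; must be <= 0.5.
#' @param ancestral_divergence fraction of sites at which the two
#'   environments' ancestral sequences differ.
#' @param coverage_dropout per-sample probability that a site is uncovered.
#' @param abundance_sigma sdlog of the log-normal abundance weights (tail
#'   control of the rank-abundance curve).
#' @param prok_fraction_preset `"gut"` (Beta(7,3), near-complete prokaryotic
#'   recovery) or `"skin"` (Beta(1,9), host-dominated).
#' @param environments environment labels; the second is the "high" one by
#'   default.
#' @param high_environment which environment gets the higher endemic
#'   completion probability and divergence rate.
#' @param seed integer seed recorded in the config and used by
#'   [generate_dataset()].
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_environments = 2,
                       streams_per_environment = 2,
                       samples_per_stream = c(8, 7, 7, 9),
                       n_core = 50,
                       n_endemic_per_environment = 15,
                       n_marginal = 10,
                       core_mass_target = 0.87,
                       endemic_prevalence = 0.6,
                       marginal_prevalence = 0.08,
                       pathway_count = 40,
                       steps_per_pathway = 4,
                       completion_prob = list(core = 0.8, endemic_high = 0.75,
                                              endemic_low = 0.55, marginal = 0.5),
                       allele_positions = 1000,
                       divergence_rate = NULL,
                       ancestral_divergence = 0.05,
                       coverage_dropout = 0.05,
                       abundance_sigma = 1.0,
                       prok_fraction_preset = c("gut", "skin"),
                       environments = c("subalpine", "montane"),
                       high_environment = "montane",
                       seed = 42) {
  prok_fraction_preset <- match.arg(prok_fraction_preset)
  if (is.null(divergence_rate)) {
    divergence_rate <- stats::setNames(
      ifelse(environments == high_environment, 0.02, 0.005), environments)
  }
  cfg <- list(
    n_environments = as.integer(n_environments),
    streams_per_environment = as.integer(streams_per_environment),
    samples_per_stream = as.integer(samples_per_stream),
    n_core = as.integer(n_core),
    n_endemic_per_environment = as.integer(n_endemic_per_environment),
    n_marginal = as.integer(n_marginal),
    core_mass_target = core_mass_target,
    endemic_prevalence = endemic_prevalence,
    marginal_prevalence = marginal_prevalence,
    pathway_count = as.integer(pathway_count),
    steps_per_pathway = as.integer(steps_per_pathway),
    completion_prob = completion_prob,
    allele_positions = as.integer(allele_positions),
    divergence_rate = divergence_rate,
    ancestral_divergence = ancestral_divergence,
    coverage_dropout = coverage_dropout,
    abundance_sigma = abundance_sigma,
    prok_fraction_preset = prok_fraction_preset,
    environments = environments,
    high_environment = high_environment,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  n_streams <- cfg$n_environments * cfg$streams_per_environment
  if (length(cfg$environments) != cfg$n_environments) {
    stopf("need %d environment labels", cfg$n_environments)
  }
  if (!cfg$high_environment %in% cfg$environments) {
    stopf("high_environment must be one of the environment labels")
  }
  if (length(cfg$samples_per_stream) != n_streams) {
    stopf("samples_per_stream must have one entry per stream (%d)", n_streams)
  }
  if (sum(cfg$samples_per_stream) < 4L) stopf("need at least 4 samples in total")
  if (any(cfg$samples_per_stream < 1L)) stopf("every stream needs at least 1 sample")
  if (cfg$n_core < 1L) stopf("need at least 1 core genome")
  if (cfg$n_endemic_per_environment < 0L || cfg$n_marginal < 0L) {
    stopf("genome counts must be non-negative")
  }
  probs <- c(cfg$core_mass_target, cfg$endemic_prevalence, cfg$marginal_prevalence,
             unlist(cfg$completion_prob), cfg$ancestral_divergence,
             cfg$coverage_dropout, cfg$divergence_rate)
  if (any(probs < 0 | probs > 1)) stopf("all probabilities must lie in [0, 1]")
  if (any(cfg$divergence_rate > 0.5)) {
    stopf("divergence_rate > 0.5 rejected (alleles would be anti-correlated)")
  }
  noncore <- cfg$n_endemic_per_environment * cfg$endemic_prevalence +
    cfg$n_marginal * cfg$marginal_prevalence
  if (cfg$core_mass_target >= 1 && noncore > 0) {
    stopf("impossible mass target: core_mass_target = 1 with non-core genomes present")
  }
  if (cfg$core_mass_target <= 0) stopf("core_mass_target must be positive")
  invisible(cfg)
}

#' Sample layout implied by a simulation configuration
#'
#' Deterministic given the config: sample ids, stream and environment labels.
#'
#' @param config a [sim_config()].
#' @return data.frame with `sample_id`, `stream`, `environment`.
#' @export
sample_layout <- function(config) {
  envs <- rep(config$environments, each = config$streams_per_environment)
  streams <- paste0(envs, "_s", rep(seq_len(config$streams_per_environment),
                                    times = config$n_environments))
  n <- sum(config$samples_per_stream)
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    stream = rep(streams, times = config$samples_per_stream),
    environment = rep(envs, times = config$samples_per_stream),
    stringsAsFactors = FALSE
  )
}

#' Ground truth for a synthetic dataset
#'
#' Assigns genome ids, true fraction labels, endemic/marginal environments,
#' per-genome pathway-completion probabilities and per-environment allele
#' divergence rates — the bookkeeping against which recovery is tested.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (marginal genomes are assigned an environment at
#'   random).
#' @return list of class `ground_truth` with `genome_id`, `true_fraction`,
#'   `true_environment` (endemic and marginal genomes), `true_completion_prob`,
#'   `true_divergence`.
#' @export
make_truth <- function(config, seed = config$seed) {
  envs <- config$environments
  high <- config$high_environment
  core_ids <- sprintf("core_%03d", seq_len(config$n_core))
  endemic_ids <- unlist(lapply(envs, function(e) {
    if (config$n_endemic_per_environment == 0L) return(character(0))
    sprintf("end_%s_%02d", e, seq_len(config$n_endemic_per_environment))
  }))
  marg_ids <- if (config$n_marginal > 0L) sprintf("marg_%02d", seq_len(config$n_marginal)) else character(0)
  ids <- c(core_ids, endemic_ids, marg_ids)
  fraction <- stats::setNames(
    c(rep("core", length(core_ids)), rep("endemic", length(endemic_ids)),
      rep("marginal", length(marg_ids))), ids)
  environment <- stats::setNames(rep(NA_character_, length(ids)), ids)
  environment[endemic_ids] <- rep(envs, each = config$n_endemic_per_environment)
  environment[marg_ids] <- with_seed(seed, sample(envs, length(marg_ids), replace = TRUE))
  cp <- config$completion_prob
  completion <- stats::setNames(numeric(length(ids)), ids)
  completion[core_ids] <- cp$core
  completion[endemic_ids] <- ifelse(environment[endemic_ids] == high,
                                    cp$endemic_high, cp$endemic_low)
  completion[marg_ids] <- cp$marginal
  structure(list(genome_id = ids, true_fraction = fraction,
                 true_environment = environment,
                 true_completion_prob = completion,
                 true_divergence = config$divergence_rate),
            class = "ground_truth")
}

#' Generate a genomes-by-samples relative abundance table
#'
#' Occupancy first, magnitude second: core genomes occupy every sample;
#' endemic genomes occupy samples of their environment independently with
#' `endemic_prevalence`; marginal genomes occupy samples of their single
#' environment with `marginal_prevalence` (at least one sample is forced so
#' every genome is observable). Abundance weights for occupied cells are
#' log-normal (`sdlog = abundance_sigma`), core weights are scaled per
#' environment so the expected core mass share equals `core_mass_target`,
#' and each column is renormalized to sum to 1.
#'
#' @param config a [sim_config()].
#' @param truth a [make_truth()] result.
#' @param seed integer seed.
#' @return genomes-by-samples matrix; every column sums to 1.
#' @export
generate_abundances <- function(config, truth, seed = config$seed) {
  validate_config(config)
  layout <- sample_layout(config)
  n_s <- nrow(layout)
  ids <- truth$genome_id
  with_seed(seed, {
    present <- matrix(FALSE, length(ids), n_s, dimnames = list(ids, layout$sample_id))
    for (i in seq_along(ids)) {
      fr <- truth$true_fraction[i]
      if (fr == "core") {
        present[i, ] <- TRUE
      } else {
        env_cols <- which(layout$environment == truth$true_environment[i])
        p <- if (fr == "endemic") config$endemic_prevalence else config$marginal_prevalence
        occ <- stats::runif(length(env_cols)) < p
        if (!any(occ)) occ[sample.int(length(env_cols), 1L)] <- TRUE
        present[i, env_cols] <- occ
      }
    }
    W <- matrix(0, length(ids), n_s, dimnames = dimnames(present))
    W[present] <- stats::rlnorm(sum(present), 0, config$abundance_sigma)
    # expected-mass scaling of core weights, per environment (in units of the
    # common log-normal mean, which cancels)
    t <- config$core_mass_target
    is_core <- truth$true_fraction == "core"
    for (e in config$environments) {
      n_marg_e <- sum(truth$true_fraction == "marginal" & truth$true_environment == e)
      e_noncore <- config$n_endemic_per_environment * config$endemic_prevalence +
        n_marg_e * config$marginal_prevalence
      if (e_noncore == 0) next
      lambda <- t / (1 - t) * e_noncore / config$n_core
      cols <- layout$environment == e
      W[is_core, cols] <- W[is_core, cols] * lambda
    }
    sweep(W, 2L, colSums(W), "/")
  })
}

#' Construct a genome catalogue
#'
#' @param genomes data.frame with `genome_id`, `size`, `completeness`,
#'   `contamination`, `taxonomy`.
#' @param annotations named list (by genome id) of identifier character
#'   vectors.
#' @return object of class `genome_catalogue`.
#' @export
genome_catalogue <- function(genomes, annotations) {
  if (anyDuplicated(genomes$genome_id)) stopf("duplicate genome ids in catalogue")
  if (!setequal(names(annotations), genomes$genome_id)) {
    stopf("annotation list must cover exactly the catalogue genomes")
  }
  structure(list(genomes = as.data.frame(genomes, stringsAsFactors = FALSE),
                 annotations = annotations[genomes$genome_id]),
            class = "genome_catalogue")
}

#' @export
print.genome_catalogue <- function(x, ...) {
  cat(sprintf("<genome_catalogue> %d genomes, %d annotated identifiers total\n",
              nrow(x$genomes), sum(lengths(x$annotations))))
  invisible(x)
}

#' Generate genome annotations and catalogue metadata
#'
#' Every identifier required by the pathway database is included in a
#' genome's annotation set independently with that genome's true completion
#' probability. Genome sizes are log-normal with a larger mean for core
#' genomes (3.2 Mb vs 2.4 Mb); completeness and contamination are drawn in
#' CheckM-plausible ranges, taxonomy from a fixed phylum pool.
#'
#' @param config a [sim_config()].
#' @param truth a [make_truth()] result.
#' @param pathways a [pathway_db()].
#' @param seed integer seed.
#' @return a [genome_catalogue()].
#' @export
generate_annotations <- function(config, truth, pathways, seed = config$seed) {
  stopifnot(inherits(pathways, "pathway_db"))
  idents <- required_identifiers(pathways)
  ids <- truth$genome_id
  with_seed(seed, {
    annotations <- lapply(ids, function(g) {
      idents[stats::runif(length(idents)) < truth$true_completion_prob[g]]
    })
    names(annotations) <- ids
    is_core <- truth$true_fraction == "core"
    size <- round(stats::rlnorm(length(ids),
                                meanlog = ifelse(is_core, log(3.2e6), log(2.4e6)),
                                sdlog = 0.18))
    phyla <- c("p__Bacteroidota", "p__Bacillota_A", "p__Pseudomonadota",
               "p__Verrucomicrobiota", "p__Actinomycetota")
    genomes <- data.frame(
      genome_id = ids,
      size = size,
      completeness = round(stats::runif(length(ids), 80, 100), 2),
      contamination = round(stats::runif(length(ids), 0, 5), 2),
      taxonomy = sample(phyla, length(ids), replace = TRUE),
      stringsAsFactors = FALSE
    )
    genome_catalogue(genomes, annotations)
  })
}

#' Generate per-genome consensus-allele tables
#'
#' For each core and endemic genome: each environment has an ancestral
#' sequence (the two differing at `ancestral_divergence` of sites); each
#' sample's consensus is the ancestral of its environment mutated
#' independently per site at the environment's divergence rate (substituted
#' base drawn uniformly from the other three); a `coverage_dropout` fraction
#' of sites per sample is masked as uncovered (`NA`). Core genomes get
#' alleles in every sample, endemic genomes only in their environment's
#' samples; marginal genomes carry no allele table.
#'
#' @param config a [sim_config()].
#' @param truth a [make_truth()] result.
#' @param seed integer seed.
#' @return named list (by genome) of positions-by-samples character
#'   matrices.
#' @export
generate_alleles <- function(config, truth, seed = config$seed) {
  validate_config(config)
  layout <- sample_layout(config)
  bases <- c("A", "C", "G", "T")
  L <- config$allele_positions
  mutate <- function(x, rate) {
    hit <- which(stats::runif(length(x)) < rate)
    if (length(hit)) {
      x[hit] <- bases[(match(x[hit], bases) - 1L +
                         sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
    }
    x
  }
  keep <- truth$genome_id[truth$true_fraction %in% c("core", "endemic")]
  with_seed(seed, {
    out <- lapply(keep, function(g) {
      anc <- list()
      anc[[config$environments[1L]]] <- sample(bases, L, replace = TRUE)
      anc2 <- anc[[1L]]
      flip <- which(stats::runif(L) < config$ancestral_divergence)
      if (length(flip)) {
        anc2[flip] <- bases[(match(anc2[flip], bases) - 1L +
                               sample.int(3L, length(flip), replace = TRUE)) %% 4L + 1L]
      }
      anc[[config$environments[2L]]] <- anc2
      cols <- if (truth$true_fraction[g] == "core") seq_len(nrow(layout))
              else which(layout$environment == truth$true_environment[g])
      m <- matrix(NA_character_, L, length(cols),
                  dimnames = list(NULL, layout$sample_id[cols]))
      for (k in seq_along(cols)) {
        e <- layout$environment[cols[k]]
        al <- mutate(anc[[e]], config$divergence_rate[[e]])
        al[stats::runif(L) < config$coverage_dropout] <- NA_character_
        m[, k] <- al
      }
      m
    })
    names(out) <- keep
    out
  })
}

#' Generate a complete, ground-truth-annotated dataset bundle
#'
#' Orchestrates the component generators under sub-seeds derived from
#' `config$seed`: pathway database, ground truth, genome catalogue with
#' annotations, abundance table, allele tables, a random bifurcating
#' phylogeny over the genomes, and sample metadata with prokaryotic
#' fractions (Beta(7,3) for the gut preset, Beta(1,9) for skin) and
#' sequenced/mapped base counts consistent with a known mapping-rate ratio
#' (stored in the truth as `true_damr`).
#'
#' @param config a [sim_config()].
#' @return list of class `dataset_bundle`: `config`, `truth`, `pathways`,
#'   `catalogue`, `abundances`, `alleles`, `tree` (an `ape::phylo`),
#'   `tree_newick`, `metadata`.
#' @export
generate_dataset <- function(config = sim_config()) {
  validate_config(config)
  seed <- config$seed
  truth <- make_truth(config, derive_seed(seed, 1))
  pathways <- synthetic_pathway_db(config$pathway_count, config$steps_per_pathway,
                                   seed = derive_seed(seed, 2))
  catalogue <- generate_annotations(config, truth, pathways, seed = derive_seed(seed, 3))
  abundances <- generate_abundances(config, truth, seed = derive_seed(seed, 4))
  alleles <- generate_alleles(config, truth, seed = derive_seed(seed, 5))
  tree <- with_seed(derive_seed(seed, 6), {
    tr <- ape::rtree(length(truth$genome_id))
    tr$tip.label <- sample(truth$genome_id)
    tr
  })
  layout <- sample_layout(config)
  metadata <- with_seed(derive_seed(seed, 7), {
    n <- nrow(layout)
    prok <- if (config$prok_fraction_preset == "gut") stats::rbeta(n, 7, 3)
            else stats::rbeta(n, 1, 9)
    sequenced <- round(stats::rlnorm(n, log(2e9), 0.25))
    mapped <- round(sequenced * prok * stats::runif(n, 0.85, 0.98))
    cbind(layout,
          data.frame(sequenced_bases = sequenced, mapped_bases = mapped,
                     prokaryotic_fraction = prok))
  })
  truth$true_damr <- stats::setNames(
    metadata$mapped_bases / metadata$sequenced_bases / metadata$prokaryotic_fraction,
    metadata$sample_id)
  structure(list(config = config, truth = truth, pathways = pathways,
                 catalogue = catalogue, abundances = abundances,
                 alleles = alleles, tree = tree,
                 tree_newick = ape::write.tree(tree), metadata = metadata),
            class = "dataset_bundle")
}

#' Check the internal consistency of a dataset bundle
#'
#' Verifies the cross-component invariants: abundance columns match metadata
#' sample ids and sum to 1, genome ids agree between truth, catalogue,
#' abundances and tree tips, endemic genomes never occur outside their
#' environment, every genome carries exactly one truth label, and allele
#' tables cover core and endemic genomes.
#'
#' @param bundle a [generate_dataset()] result.
#' @return TRUE invisibly; errors on the first violated invariant.
#' @export
validate_dataset <- function(bundle) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  ab <- bundle$abundances
  md <- bundle$metadata
  if (!identical(colnames(ab), md$sample_id)) stopf("abundance samples != metadata samples")
  if (any(abs(colSums(ab) - 1) > 1e-9)) stopf("abundance columns must sum to 1")
  ids <- bundle$truth$genome_id
  if (!identical(rownames(ab), ids)) stopf("abundance genomes != truth genomes")
  if (!setequal(bundle$tree$tip.label, ids)) stopf("tree tips != genome ids")
  if (!setequal(bundle$catalogue$genomes$genome_id, ids)) stopf("catalogue != truth genomes")
  if (anyNA(bundle$truth$true_fraction) ||
      !all(bundle$truth$true_fraction %in% c("core", "endemic", "marginal"))) {
    stopf("every genome needs exactly one fraction label")
  }
  for (g in ids[bundle$truth$true_fraction == "endemic"]) {
    env <- bundle$truth$true_environment[g]
    outside <- md$sample_id[md$environment != env]
    if (any(ab[g, outside] > 0)) stopf("endemic genome %s detected outside %s", g, env)
  }
  need_alleles <- ids[bundle$truth$true_fraction %in% c("core", "endemic")]
  if (!setequal(names(bundle$alleles), need_alleles)) {
    stopf("allele tables must cover exactly the core and endemic genomes")
  }
  invisible(TRUE)
}
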