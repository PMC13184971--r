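test_that("configuration validation catches impossible designs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(samples_per_stream = c(8, 7, 7)), "one entry per stream")
  expect_error(sim_config(core_mass_target = 1), "impossible mass target")
  expect_error(sim_config(endemic_prevalence = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_core = 0), "at least 1 core")
  # a pure-core design may carry all the mass
  expect_silent(sim_config(core_mass_target = 1, n_endemic_per_environment = 0,
                           n_marginal = 0))
})

test_that("abundance tables conserve mass and honour the occupancy structure", {
  cfg <- small_config(seed = 71)
  truth <- make_truth(cfg, 1)
  ab <- generate_abundances(cfg, truth, seed = 2)
  expect_equal(unname(colSums(ab)), rep(1, ncol(ab)), tolerance = 1e-9)
  expect_true(all(ab >= 0))
  # determinism
  expect_identical(ab, generate_abundances(cfg, truth, seed = 2))
  # core genomes present everywhere
  core <- truth$genome_id[truth$true_fraction == "core"]
  expect_true(all(ab[core, ] > 0))
  # endemic genomes never outside their environment
  layout <- sample_layout(cfg)
  for (g in truth$genome_id[truth$true_fraction == "endemic"]) {
    out <- layout$sample_id[layout$environment != truth$true_environment[g]]
    expect_true(all(ab[g, out] == 0))
  }
  # every genome observable somewhere
  expect_true(all(rowSums(ab) > 0))
  # pure-core config: each column is 100% core
  cfg0 <- small_config(seed = 71)
  cfg0$n_endemic_per_environment <- 0L; cfg0$n_marginal <- 0L
  tr0 <- make_truth(cfg0, 1)
  ab0 <- generate_abundances(cfg0, tr0, seed = 3)
  expect_equal(unname(colSums(ab0[tr0$true_fraction == "core", ])),
               rep(1, ncol(ab0)))
})

test_that("realized core mass converges to the configured target", {
  # Monte-Carlo calibration check: 1000 samples under the default genome
  # structure should land within +-0.03 of the 0.87 target
  cfg <- sim_config(samples_per_stream = rep(250, 4), seed = 72)
  truth <- make_truth(cfg, 1)
  ab <- generate_abundances(cfg, truth, seed = 4)
  core_mass <- mean(colSums(ab[truth$true_fraction == "core", ]))
  expect_lt(abs(core_mass - cfg$core_mass_target), 0.03)
  # realized endemic prevalence distributes around its target
  det <- detect_presence(ab)
  layout <- sample_layout(cfg)
  prev <- prevalence_by_environment(det, layout)
  end_high <- truth$genome_id[truth$true_fraction == "endemic" &
                                truth$true_environment == "montane"]
  expect_lt(abs(mean(prev[end_high, "montane"]) - cfg$endemic_prevalence), 0.05)
})

test_that("annotation generation expresses the completion-probability gradient", {
  cfg <- sim_config(seed = 73)
  truth <- make_truth(cfg, 1)
  db <- synthetic_pathway_db(cfg$pathway_count, cfg$steps_per_pathway, seed = 2)
  # boundary cases: all and nothing
  t1 <- truth; t1$true_completion_prob[] <- 1
  cat1 <- generate_annotations(cfg, t1, db, seed = 3)
  expect_true(all(lengths(cat1$annotations) == length(required_identifiers(db))))
  t0 <- truth; t0$true_completion_prob[] <- 0
  cat0 <- generate_annotations(cfg, t0, db, seed = 3)
  expect_true(all(lengths(cat0$annotations) == 0))
  # high-environment endemics out-score low-environment endemics in mean MCI
  # across independent seeds (effect placed by the completion probabilities)
  end_ids <- truth$genome_id[truth$true_fraction == "endemic"]
  hi <- end_ids[truth$true_environment[end_ids] == "montane"]
  lo <- end_ids[truth$true_environment[end_ids] == "subalpine"]
  wins <- vapply(1:200, function(s) {
    cat_s <- generate_annotations(cfg, truth, db, seed = 1000 + s)
    gm <- distill_catalogue(cat_s$annotations[end_ids], db)
    mci <- genome_mci(gm, db)
    mean(mci[hi]) > mean(mci[lo])
  }, TRUE)
  expect_gte(mean(wins), 0.95)
  # core genomes are drawn larger on average
  sizes <- cat1$genomes$size
  expect_gt(mean(sizes[truth$true_fraction == "core"]),
            mean(sizes[truth$true_fraction != "core"]))
})

test_that("dataset bundles are internally consistent and reproducible", {
  cfg <- small_config(seed = 74)
  b <- generate_dataset(cfg)
  expect_true(validate_dataset(b))
  b2 <- generate_dataset(cfg)
  expect_identical(b$abundances, b2$abundances)
  expect_identical(b$catalogue$annotations, b2$catalogue$annotations)
  expect_identical(b$tree_newick, b2$tree_newick)
  expect_identical(b$metadata, b2$metadata)
  # four streams across two environments
  expect_equal(length(unique(b$metadata$stream)), 4L)
  expect_equal(length(unique(b$metadata$environment)), 2L)
  # tree is bifurcating with positive branch lengths over all genomes
  expect_true(ape::is.binary(b$tree))
  expect_true(all(b$tree$edge.length > 0))
  # DAMR recovers the generator's mapping-rate ratio
  r <- damr(b$metadata$mapped_bases / b$metadata$sequenced_bases,
            b$metadata$prokaryotic_fraction)
  expect_equal(r$damr, unname(b$truth$true_damr[b$metadata$sample_id]),
               tolerance = 1e-9)
})

test_that("the classifier recovers the planted fraction labels", {
  b <- generate_dataset(sim_config(seed = 75))
  det <- detect_presence(b$abundances)
  lab <- classify_fractions(det, b$metadata)
  truth_lab <- unname(b$truth$true_fraction[lab$genome_id])
  expect_gte(mean(lab$fraction == truth_lab), 0.95)
  # endemic environment assignments match the ground truth
  hit <- lab$fraction == "endemic" & truth_lab == "endemic"
  expect_true(all(lab$environment[hit] ==
                    unname(b$truth$true_environment[lab$genome_id[hit]])))
  # misclassifications only happen at prevalence boundaries
  wrong <- lab$genome_id[lab$fraction != truth_lab]
  if (length(wrong)) {
    prev <- prevalence_by_environment(det, b$metadata)
    near <- apply(prev[wrong, , drop = FALSE], 1, function(p) {
      any(abs(p[p > 0] - 0.20) <= 0.15)
    })
    expect_true(all(near))
  }
})
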