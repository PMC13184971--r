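test_that("detection thresholds act monotonically on prevalence", {
  ab <- matrix(c(0.5, 0.3, 0.2,
                 0.0, 0.9, 0.1,
                 0.1, 0.0, 0.9), 3, 3, byrow = TRUE,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  d0 <- detect_presence(ab)
  expect_true(all(d0[1, ]))
  expect_equal(sum(d0), 7L)
  expect_false(any(detect_presence(ab, min_abundance = 0.95)))
  for (th in c(0, 0.05, 0.15, 0.4)) {
    expect_true(all(rowSums(detect_presence(ab, th)) >= rowSums(detect_presence(ab, th + 0.1))))
  }
  expect_error(detect_presence(ab, -0.1), "non-negative")
})

test_that("fraction classification fires the published prevalence rules", {
  md <- toy_metadata(c(3, 2, 3, 2))  # envA: 5 samples, envB: 5 samples
  det <- toy_detection(md, list(
    core1   = md$sample_id,                       # all four streams
    core2   = c("t01", "t04", "t06", "t09"),      # one per stream
    end_a   = c("t01", "t02", "t04"),             # both envA streams, prevalence 0.6
    end_b20 = c("t06", "t09"),                    # both envB streams, prevalence 0.4
    marg1   = "t02",                              # one sample, one stream
    marg2   = c("t01", "t02", "t03"),             # single stream only
    cross   = c("t01", "t04", "t06")              # both envs, 3 of 4 streams
  ))
  lab <- classify_fractions(det, md, prevalence_threshold = 0.20)
  lab <- stats::setNames(lab$fraction, lab$genome_id)
  expect_equal(unname(lab[c("core1", "core2")]), c("core", "core"))
  expect_equal(unname(lab[c("end_a", "end_b20")]), c("endemic", "endemic"))
  expect_equal(unname(lab[c("marg1", "marg2", "cross")]), rep("marginal", 3))
  full <- classify_fractions(det, md)
  expect_equal(full$environment[full$genome_id == "end_a"], "envA")
  expect_equal(full$rule_fired[full$genome_id == "cross"], "cross_env_partial_streams")
  expect_equal(full$rule_fired[full$genome_id == "marg1"], "single_stream")
  # residual policy switch sends cross-environment genomes to core
  alt <- classify_fractions(det, md, cross_env_policy = "core")
  expect_equal(alt$fraction[alt$genome_id == "cross"], "core")
})

test_that("classification is exhaustive, order-invariant and threshold-monotone", {
  set.seed(51)
  md <- toy_metadata(c(4, 4, 4, 4))
  ab <- matrix(stats::rbinom(30 * 16, 1, 0.35) * stats::rgamma(30 * 16, 1), 30, 16,
               dimnames = list(sprintf("g%02d", 1:30), md$sample_id))
  ab <- sweep(ab + 1e-12, 2, colSums(ab + 1e-12), "/")
  det <- detect_presence(ab, 1e-6)
  lab <- classify_fractions(det, md)
  expect_setequal(lab$genome_id, rownames(det))
  expect_true(all(lab$fraction %in% c("core", "endemic", "marginal")))
  expect_true(all(!is.na(lab$environment[lab$fraction == "endemic"])))
  # invariant to genome and sample order
  gp <- sample(nrow(det)); sp <- sample(ncol(det))
  lab2 <- classify_fractions(det[gp, sp], md[match(colnames(det)[sp], md$sample_id), ])
  lab2 <- lab2[match(lab$genome_id, lab2$genome_id), ]
  expect_equal(lab$fraction, lab2$fraction)
  # raising the threshold can only move endemic -> marginal, never the reverse
  for (th in c(0.3, 0.5, 0.8)) {
    hi <- classify_fractions(det, md, prevalence_threshold = th)
    was_marg <- lab$fraction == "marginal"
    expect_false(any(hi$fraction[was_marg] == "endemic"))
  }
})

test_that("fraction summaries reproduce count percentages and abundance masses", {
  md <- toy_metadata()
  det <- toy_detection(md, list(
    c1 = md$sample_id, c2 = md$sample_id,
    e1 = md$sample_id[md$environment == "envA"],
    m1 = "t01"
  ))
  lab <- classify_fractions(det, md)
  ab <- matrix(0, 4, 8, dimnames = list(rownames(det), md$sample_id))
  ab[det] <- 1
  ab <- sweep(ab, 2, colSums(ab), "/")
  sm <- fraction_summary(lab, ab)
  expect_equal(sm$percent[sm$fraction == "core"], 50.0)
  expect_equal(sm$n_genomes, c(2L, 1L, 1L))
  expect_equal(sum(sm$percent), 100)
  # cumulative abundance per fraction averages the member mass over samples
  expect_equal(sm$mean_cumulative_abundance[sm$fraction == "core"],
               mean(colSums(ab[c("c1", "c2"), ])))
  # single-fraction catalogue: 100% and full mass
  lab1 <- lab[lab$fraction == "core", ]
  ab1 <- sweep(ab[c("c1", "c2"), ], 2, colSums(ab[c("c1", "c2"), ]), "/")
  sm1 <- fraction_summary(lab1, ab1)
  expect_equal(sm1$percent, 100)
  expect_equal(sm1$mean_cumulative_abundance, 1)
})

test_that("genome-level fraction contrasts detect planted size shifts and stay null otherwise", {
  set.seed(52)
  db <- synthetic_pathway_db(10, 2, seed = 5)
  make_cat <- function(sizes) {
    ids <- names(sizes)
    genome_catalogue(
      data.frame(genome_id = ids, size = unname(sizes), completeness = 95,
                 contamination = 1, taxonomy = "p__Bacteroidota",
                 stringsAsFactors = FALSE),
      stats::setNames(replicate(length(ids), character(0), simplify = FALSE), ids))
  }
  n <- 30
  ids <- c(sprintf("c%02d", 1:n), sprintf("e%02d", 1:n))
  lab <- data.frame(genome_id = ids,
                    fraction = rep(c("core", "endemic"), each = n),
                    environment = NA_character_, stringsAsFactors = FALSE)
  gifts <- matrix(runif(2 * n * 10), 2 * n, 10,
                  dimnames = list(ids, db$table$element_id))
  attr(gifts, "level") <- "element"
  # planted +50% core size shift is detected
  cat_shift <- make_cat(stats::setNames(c(rlnorm(n, log(3e6), 0.15),
                                          rlnorm(n, log(2e6), 0.15)), ids))
  res <- genome_level_comparison(lab, cat_shift, gifts, db)
  expect_lt(res$p_adj[res$metric == "genome_size" & res$contrast == "core vs endemic"], 0.05)
  # identical size distributions: null behaviour over repeated draws
  ps <- replicate(30, {
    cat_null <- make_cat(stats::setNames(rlnorm(2 * n, log(2.5e6), 0.2), ids))
    r <- genome_level_comparison(lab, cat_null, gifts, db)
    r$p[r$metric == "genome_size" & r$contrast == "core vs endemic"]
  })
  expect_lt(mean(ps < 0.05), 0.25)
  # single fraction present: empty result
  expect_equal(nrow(genome_level_comparison(lab[lab$fraction == "core", ],
                                            cat_shift, gifts, db)), 0L)
})

test_that("fraction-wise functional comparison flags non-comparable and degenerate cases", {
  cfg <- small_config(seed = 77)
  b <- generate_dataset(cfg)
  lab <- classify_fractions(detect_presence(b$abundances), b$metadata)
  gifts <- distill_catalogue(b$catalogue, b$pathways)
  res <- fraction_functional_comparison(lab, gifts, b$abundances, b$metadata,
                                        b$pathways, n_perm = 49, seed = 1)
  expect_true(res$core$comparable)
  expect_true(res$core$R2 >= 0 && res$core$R2 <= 1)
  expect_true(all(res$core$trait_tests$p_adj >= res$core$trait_tests$p - 1e-12))
  # endemics exist in both environments so the endemic fraction is comparable
  expect_true(res$endemic$comparable)
  # constant profiles across samples: flagged degenerate, not an error
  const_gifts <- gifts; const_gifts[] <- 0.5
  attr(const_gifts, "level") <- "element"
  res2 <- fraction_functional_comparison(lab, const_gifts, b$abundances,
                                         b$metadata, b$pathways, n_perm = 19, seed = 1)
  expect_true(isTRUE(res2$core$degenerate))
  expect_equal(res2$core$n_significant, 0L)
})
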