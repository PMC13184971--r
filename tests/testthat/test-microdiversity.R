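test_that("population ANI counts matches over shared covered sites", {
  a <- rep("A", 100); b <- rep("A", 100)
  r <- pop_ani_pair(a, b)
  expect_equal(r$ani, 1); expect_equal(r$microdiversity, 0); expect_equal(r$shared, 100)
  b[1] <- "C"
  r2 <- pop_ani_pair(a[1:10], b[1:10], min_shared = 5)
  expect_equal(r2$ani, 0.9)
  expect_equal(r2$microdiversity, 0.1)
  # no shared coverage: missing, not zero
  a2 <- c("A", NA, "G"); b2 <- c(NA, "C", NA)
  r3 <- pop_ani_pair(a2, b2, min_shared = 1)
  expect_true(is.na(r3$ani)); expect_equal(r3$shared, 0L)
  # below the minimum-shared threshold: missing
  expect_true(is.na(pop_ani_pair(a[1:30], b[1:30], min_shared = 50)$ani))
  expect_error(pop_ani_pair(a, b[1:50]), "aligned")
})

test_that("the microdiversity matrix equals pairwise popANI and respects permutations", {
  set.seed(61)
  m <- matrix(sample(c("A", "C", "G", "T"), 200 * 5, replace = TRUE), 200, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  m[sample(length(m), 80)] <- NA
  res <- microdiversity_matrix(m, min_shared = 20)
  md <- res$microdiversity
  expect_true(isSymmetric(md))
  expect_equal(unname(diag(md)), rep(0, 5))
  expect_true(all(md[!is.na(md)] >= 0 & md[!is.na(md)] <= 1))
  for (pair in list(c(1, 2), c(2, 5), c(3, 4))) {
    ref <- pop_ani_pair(m[, pair[1]], m[, pair[2]], min_shared = 20)
    expect_equal(md[pair[1], pair[2]], ref$microdiversity)
    expect_equal(res$shared[pair[1], pair[2]], ref$shared)
  }
  # permuting samples permutes rows and columns consistently
  pm <- c(4, 1, 5, 2, 3)
  res2 <- microdiversity_matrix(m[, pm], min_shared = 20)
  expect_equal(res2$microdiversity, md[pm, pm])
  # identical samples give an all-zero matrix
  same <- matrix(rep(m[, 1], 3), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  expect_equal(max(microdiversity_matrix(same, min_shared = 20)$microdiversity,
                   na.rm = TRUE), 0)
})

test_that("lowering the minimum-shared-sites threshold never removes a defined pair", {
  set.seed(62)
  m <- matrix(sample(c("A", "C", "G", "T"), 100 * 4, replace = TRUE), 100, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  m[sample(length(m), 230)] <- NA  # heavy masking so some pairs fall below thresholds
  defined <- function(th) !is.na(microdiversity_matrix(m, min_shared = th)$microdiversity)
  d10 <- defined(10); d30 <- defined(30); d60 <- defined(60)
  expect_true(all(d10[d30])); expect_true(all(d30[d60]))
})

test_that("generated alleles reproduce the divergence model", {
  cfg <- small_config(seed = 63)
  truth <- make_truth(cfg, 1)
  # zero divergence, no masking, identical ancestors: all samples identical
  cfg0 <- small_config(seed = 63)
  cfg0$divergence_rate[] <- 0; cfg0$coverage_dropout <- 0; cfg0$ancestral_divergence <- 0
  al0 <- generate_alleles(cfg0, truth, seed = 5)
  g <- al0[[1]]
  expect_true(all(apply(g, 1, function(r) length(unique(r)) == 1L)))
  # determinism under a fixed seed
  expect_identical(generate_alleles(cfg, truth, seed = 9),
                   generate_alleles(cfg, truth, seed = 9))
  # within-environment expected mismatch ~= 2 * divergence rate (loose band)
  cfg2 <- sim_config(seed = 64)
  tr2 <- make_truth(cfg2, 2)
  al2 <- generate_alleles(cfg2, tr2, seed = 3)
  layout <- sample_layout(cfg2)
  core <- names(al2)[startsWith(names(al2), "core")]
  env_mean <- function(env) {
    s <- layout$sample_id[layout$environment == env]
    mean(vapply(core[1:20], function(g) {
      md <- microdiversity_matrix(al2[[g]][, s], min_shared = 50)$microdiversity
      mean(md[upper.tri(md)], na.rm = TRUE)
    }, 0))
  }
  for (env in cfg2$environments) {
    expected <- 2 * cfg2$divergence_rate[[env]]
    expect_lt(abs(env_mean(env) - expected) / expected, 0.2)
  }
  expect_error(sim_config(divergence_rate = c(subalpine = 0.6, montane = 0.01)),
               "anti-correlated")
})

test_that("environment contrasts recover planted divergence structure", {
  cfg <- sim_config(seed = 65)
  truth <- make_truth(cfg, 1)
  al <- generate_alleles(cfg, truth, seed = 2)
  mats <- lapply(al, microdiversity_matrix)
  layout <- sample_layout(cfg)
  lab <- data.frame(genome_id = truth$genome_id,
                    fraction = unname(truth$true_fraction),
                    environment = unname(truth$true_environment),
                    stringsAsFactors = FALSE)
  res <- group_microdiversity_compare(mats, lab, layout)
  core_rows <- res$per_genome$fraction == "core"
  # between-environment divergence exceeds within-environment for core genomes
  expect_true(all(res$per_genome$between[core_rows] >
                    res$per_genome$within_montane[core_rows], na.rm = TRUE))
  # the high-divergence environment shows higher within-environment values
  ct <- res$contrasts[res$contrasts$unit == "genome_mean" &
                        startsWith(res$contrasts$contrast, "core"), ]
  expect_gt(ct$mean_1, ct$mean_2)  # montane listed first
  expect_lt(ct$p, 0.05)
  # genome-mean and pooled-pair variants are both reported
  expect_setequal(unique(res$contrasts$unit), c("genome_mean", "pooled_pairs"))
})
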