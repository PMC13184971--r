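test_that("PERMANOVA matches the adonis2 sequential partition on random data", {
  set.seed(31)
  X <- matrix(rnorm(12 * 4), 12)
  D <- as.matrix(dist(X))
  rownames(D) <- colnames(D) <- sprintf("s%02d", 1:12)
  md <- data.frame(sample_id = rownames(D),
                   environment = rep(c("a", "b"), each = 6),
                   stream = rep(c("x", "y", "x", "y"), each = 3))
  fit <- permanova(D, md, c("environment", "stream"), n_perm = 99, seed = 2)
  vfit <- vegan::adonis2(stats::as.dist(D) ~ environment + stream, data = md,
                         permutations = 99, by = "terms")
  expect_equal(fit$SS[1:2], vfit$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(fit$R2[1:2], vfit$R2[1:2], tolerance = 1e-10)
  expect_equal(fit$F[1:2], vfit$F[1:2], tolerance = 1e-10)
  expect_equal(fit$df, c(1, 1, 9, 11))
  expect_equal(sum(fit$SS[1:3]), fit$SS[4], tolerance = 1e-10)
})

test_that("PERMANOVA is invariant to sample reordering and errors on degenerate factors", {
  set.seed(32)
  X <- matrix(rnorm(8 * 3), 8)
  D <- as.matrix(dist(X))
  rownames(D) <- colnames(D) <- paste0("s", 1:8)
  md <- data.frame(sample_id = rownames(D), g = rep(c("a", "b"), 4))
  f1 <- permanova(D, md, "g", n_perm = 49, seed = 9)
  perm <- c(5, 2, 8, 1, 3, 7, 4, 6)
  f2 <- permanova(D[perm, perm], md[perm, ], "g", n_perm = 49, seed = 9)
  expect_equal(f1$SS, f2$SS, tolerance = 1e-10)
  expect_equal(f1$F[1], f2$F[1], tolerance = 1e-10)
  expect_error(permanova(D, data.frame(sample_id = rownames(D), g = "a"), "g"),
               "fewer than 2 levels")
})

test_that("exhaustive-mode p equals the brute-force enumeration oracle", {
  set.seed(33)
  for (k in 1:3) {
    n <- c(5, 6, 6)[k]
    X <- matrix(rnorm(n * 2), n)
    D <- as.matrix(dist(X))
    rownames(D) <- colnames(D) <- paste0("s", seq_len(n))
    groups <- c(rep("a", 2), rep("b", n - 2))
    md <- data.frame(sample_id = rownames(D), g = groups)
    fit <- permanova(D, md, "g", exhaustive = TRUE)
    expect_equal(fit$p[1], oracle_permanova_p(D, groups), tolerance = 1e-12)
    # and the analytic statistic agrees with the group-sum formulas
    o <- oracle_permanova_stat(D, groups)
    expect_equal(fit$F[1], o$F, tolerance = 1e-10)
    expect_equal(fit$R2[1], o$R2, tolerance = 1e-10)
    expect_equal(fit$SS[3], o$SS_total, tolerance = 1e-10)  # Total row
  }
})

test_that("perfectly separated groups explain all distance variance", {
  D <- matrix(1, 4, 4); D[1:2, 1:2] <- 0; D[3:4, 3:4] <- 0; diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("t", 1:4)
  md <- data.frame(sample_id = rownames(D), g = rep(c("a", "b"), each = 2))
  fit <- permanova(D, md, "g", exhaustive = TRUE)
  expect_equal(fit$R2[1], 1.0)
  expect_equal(fit$SS[fit$term == "Total"], 1.0)  # (1/4) * 4 between-pairs of d^2 = 1
  expect_equal(fit$SS[fit$term == "Residual"], 0.0, tolerance = 1e-12)
})

test_that("pairwise PERMANOVA applies Holm and collapses to one comparison for 2 levels", {
  set.seed(35)
  X <- rbind(matrix(rnorm(8), 4), matrix(rnorm(8, 2), 4), matrix(rnorm(8, 4), 4))
  D <- as.matrix(dist(X)); rownames(D) <- colnames(D) <- paste0("s", 1:12)
  md <- data.frame(sample_id = rownames(D), g = rep(c("a", "b", "c"), each = 4))
  pw <- pairwise_permanova(D, md, "g", n_perm = 99, seed = 3)
  expect_equal(nrow(pw), 3L)
  expect_true(all(pw$p_adj >= pw$p - 1e-12))
  expect_equal(pw$p_adj, holm_adjust(pw$p))
  md2 <- md[md$g != "c", ]
  pw2 <- pairwise_permanova(D[1:8, 1:8], md2, "g", n_perm = 99, seed = 3)
  expect_equal(nrow(pw2), 1L)
  expect_equal(pw2$p_adj, pw2$p)
})

test_that("dispersion distances match the centroid betadisper and identical pairs give zero", {
  set.seed(36)
  X <- matrix(rnorm(10 * 3), 10)
  D <- as.matrix(dist(X)); rownames(D) <- colnames(D) <- paste0("s", 1:10)
  g <- rep(c("a", "b"), each = 5)
  bd <- beta_dispersion(D, g, n_perm = 99, seed = 4)
  vb <- vegan::betadisper(stats::as.dist(D), g, type = "centroid")
  expect_equal(unname(bd$distances), unname(vb$distances), tolerance = 1e-8)
  expect_equal(bd$F, stats::anova(vb)[1, 4], tolerance = 1e-8)
  # two groups each made of identical samples: all centroid distances zero
  D0 <- matrix(1, 4, 4); D0[1:2, 1:2] <- 0; D0[3:4, 3:4] <- 0; diag(D0) <- 0
  bd0 <- beta_dispersion(D0, rep(c("a", "b"), each = 2), n_perm = 19, seed = 1)
  expect_equal(unname(bd0$distances), rep(0, 4))
  expect_true(all(bd$distances >= 0))
  expect_error(beta_dispersion(D, c(rep("a", 9), "b")), "at least 2 samples")
})

test_that("dispersion test is calibrated when groups are equally dispersed", {
  # mirror-symmetric coordinates: both groups share the same spread
  set.seed(37)
  ps <- replicate(40, {
    Y <- matrix(rnorm(12 * 2), 12)
    Y2 <- rbind(Y, -Y)  # group b is a mirror image of group a
    D <- as.matrix(dist(Y2))
    beta_dispersion(D, rep(c("a", "b"), each = 12), n_perm = 49,
                    seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.25)          # far from systematic rejection
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("alpha comparison selects tests from assumption checks", {
  set.seed(38)
  # clearly normal, equal variance, big shift: parametric branch
  r1 <- compare_alpha(list(rnorm(20), rnorm(20, 3)))
  expect_equal(r1$test, "t")
  expect_lt(r1$p, 0.01)
  # heavily skewed data: nonparametric branch
  r2 <- compare_alpha(list(rlnorm(20, 0, 2), rlnorm(20, 0.5, 2)))
  expect_equal(r2$test, "wilcoxon")
  # identical groups: rank-sum with mid-rank ties gives p = 1
  r3 <- compare_alpha(list(rep(1, 5), rep(1, 5)))
  expect_equal(r3$p, 1)
  expect_error(compare_alpha(list(1:2, 1:5)), "at least 3")
})

test_that("the parametric branch is chosen and powered under normal shifts", {
  set.seed(39)
  picks <- replicate(60, {
    r <- compare_alpha(list(rnorm(20), rnorm(20, 3)))
    c(r$test == "t", r$p < 0.01)
  })
  expect_gte(mean(picks[1, ]), 0.80)   # assumption checks false-alarm ~ alpha each
  expect_gte(mean(picks[2, ]), 0.95)
})

test_that("Holm adjustment follows the step-down arithmetic", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  p <- c(0.03, 0.001, 0.2, 0.04)
  a <- holm_adjust(p)
  expect_equal(order(a), order(p))     # monotone in the raw ranks
  expect_true(all(a >= p) && all(a <= 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
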