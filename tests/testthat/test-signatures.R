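test_that("summary t-test matches the closed-form pooled t and pt()", {
  r <- ttest_from_summary(10, 1, 3, 10, 1, 3)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r2 <- ttest_from_summary(10, 1, 3, 14, 1, 3)
  expect_equal(r2$t, pooled_t_oracle(10, 1, 3, 14, 1, 3))
  expect_equal(r2$t, -4 / sqrt(2 / 3), tolerance = 1e-12)  # -4.899
  expect_equal(r2$df, 4)
  expect_equal(r2$p, 2 * pt(-abs(r2$t), 4))

  expect_error(ttest_from_summary(1, 0, 1, 2, 1, 3), "at least 2 replicates")

  deg <- ttest_from_summary(1, 0, 3, 2, 0, 3)
  expect_equal(deg$p, 0)
  expect_equal(deg$flag, "degenerate")
})

test_that("summary t-test agrees with stats::t.test on raw replicates", {
  set.seed(22)
  for (i in 1:10) {
    a <- rnorm(4, 10, 2); b <- rnorm(5, 11, 2)
    ours <- ttest_from_summary(mean(a), sd(a), 4, mean(b), sd(b), 5)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("fold-changes: identity, reciprocity under group swap, sentinels", {
  x <- matrix(c(10, 11, 9, 5, 6, 4), 3,
              dimnames = list(NULL, c("a", "b")))
  id <- fold_changes(x, x)
  expect_equal(id$fold_change, c(1, 1))
  expect_equal(id$log2_fc, c(0, 0))
  expect_equal(id$p_value, c(1, 1))

  y <- x * matrix(c(2, 2, 2, 0.5, 0.5, 0.5), 3)
  fwd <- fold_changes(y, x)
  rev <- fold_changes(x, y)
  expect_equal(fwd$fold_change, 1 / rev$fold_change)
  expect_equal(fwd$p_value, rev$p_value)

  z <- x; z[, "a"] <- 0
  s <- fold_changes(z, x)
  expect_equal(s$fold_change[s$short_name == "a"], 1e-05)
  expect_match(s$flags[s$short_name == "a"], "undetected_treated")
  s2 <- fold_changes(x, z)
  expect_true(is.na(s2$fold_change[s2$short_name == "a"]))
  expect_match(s2$flags[s2$short_name == "a"], "undetected_control")
})

test_that("a simulated 2-fold change is recovered by the full pipeline", {
  est <- vapply(1:20, function(s) {
    d <- experiment_design(fold_change = c(m5C = 2.0), seed = 100 + s)
    ex <- simulate_experiment(d)
    tab <- intensity_table(ex$samples)
    fc <- fold_change_matrix(tab, "control")
    fc$fold_change[fc$short_name == "m5C"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 2) / 2, 0.05)
})

test_that("centroid clustering reproduces trivial geometry", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 0, 9))
  tr <- hierarchical_cluster(m, mean_center = FALSE)
  expect_equal(tr$height[1], 0)           # identical rows merge first, at 0
  expect_setequal(abs(tr$merge[1, ]), c(1, 2))

  m2 <- rbind(x = c(1, 2, 3, 5), y = -c(1, 2, 3, 5))
  tr2 <- hierarchical_cluster(m2, mean_center = FALSE)
  expect_equal(tr2$height[1], 2)          # r = -1 so d = 1 - r = 2

  const <- rbind(u = c(1, 1, 1, 1), v = c(1, 2, 3, 4))
  expect_error(hierarchical_cluster(const), "zero-variance item.*u")
})

test_that("merge order matches the exhaustive centroid-linkage oracle", {
  set.seed(33)
  for (i in 1:5) {
    n <- sample(4:5, 1)
    m <- matrix(rnorm(n * 6), n, dimnames = list(letters[1:n], NULL))
    tr <- hierarchical_cluster(m)
    oracle <- centroid_cluster_oracle(m)
    got <- tree_merge_sets(tr)
    for (k in seq_along(oracle$merges)) {
      expect_setequal(c(got[[k]]$left, got[[k]]$right),
                      c(oracle$merges[[k]]$left, oracle$merges[[k]]$right))
      expect_equal(tr$height[k], oracle$heights[k], tolerance = 1e-12)
    }
  }
})

test_that("clustering is permutation-equivariant", {
  set.seed(34)
  m <- matrix(rnorm(5 * 8), 5, dimnames = list(letters[1:5], NULL))
  t1 <- hierarchical_cluster(m)
  perm <- c(3, 5, 1, 2, 4)
  t2 <- hierarchical_cluster(m[perm, ])
  label_sets <- function(tree) {
    sets <- tree_merge_sets(tree)
    lapply(sets, function(s)
      sort(tree$labels[c(s$left, s$right)]))
  }
  expect_equal(label_sets(t1), label_sets(t2))
  expect_equal(t1$height, t2$height, tolerance = 1e-12)
})

test_that("PCA matches closed forms and prcomp cross-check", {
  # 2x2 correlation matrix has eigenvalues 1 +/- r
  set.seed(35)
  x <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("v1", "v2")))
  p <- pca_signature(x)
  r <- cor(x)[1, 2]
  expect_equal(sort(p$eigenvalues, decreasing = TRUE),
               sort(c(1 + r, 1 - r), decreasing = TRUE),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(p$variance_percent), 100)

  # independent route: prcomp on the standardized matrix
  y <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(NULL, paste0("v", 1:5)))
  p2 <- pca_signature(y)
  ref <- prcomp(y, center = TRUE, scale. = TRUE)
  expect_equal(unname(p2$eigenvalues), unname(ref$sdev^2), tolerance = 1e-9)
  for (j in 1:5)
    expect_equal(abs(unname(p2$scores[, j])), abs(unname(ref$x[, j])),
                 tolerance = 1e-9)

  # a single shared signal: P1 carries all the variance
  s <- rnorm(6)
  z <- cbind(v1 = s, v2 = 0.01 * s, v3 = -2 * s + 5)
  pz <- pca_signature(z)
  expect_equal(unname(pz$variance_percent[1]), 100, tolerance = 1e-9)

  expect_error(pca_signature(cbind(a = rnorm(4), b = rep(1, 4))),
               "zero-variance variable.*b")
})

test_that("PCA on independent noise spreads variance near-uniformly", {
  set.seed(36)
  x <- matrix(rnorm(4000 * 4), 4000, 4, dimnames = list(NULL, paste0("v", 1:4)))
  p <- pca_signature(x)
  expect_lt(max(p$variance_percent) - min(p$variance_percent), 5)
})

test_that("observation contributions follow the squared-score convention", {
  fake <- structure(list(scores = matrix(c(1, 2), 2, 1,
                                         dimnames = list(c("o1", "o2"), "P1"))),
                    class = "pca_result")
  contrib <- observation_contributions(fake)
  expect_equal(unname(contrib[, 1]), c(20, 80))

  set.seed(37)
  sc <- matrix(rnorm(12), 4, 3,
               dimnames = list(paste0("o", 1:4), paste0("P", 1:3)))
  fake2 <- structure(list(scores = sc), class = "pca_result")
  got <- observation_contributions(fake2)
  brute <- 100 * sc^2 / matrix(colSums(sc^2), 4, 3, byrow = TRUE)
  expect_equal(got, brute)
  expect_equal(unname(colSums(got)), rep(100, 3))

  one_group <- observation_contributions(fake2,
                                         grouping = rep("all", 4))
  expect_equal(unname(one_group[1, ]), rep(100, 3))

  zero <- structure(list(scores = matrix(0, 2, 1,
                                         dimnames = list(NULL, "P1"))),
                    class = "pca_result")
  expect_error(observation_contributions(zero), "all-zero scores")
})

test_that("profile correlations match textbook arithmetic and flag constants", {
  set.seed(38)
  x <- rnorm(5); y <- rnorm(5)
  m <- rbind(p1 = x, p2 = y, p3 = 2 * x)
  cm <- profile_correlation(m)
  expect_equal(diag(cm), c(p1 = 1, p2 = 1, p3 = 1))
  expect_equal(cm["p1", "p3"], 1)
  expect_equal(cm["p1", "p2"], pearson_oracle(x, y), tolerance = 1e-12)
  expect_equal(cm, t(cm))
  expect_true(all(cm >= -1 & cm <= 1))

  mc <- rbind(flat = rep(2, 5), p2 = y)
  cmc <- profile_correlation(mc)
  expect_equal(attr(cmc, "undefined"), "flat")
  expect_true(is.na(cmc["flat", "p2"]))
  expect_equal(cmc["flat", "flat"], 1)
})
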