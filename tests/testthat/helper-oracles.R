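# Independent oracles used across tests. Each is deliberately written as a
# naive, from-scratch computation so it shares no code path with the package.

# expected trapezoidal integral of a Gaussian peak sampled on a grid,
# from the closed-form CDF (truncation error only)
gaussian_area_oracle <- function(area, mu, sigma, grid) {
  area * (pnorm(max(grid), mu, sigma) - pnorm(min(grid), mu, sigma))
}

# naive trapezoid rule
trapz_oracle <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# textbook Pearson coefficient: cov / (sd * sd), all from first principles
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# pooled-variance two-sample t from the closed-form normal equations
pooled_t_oracle <- function(m1, s1, n1, m2, s2, n2) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# OLS slope/intercept by explicit sums
ols_oracle <- function(x, y) {
  n <- length(x)
  sl <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  list(slope = sl, intercept = mean(y) - sl * mean(x))
}

# exhaustive centroid-linkage agglomeration with d = 1 - Pearson, keeping
# explicit member lists and recomputing every centroid from scratch at each
# step; returns the sequence of merged label sets and heights
centroid_cluster_oracle <- function(x, mean_center = TRUE) {
  if (mean_center) x <- x - rowMeans(x)
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      ca <- colMeans(x[clusters[[a]], , drop = FALSE])
      cb <- colMeans(x[clusters[[b]], , drop = FALSE])
      d <- 1 - pearson_oracle(ca, cb)
      if (d < best_d) { best_d <- d; best <- c(a, b) }
    }
    merges[[length(merges) + 1L]] <-
      list(left = sort(clusters[[best[1]]]), right = sort(clusters[[best[2]]]))
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# member index sets at each merge of a cluster_tree, for comparison with the
# oracle above
tree_merge_sets <- function(tree) {
  n <- length(tree$labels)
  members <- function(k) {
    if (k < 0) return(-k)
    sort(c(members(tree$merge[k, 1]), members(tree$merge[k, 2])))
  }
  lapply(seq_len(n - 1), function(k)
    list(left = members(tree$merge[k, 1]), right = members(tree$merge[k, 2])))
}

# tiny noiseless simulation shared by several tests
noiseless_design <- function(fold_change = numeric(0), seed = 1,
                             n_replicates = 3) {
  experiment_design(fold_change = fold_change, n_replicates = n_replicates,
                    injection_cv = 0, biological_cv = 0, rt_jitter_sd = 0,
                    baseline_level = 0, baseline_noise_sd = 0, seed = seed)
}
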