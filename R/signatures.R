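#' Two-sample Student's t-test from summary statistics
#'
#' Classical unpaired, equal-variance (pooled) two-sided t-test computed from
#' per-group mean, SD and N — the form in which replicate tables are
#' published (mean +/- SD, N = 3).
#'
#' Degenerate inputs follow a stated convention: both SDs zero with equal
#' means gives t = 0, p = 1; both SDs zero with different means gives
#' p = 0 with a `degenerate` flag.
#'
#' @param mean1,sd1,n1 first group summary (n1 >= 2).
#' @param mean2,sd2,n2 second group summary (n2 >= 2).
#' @return List with `t`, `p`, `df`, `flag` (`""` or `"degenerate"`).
#' @examples
#' ttest_from_summary(10, 1, 3, 14, 1, 3)  # t = -4.899, df = 4
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2)
    stop("t-test needs at least 2 replicates per group (got n1=", n1,
         ", n2=", n2, ")")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (mean1 == mean2) return(list(t = 0, p = 1, df = df, flag = ""))
    return(list(t = sign(mean1 - mean2) * Inf, p = 0, df = df,
                flag = "degenerate"))
  }
  tval <- (mean1 - mean2) / se
  list(t = tval, p = 2 * stats::pt(-abs(tval), df), df = df, flag = "")
}

#' Fold-changes with per-analyte t-tests for one condition
#'
#' For each analyte, fold-change = mean(treated) / mean(control) of the
#' normalized intensities, with a two-sided pooled-variance Student's t-test
#' on the replicate values. Analytes undetected in the control (mean 0) get
#' `NA` fold-change with an `undetected_control` flag; analytes undetected in
#' the treated group but present in control get the sentinel ratio 0.00001
#' (the table convention for "undetectable").
#'
#' @param treated,control numeric matrices or data.frames, replicates x
#'   analytes, with matching analyte columns; >= 2 replicates each.
#' @param condition condition label attached to the result.
#' @return data.frame: `condition`, `short_name`, `fold_change`, `log2_fc`,
#'   `t_statistic`, `p_value`, `n_treated`, `n_control`, `flags`.
#' @export
fold_changes <- function(treated, control, condition = "treated") {
  treated <- as.matrix(treated)
  control <- as.matrix(control)
  if (!identical(colnames(treated), colnames(control)))
    stop("treated and control analyte columns must match")
  if (nrow(treated) < 2 || nrow(control) < 2)
    stop("condition '", condition,
         "' needs >= 2 replicates per group for a t-test")
  out <- lapply(colnames(treated), function(nm) {
    tv <- treated[, nm]
    cv <- control[, nm]
    mt <- mean(tv); mc <- mean(cv)
    flags <- ""
    if (mc == 0) {
      fc <- NA_real_
      flags <- "undetected_control"
    } else if (mt == 0) {
      fc <- 1e-05
      flags <- "undetected_treated"
    } else fc <- mt / mc
    tt <- ttest_from_summary(mt, stats::sd(tv), length(tv),
                             mc, stats::sd(cv), length(cv))
    data.frame(condition = condition, short_name = nm, fold_change = fc,
               log2_fc = ifelse(is.na(fc), NA_real_, log2(fc)),
               t_statistic = tt$t, p_value = tt$p,
               n_treated = length(tv), n_control = length(cv),
               flags = paste(c(tt$flag[tt$flag != ""], flags[flags != ""]),
                             collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Fold-change matrix over all exposure conditions in an intensity table
#'
#' Compares every non-control group in the table against the control group,
#' producing the conditions x analytes fold-change object that feeds
#' clustering and PCA.
#'
#' @param table an `intensity_table` with a `group` column.
#' @param control_group label of the unexposed control group.
#' @return A `fold_change_matrix`: long-format data.frame as in
#'   [fold_changes()], with attribute `wide` (conditions x analytes
#'   fold-change matrix) and `p_wide` (matching p-value matrix).
#' @export
fold_change_matrix <- function(table, control_group = "control") {
  cols <- intensity_columns(table)
  if (!control_group %in% table$group)
    stop("control group '", control_group, "' not present in table")
  ctrl <- as.matrix(table[table$group == control_group, cols, drop = FALSE])
  conditions <- setdiff(unique(table$group), control_group)
  long <- do.call(rbind, lapply(conditions, function(g) {
    fold_changes(as.matrix(table[table$group == g, cols, drop = FALSE]),
                 ctrl, condition = g)
  }))
  wide <- matrix(long$fold_change, nrow = length(conditions), byrow = TRUE,
                 dimnames = list(conditions, cols))
  p_wide <- matrix(long$p_value, nrow = length(conditions), byrow = TRUE,
                   dimnames = list(conditions, cols))
  structure(long, wide = wide, p_wide = p_wide,
            class = c("fold_change_matrix", "data.frame"))
}

#' Fraction of condition x analyte cells significant at a p threshold
#'
#' @param fc a `fold_change_matrix` (or any data.frame with `p_value`).
#' @param alpha significance threshold (default 0.05).
#' @return Percentage (0-100) of cells with `p_value < alpha`.
#' @export
significant_fraction <- function(fc, alpha = 0.05) {
  p <- fc$p_value
  100 * mean(p < alpha, na.rm = TRUE)
}

# centered Pearson distance between rows of a matrix: d = 1 - r
pearson_distance <- function(x, y) 1 - stats::cor(x, y)

#' Agglomerative hierarchical clustering with centroid linkage on Pearson
#' distance
#'
#' Clusters the rows (or columns) of a matrix with the distance
#' `d = 1 - r` (centered Pearson correlation) and centroid linkage: after
#' each merge the new cluster is represented by the coordinate-wise mean of
#' its members, and distances to all other clusters are recomputed against
#' that centroid. This is the scheme used by classical gene-expression
#' clustering programs; note centroid linkage can produce height inversions,
#' which are preserved, not repaired.
#'
#' Input is expected to be the log2 fold-change matrix; rows are mean-centered
#' internally before clustering (the Pearson distance is invariant to that
#' centering, but the exported centroids are the centered ones).
#'
#' @param mat numeric matrix with row and column names.
#' @param axis `"rows"` (default) or `"cols"`.
#' @param mean_center mean-center each item before clustering (default TRUE).
#' @return A `cluster_tree`: list with `merge` (hclust-style merge matrix:
#'   negative entries are singleton items, positive are earlier merges),
#'   `height` (1 - centroid correlation at each merge), `labels`, `order`
#'   (leaf order for display), `metric = "pearson_centered"`,
#'   `linkage = "centroid"`.
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "cols"),
                                 mean_center = TRUE) {
  axis <- match.arg(axis)
  x <- as.matrix(mat)
  if (axis == "cols") x <- t(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 items to cluster")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance item(s): ", paste(rownames(x)[sds == 0], collapse = ", "),
         " (Pearson correlation undefined)")
  if (mean_center) x <- x - rowMeans(x)

  labels <- rownames(x)
  centroids <- lapply(seq_len(n), function(i) x[i, ])
  ids <- -(seq_len(n))          # hclust convention: negative = singleton
  active <- seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    # full recomputation of centroid-to-centroid distances each step
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        d <- pearson_distance(centroids[[active[a]]], centroids[[active[b]]])
        if (d < best_d) { best_d <- d; best <- c(active[a], active[b]) }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- best_d
    size_i <- attr(centroids[[i]], "size") %||% 1
    size_j <- attr(centroids[[j]], "size") %||% 1
    merged <- (centroids[[i]] * size_i + centroids[[j]] * size_j) /
      (size_i + size_j)
    attr(merged, "size") <- size_i + size_j
    centroids[[i]] <- merged
    ids[i] <- step
    active <- setdiff(active, j)
  }

  order <- tree_leaf_order(merge, n)
  structure(list(merge = merge, height = height, labels = labels,
                 order = order, metric = "pearson_centered",
                 linkage = "centroid", axis = axis),
            class = "cluster_tree")
}

# depth-first leaf order from an hclust-style merge matrix
tree_leaf_order <- function(merge, n) {
  leaves <- function(k) {
    if (k < 0) return(-k)
    c(leaves(merge[k, 1]), leaves(merge[k, 2]))
  }
  leaves(n - 1L)
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree (%s linkage, %s distance): %d leaves, %d merges\n",
              x$linkage, x$metric, length(x$labels), nrow(x$merge)))
  invisible(x)
}

#' Convert a cluster_tree to an hclust object
#'
#' Centroid linkage can invert heights, which `plot.hclust` dislikes but
#' tolerates; the conversion is faithful, not repaired.
#' @param tree a `cluster_tree`.
#' @return An object of class `hclust`.
#' @export
as_hclust <- function(tree) {
  structure(list(merge = tree$merge, height = tree$height,
                 order = tree$order, labels = tree$labels,
                 method = tree$linkage, dist.method = tree$metric),
            class = "hclust")
}

#' Principal component analysis of a correlation matrix
#'
#' Mean-centers and scales each variable to unit standard deviation, then
#' eigendecomposes the Pearson correlation matrix of the variables.
#' Component scores are the projections of the standardized observations on
#' the eigenvectors; the variance share of each component is its eigenvalue
#' as a percentage of the eigenvalue total. The number of retained
#' components is `min(observations - 1, variables)`. Sign convention: the
#' largest-magnitude loading of every component is made positive.
#'
#' @param mat numeric matrix, observations x variables (e.g. the linear
#'   fold-change matrix, conditions x modifications).
#' @return A `pca_result`: list with `scores`, `loadings`, `eigenvalues`,
#'   `variance_percent`, `n_obs`, `n_var`.
#' @export
pca_signature <- function(mat) {
  x <- as.matrix(mat)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("PCA needs >= 2 observations and >= 2 variables")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  xs <- scale(x, center = TRUE, scale = TRUE)
  r <- stats::cor(x)
  eg <- eigen(r, symmetric = TRUE)
  k <- min(nrow(x) - 1L, ncol(x))
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    m <- which.max(abs(vecs[, j]))
    if (vecs[m, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- xs %*% vecs
  comp <- paste0("P", seq_len(k))
  dimnames(scores) <- list(rownames(x), comp)
  dimnames(vecs) <- list(colnames(x), comp)
  structure(list(scores = scores, loadings = vecs,
                 eigenvalues = stats::setNames(vals[seq_len(k)], comp),
                 variance_percent = stats::setNames(
                   100 * vals[seq_len(k)] / sum(vals), comp),
                 n_obs = nrow(x), n_var = ncol(x)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d obs x %d var, %d components\n",
              x$n_obs, x$n_var, length(x$eigenvalues)))
  vp <- round(x$variance_percent, 1)
  cat("  variance %:", paste(names(vp), vp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Observation (and group) contributions to each principal component
#'
#' The contribution of observation i to component k is
#' `100 * score(i,k)^2 / sum_j score(j,k)^2`. With a grouping (e.g. the
#' three doses of one toxicant), group contributions are the sums over
#' members, giving the share of each component's variance attributable to
#' each agent.
#'
#' @param pca a `pca_result`.
#' @param grouping optional character/factor vector over observations (or a
#'   named vector keyed by observation name).
#' @return Matrix of contribution percentages (observations or groups x
#'   components); columns sum to 100.
#' @export
observation_contributions <- function(pca, grouping = NULL) {
  s2 <- pca$scores^2
  tot <- colSums(s2)
  if (any(tot == 0))
    stop("component(s) with all-zero scores: contribution undefined: ",
         paste(colnames(s2)[tot == 0], collapse = ", "))
  contrib <- sweep(s2, 2, tot, "/") * 100
  if (is.null(grouping)) return(contrib)
  if (!is.null(names(grouping)))
    grouping <- grouping[rownames(contrib)]
  if (length(grouping) != nrow(contrib))
    stop("grouping must cover every observation")
  rowsum(contrib, group = as.character(grouping))
}

#' Pairwise Pearson correlation between profiles
#'
#' Correlates every pair of row profiles (e.g. each mutant's vector of
#' modification fold-changes) with pairwise-complete observations. Constant
#' profiles yield undefined coefficients, which are flagged rather than
#' zeroed; the diagonal is 1 by definition.
#'
#' @param mat numeric matrix, profiles x values (>= 3 values per profile).
#' @return A `correlation_matrix`: symmetric matrix of Pearson coefficients
#'   with unit diagonal; attribute `undefined` lists flagged profile names.
#' @export
profile_correlation <- function(mat) {
  x <- as.matrix(mat)
  if (nrow(x) < 2) stop("need >= 2 profiles")
  if (ncol(x) < 3) stop("profiles need >= 3 values")
  sds <- apply(x, 1, stats::sd, na.rm = TRUE)
  undef <- rownames(x)[!is.na(sds) & sds == 0]
  cm <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  diag(cm) <- 1
  structure(cm, undefined = undef, class = c("correlation_matrix", "matrix"))
}
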