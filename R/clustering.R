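#' Spearman-rank correlation distance matrix
#'
#' Distance between two items is `1 - rho`, with Spearman's rho computed
#' on mid-ranks (ties averaged), giving distances in `[0, 2]`. Items with
#' constant values have no defined rank correlation and are excluded,
#' with their ids recorded in the `"excluded"` attribute.
#'
#' @param x numeric matrix; items are rows by default.
#' @param axis cluster `"rows"` (features) or `"cols"` (samples).
#' @return symmetric distance matrix of class `dist_matrix` with zero
#'   diagonal.
#' @export
spearman_distance <- function(x, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  m <- if (axis == "rows") t(as.matrix(x)) else as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 items")
  if (nrow(m) < 3) stop("need at least 3 observations per item")
  const <- apply(m, 2, function(v) stats::var(v) == 0)
  excluded <- colnames(m)[const]
  if (any(const)) {
    warning("excluding ", sum(const),
            " constant item(s) with undefined rank correlation")
    m <- m[, !const, drop = FALSE]
    if (ncol(m) < 2) stop("fewer than 2 non-constant items remain")
  }
  d <- 1 - stats::cor(m, method = "spearman")
  diag(d) <- 0
  attr(d, "excluded") <- excluded
  attr(d, "metric") <- "1 - spearman"
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates the closest pair at each step, with inter-cluster
#' distance the unweighted mean of all cross-pair distances (UPGMA), via
#' [stats::hclust()] with `method = "average"`.
#'
#' @param d a distance matrix from [spearman_distance()] (or any
#'   symmetric distance matrix / `dist` object).
#' @return an [stats::hclust] dendrogram.
#' @export
average_linkage <- function(d) {
  if (inherits(d, "dist_matrix") || is.matrix(d)) {
    if (nrow(as.matrix(d)) < 2) stop("need at least 2 items")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram at a correlation threshold
#'
#' With correlation distance `d = 1 - r`, a correlation threshold `r`
#' corresponds to cutting the tree at height `h = 1 - r`: connected
#' sub-trees whose merges all lie at or below `h` become clusters (items
#' joined at correlation >= r cluster together).
#'
#' @param hc an [stats::hclust] tree (heights in correlation-distance
#'   units).
#' @param r_threshold correlation threshold in `[-1, 1]`.
#' @return named integer vector of cluster ids (a partition of the
#'   leaves), with attribute `r_threshold`.
#' @export
cut_tree_at_correlation <- function(hc, r_threshold) {
  if (!is.numeric(r_threshold) || r_threshold < -1 || r_threshold > 1)
    stop("r_threshold must lie in [-1, 1]")
  cl <- stats::cutree(hc, h = 1 - r_threshold)
  attr(cl, "r_threshold") <- r_threshold
  cl
}

#' Smallest correlation threshold yielding a requested cluster count
#'
#' Searches the merge heights for the smallest `r_threshold` at which
#' [cut_tree_at_correlation()] returns exactly `k` clusters (i.e. the
#' cut sits at the height of the `(n-k)`-th merge). Errors if `k`
#' clusters are unattainable (tied merge heights can skip counts).
#'
#' @param hc an [stats::hclust] tree.
#' @param k requested number of clusters.
#' @return the correlation threshold.
#' @export
threshold_for_clusters <- function(hc, k) {
  n <- length(hc$order)
  if (k < 1 || k > n) stop("k must be between 1 and the number of leaves")
  if (k == n) return(1)
  r <- 1 - hc$height[n - k]
  cl <- cut_tree_at_correlation(hc, r)
  if (max(cl) != k)
    stop("no threshold yields exactly ", k, " clusters (tied merge heights)")
  r
}

#' Leaf order of a dendrogram for heatmap export
#'
#' @param hc an [stats::hclust] tree.
#' @return character vector of leaf labels in dendrogram order.
#' @export
leaf_order <- function(hc) hc$labels[hc$order]
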