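#' Davies-Bouldin index of a clustering
#'
#' `DB = (1/k) * sum_i max_{j != i} (S_i + S_j) / M_ij`, where `S_i` is the
#' mean Euclidean distance of cluster-i points to their centroid and `M_ij`
#' the Euclidean distance between centroids i and j. Lower values indicate
#' tighter, better-separated clusters. Computed in whatever space the labels
#' were derived in; the component-selection stage evaluates it on the
#' robust-scaled feature matrix.
#'
#' @param scaled Numeric matrix (rows = points).
#' @param labels Cluster labels (any atomic type; at least 2 non-empty
#'   clusters).
#' @return Non-negative scalar.
#' @examples
#' x <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
#' davies_bouldin(x, c(1, 1, 2, 2)) # 0.2
#' @export
davies_bouldin <- function(scaled, labels) {
  x <- as_feature_matrix(scaled, "scaled")
  labels <- as.vector(labels)
  if (length(labels) != nrow(x)) abort("`labels` length must match rows of `scaled`.")
  lv <- unique(labels)
  k <- length(lv)
  if (k < 2L) abort("Need at least 2 non-empty clusters.")
  centroids <- matrix(0, k, ncol(x))
  scatter <- numeric(k)
  for (i in seq_len(k)) {
    pts <- x[labels == lv[i], , drop = FALSE]
    centroids[i, ] <- colMeans(pts)
    scatter[i] <- mean(sqrt(rowSums(sweep(pts, 2L, centroids[i, ])^2)))
  }
  M <- as.matrix(dist(centroids))
  if (any(M[upper.tri(M)] == 0)) abort("Degenerate centroids: two clusters share a centroid.")
  ratio <- outer(scatter, scatter, "+") / M
  diag(ratio) <- -Inf
  mean(apply(ratio, 1L, max))
}
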