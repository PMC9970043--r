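# Isolation forest for patient-level outlier flagging.
#
# Standard construction: each tree is grown on a random subsample of size
# psi = min(256, n); splits pick a random feature with positive range and a
# uniform split point; growth stops at singleton nodes or depth
# ceiling(log2(psi)). The anomaly score of a point is
# 2^(-E[h(x)] / c(psi)) where h is the path length (external nodes of size m
# are credited the average unsuccessful-search depth c(m)).

harmonic <- function(x) log(x) + 0.5772156649015329

# average path length of an unsuccessful BST search among m points
avg_path_length <- function(m) {
  ifelse(m <= 1, 0, 2 * harmonic(m - 1) - 2 * (m - 1) / m)
}

grow_itree <- function(x, depth_limit) {
  build <- function(idx, depth) {
    n <- length(idx)
    if (n <= 1L || depth >= depth_limit) {
      return(list(size = n))
    }
    ranges <- apply(x[idx, , drop = FALSE], 2L, range)
    usable <- which(ranges[2L, ] > ranges[1L, ])
    if (length(usable) == 0L) {
      return(list(size = n))
    }
    j <- usable[sample.int(length(usable), 1L)]
    split <- runif(1L, ranges[1L, j], ranges[2L, j])
    left <- idx[x[idx, j] < split]
    right <- setdiff(idx, left)
    if (length(left) == 0L || length(right) == 0L) {
      return(list(size = n))
    }
    list(
      feature = j, split = split,
      left = build(left, depth + 1L),
      right = build(right, depth + 1L)
    )
  }
  build(seq_len(nrow(x)), 0L)
}

# path lengths of all rows of `x` through one tree, by recursive partition
itree_depths <- function(tree, x) {
  out <- numeric(nrow(x))
  descend <- function(node, idx, depth) {
    if (length(idx) == 0L) return(invisible())
    if (is.null(node$feature)) {
      out[idx] <<- depth + avg_path_length(node$size)
      return(invisible())
    }
    go_left <- x[idx, node$feature] < node$split
    descend(node$left, idx[go_left], depth + 1L)
    descend(node$right, idx[!go_left], depth + 1L)
  }
  descend(tree, seq_len(nrow(x)), 0)
  out
}

#' Isolation-forest anomaly scores
#'
#' Fits an isolation forest on a complete numeric matrix and returns the
#' anomaly score of every row (higher = more isolated, in (0, 1)).
#'
#' @param x Numeric matrix or data frame, no missing values.
#' @param n_trees Number of isolation trees.
#' @param subsample Subsample size per tree (capped at `nrow(x)`).
#' @param seed Integer seed; scores are deterministic given the seed.
#' @return Numeric vector of anomaly scores, one per row.
#' @export
isolation_scores <- function(x, n_trees = 100L, subsample = 256L, seed = 1L) {
  x <- as_feature_matrix(x, "x")
  if (anyNA(x)) abort("`x` must not contain missing values.")
  n <- nrow(x)
  psi <- min(as.integer(subsample), n)
  with_seed_offset(seed, 0L, {
    depths <- matrix(0, n, n_trees)
    for (b in seq_len(n_trees)) {
      idx <- sample.int(n, psi)
      tree <- grow_itree(x[idx, , drop = FALSE], ceiling(log2(max(psi, 2L))))
      depths[, b] <- itree_depths(tree, x)
    }
  })
  denom <- avg_path_length(psi)
  if (denom <= 0) denom <- 1
  2^(-rowMeans(depths) / denom)
}

#' Flag outlying patients
#'
#' Scores each complete-case row with an isolation forest and flags the
#' `ceiling(contamination * n)` most anomalous rows. Used by [curate()] on
#' the complete-case rows of the eligible features; flagged rows are kept in
#' the curated output but excluded from downstream model fitting.
#'
#' @param data Complete numeric data frame or matrix (rows = patients).
#' @param contamination Expected outlier fraction, in (0, 0.5).
#' @param seed Integer seed.
#' @param n_trees Number of isolation trees.
#' @return Logical vector, `TRUE` for flagged rows.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(100), 50), c(40, 40))
#' which(detect_outliers(x, contamination = 0.02))
#' @export
detect_outliers <- function(data, contamination = 0.05, seed = 1L, n_trees = 100L) {
  x <- as_feature_matrix(data, "data")
  if (!is.numeric(contamination) || contamination <= 0 || contamination >= 0.5) {
    abort("`contamination` must lie in (0, 0.5).")
  }
  n <- nrow(x)
  if (n < 10L) abort("Outlier detection needs at least 10 complete rows.")
  scores <- isolation_scores(x, n_trees = n_trees, seed = seed)
  n_flag <- min(ceiling(contamination * n), n - 1L)
  # ties broken by row order for determinism
  cut <- order(-scores, seq_len(n))[seq_len(n_flag)]
  flags <- logical(n)
  flags[cut] <- TRUE
  flags
}
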