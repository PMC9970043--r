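# Spectral embedding: Gaussian-kernel affinity with median-heuristic
# bandwidth, symmetrized m-nearest-neighbour sparsification, symmetric
# normalized Laplacian, smallest-k eigenvectors via LOBPCG (dense
# eigendecomposition on small problems or on solver failure).

# Sparse symmetric affinity matrix from a scaled data matrix: Gaussian
# kernel on Euclidean distances, symmetrized m-nearest-neighbour graph.
affinity_graph <- function(scaled, n_neighbors = NULL, bandwidth = NULL) {
  n <- nrow(scaled)
  dm <- as.matrix(dist(scaled))
  if (is.null(bandwidth)) {
    off <- dm[upper.tri(dm)]
    bandwidth <- median(off)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  m <- n_neighbors %||% max(10L, ceiling(log2(n)))
  m <- min(as.integer(m), n - 1L)
  nb <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ])
    ord <- ord[ord != i]
    nb[i, ] <- ord[seq_len(m)]
  }
  ii <- rep(seq_len(n), times = m)
  jj <- as.vector(nb)
  # union symmetrization on the undirected edge set
  key <- (pmin(ii, jj) - 1) * n + pmax(ii, jj)
  u <- !duplicated(key)
  i1 <- pmin(ii, jj)[u]
  j1 <- pmax(ii, jj)[u]
  v <- exp(-dm[cbind(i1, j1)]^2 / (2 * bandwidth^2))
  Matrix::sparseMatrix(i = c(i1, j1), j = c(j1, i1), x = c(v, v), dims = c(n, n))
}

# Symmetric normalized Laplacian L = I - D^(-1/2) W D^(-1/2).
normalized_laplacian <- function(w) {
  deg <- Matrix::rowSums(w)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  n <- nrow(w)
  Dinv <- Matrix::Diagonal(n, dinv)
  Matrix::Diagonal(n, 1) - Dinv %*% w %*% Dinv
}

#' Spectral embedding of a scaled cohort
#'
#' Builds a Gaussian-kernel affinity graph on pairwise Euclidean distances
#' (bandwidth = median pairwise distance, symmetrized m-nearest-neighbour
#' sparsification with `m = max(10, ceiling(log2(n)))`), forms the symmetric
#' normalized Laplacian, and extracts the `k` eigenvectors of smallest
#' eigenvalue with the [lobpcg()] solver. Rows of the eigenvector matrix are
#' L2-normalized. Small problems (`n < max(40, 8k)`) and solver
#' non-convergence fall back to a dense eigendecomposition (with a warning
#' in the latter case).
#'
#' @param scaled Numeric matrix, already robust-scaled.
#' @param k Number of embedding dimensions, `2 <= k < n`.
#' @param n_neighbors,bandwidth Affinity-graph overrides (`NULL` = defaults).
#' @param tol,max_iter LOBPCG controls.
#' @param seed Seed for the solver's random start block.
#' @return List of class `spectral_embedding`: `embedding` (n-by-k,
#'   row-normalized), `values` (k smallest Laplacian eigenvalues), `solver`
#'   (`"lobpcg"` or `"dense"`), `converged`.
#' @export
spectral_embed <- function(scaled, k, n_neighbors = NULL, bandwidth = NULL,
                           tol = 1e-8, max_iter = 2000L, seed = 1L) {
  scaled <- as_feature_matrix(scaled, "scaled")
  n <- nrow(scaled)
  k <- check_scalar_int(k, "k", min = 2L)
  if (k >= n) abort("`k` must satisfy 2 <= k < n.")
  w <- affinity_graph(scaled, n_neighbors, bandwidth)
  L <- normalized_laplacian(w)
  embed_laplacian(L, k, tol = tol, max_iter = max_iter, seed = seed)
}

# eigenvector embedding from a precomputed normalized Laplacian (shared by
# spectral_embed and the per-k loop of select_components)
embed_laplacian <- function(L, k, tol = 1e-8, max_iter = 2000L, seed = 1L) {
  n <- nrow(L)
  solver <- "lobpcg"
  converged <- TRUE
  if (n < max(40L, 8L * k)) {
    e <- eigen(as.matrix(L), symmetric = TRUE)
    vals <- rev(e$values)[seq_len(k)]
    vecs <- e$vectors[, rev(seq_len(n))[seq_len(k)], drop = FALSE]
    solver <- "dense"
  } else {
    res <- lobpcg(L, k, tol = tol, max_iter = max_iter,
                  precond = pmax(Matrix::diag(L), 1e-8), seed = seed)
    if (!res$converged) {
      warn("LOBPCG did not converge; falling back to dense eigendecomposition.")
      e <- eigen(as.matrix(L), symmetric = TRUE)
      vals <- rev(e$values)[seq_len(k)]
      vecs <- e$vectors[, rev(seq_len(n))[seq_len(k)], drop = FALSE]
      solver <- "dense"
      converged <- FALSE
    } else {
      vals <- res$values
      vecs <- res$vectors
    }
  }
  rn <- sqrt(rowSums(vecs^2))
  emb <- vecs / ifelse(rn > 0, rn, 1)
  structure(
    list(embedding = emb, values = vals, solver = solver, converged = converged),
    class = "spectral_embedding"
  )
}

# Greedy k-means++ seeding (several candidates per step, keep the one that
# minimizes the resulting potential).
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  n_cand <- 2L + as.integer(floor(log(k)))
  centers <- matrix(NA_real_, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  d2 <- cross_dist2(x, centers[1L, , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L) + 1L) {
    probs <- pmax(d2, 0)
    if (sum(probs) <= 0) {
      cand <- sample.int(n, n_cand, replace = TRUE)
    } else {
      cand <- sample.int(n, n_cand, replace = TRUE, prob = probs)
    }
    best_pot <- Inf
    best <- cand[1L]
    for (c_i in cand) {
      pot <- sum(pmin(d2, cross_dist2(x, x[c_i, , drop = FALSE])[, 1L]))
      if (pot < best_pot) {
        best_pot <- pot
        best <- c_i
      }
    }
    centers[j, ] <- x[best, ]
    d2 <- pmin(d2, cross_dist2(x, centers[j, , drop = FALSE])[, 1L])
  }
  centers
}

#' Cluster a spectral embedding with k-means
#'
#' Runs k-means with greedy k-means++ seeding and multiple restarts on the
#' rows of an embedding; the best restart by total within-cluster sum of
#' squares wins. Restarts that produce an empty cluster are retried with a
#' fresh seeding. Deterministic for a fixed seed.
#'
#' @param embedding n-by-k numeric matrix (or a `spectral_embedding`).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_start Number of restarts (at least 10 by default).
#' @return Integer vector of cluster labels in `1..k`.
#' @export
cluster_embedding <- function(embedding, k, seed = 1L, n_start = 10L) {
  if (inherits(embedding, "spectral_embedding")) embedding <- embedding$embedding
  x <- as_feature_matrix(embedding, "embedding")
  if (!all(is.finite(x))) abort("`embedding` must be finite.")
  k <- check_scalar_int(k, "k")
  if (k > nrow(x)) abort("`k` cannot exceed the number of rows.")
  with_seed_offset(seed, 23L, {
    best <- NULL
    attempts <- 0L
    done <- 0L
    while (done < n_start && attempts < 5L * n_start) {
      attempts <- attempts + 1L
      centers <- kmeanspp_init(x, k)
      km <- tryCatch(
        suppressWarnings(kmeans(x, centers = centers, iter.max = 100L)),
        error = function(e) NULL
      )
      if (is.null(km) || length(unique(km$cluster)) < k) next # empty cluster
      done <- done + 1L
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) abort("k-means failed to produce k non-empty clusters.")
    as.integer(best$cluster)
  })
}
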