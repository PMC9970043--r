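test_that("disconnected cliques give repeated zero eigenvalues and a block embedding", {
  set.seed(4)
  a <- matrix(rnorm(60, sd = 0.05), 30, 2)
  b <- matrix(rnorm(60, sd = 0.05), 30, 2) + 50
  emb <- spectral_embed(rbind(a, b), k = 2, seed = 4)
  expect_lt(max(abs(emb$values)), 1e-8) # two connected components
  grp <- rep(1:2, each = 30)
  for (g in 1:2) {
    rows <- emb$embedding[grp == g, ]
    expect_lt(max(stats::dist(rows)), 1e-6) # constant within a clique
  }
  expect_gt(sqrt(sum((emb$embedding[1, ] - emb$embedding[31, ])^2)), 0.5)
})

test_that("LOBPCG matches the dense eigendecomposition on the same Laplacian", {
  set.seed(15)
  x <- matrix(rnorm(400), 200, 2)
  W <- virtualcohort:::affinity_graph(x)
  L <- virtualcohort:::normalized_laplacian(W)
  res <- lobpcg(L, 4, seed = 15)
  expect_true(res$converged)
  ed <- eigen(as.matrix(L), symmetric = TRUE)
  dense_vals <- rev(ed$values)[1:4]
  expect_lt(max(abs(res$values - dense_vals)), 1e-6)
  dense_vecs <- ed$vectors[, seq(200, 197)]
  angles <- acos(pmin(1, svd(crossprod(res$vectors, dense_vecs))$d))
  expect_lt(max(angles), 1e-5)
})

test_that("embedding dimension must satisfy 2 <= k < n", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(spectral_embed(x, k = 20), "k")
  expect_error(spectral_embed(x, k = 1), "k")
})

test_that("k-means on the embedding recovers separated groups up to permutation", {
  blobs <- make_blobs(120, list(c(0, 0), c(10, 0), c(0, 10)), sd = 0.1, seed = 6)
  truth <- attr(blobs, "components")
  x <- as.matrix(blobs)
  sc <- fit_robust_scaler(x)
  emb <- spectral_embed(scale_transform(sc, x), k = 3, seed = 6)
  labels <- cluster_embedding(emb, 3, seed = 6)
  expect_equal(perm_agreement(labels, truth), 1)
  expect_identical(labels, cluster_embedding(emb, 3, seed = 6))
  # labels constant within each separated group
  for (g in 1:3) expect_equal(length(unique(labels[truth == g])), 1L)
})
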