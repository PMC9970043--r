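test_that("priors encode the weight-concentration rules", {
  x <- matrix(rnorm(100), 50, 2)
  expect_equal(bgmm_priors(x, 10)$gamma, exp(-10))
  expect_equal(bgmm_priors(x, 10, "inverse")$gamma, 0.1)
  p1 <- bgmm_priors(x, 1)
  expect_equal(p1$T, 1L)
  expect_equal(p1$gamma, exp(-1))
  expect_error(bgmm_priors(x, 0), "opt")
  # Wishart scale: prior expected precision matches per-feature precision
  expect_equal(diag(p1$nu0 * p1$W0), 1 / apply(x, 2, var), tolerance = 1e-12)
})

test_that("single-component posterior collapses to the conjugate limit", {
  x <- sample_mixture(1, list(c(2, -1, 3)), list(diag(3)), n = 400, seed = 11)
  fit <- fit_bgmm(x, opt = 1, seed = 11)
  X <- scale_transform(fit$scaler, as.matrix(x))
  expect_lt(max(abs(fit$means[1, ] - colMeans(X))), 1e-8)
  prec <- fit$nu[1] * fit$W[[1]]
  rel <- abs(prec - solve(cov(X))) / max(abs(solve(cov(X))))
  expect_lt(max(rel), 0.05) # nu*W approximates the inverse sample covariance
  expect_equal(fit$weights, 1)
})

test_that("one responsibility step matches the element-wise oracle", {
  set.seed(19)
  x <- matrix(rnorm(120), 40, 3)
  priors <- bgmm_priors(x, 3)
  r0 <- virtualcohort:::vb_init_resp(x, 3L, seed = 19, init = "kmeans")
  post <- virtualcohort:::vb_mstep(virtualcohort:::vb_stats(x, r0), priors)
  r_pkg <- virtualcohort:::vb_estep(x, post, priors)
  r_ora <- estep_oracle(x, post, priors)
  expect_lt(max(abs(r_pkg - r_ora)), 1e-10)
  expect_lt(max(abs(rowSums(r_pkg) - 1)), 1e-9)
})

test_that("two separated blobs are recovered with near-hard assignments", {
  x <- sample_mixture(c(.5, .5), list(c(-5, 0), c(5, 0)),
                      list(diag(2), diag(2)), n = 1000, seed = 21)
  truth <- attr(x, "components")
  fit <- fit_bgmm(x, opt = 2, seed = 21)
  expect_equal(fit$priors$gamma, exp(-2))
  m_orig <- t(apply(fit$means, 1, function(m) {
    fit$scaler$center + fit$scaler$scale * m
  }))
  ord <- order(m_orig[, 1])
  expect_lt(max(abs(m_orig[ord, ] - rbind(c(-5, 0), c(5, 0)))), 0.15)
  expect_gt(mean(apply(fit$responsibilities, 1, max) >= 0.999), 0.999)
  # assignment agreement with the ground truth, up to label swap
  hard <- apply(fit$responsibilities, 1, which.max)
  expect_gte(perm_agreement(hard, truth), 0.999)
})

test_that("the ELBO is non-decreasing across a randomized battery", {
  set.seed(77)
  for (s in 1:12) {
    n <- sample(50:120, 1)
    d <- sample(2:3, 1)
    T_ <- sample(1:4, 1)
    x <- matrix(rnorm(n * d, sd = runif(1, 0.5, 3)), n, d) + rnorm(1, 0, 4)
    fit <- fit_bgmm(as.data.frame(x), opt = T_, seed = s, max_iter = 80)
    expect_true(all(diff(fit$elbo_trace) > -1e-8))
    expect_lt(max(abs(rowSums(fit$responsibilities) - 1)), 1e-9)
    expect_true(all(fit$weights >= 0))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  }
})

test_that("surplus components shrink away under the exponential concentration", {
  x <- sample_mixture(rep(1 / 3, 3),
                      list(c(-8, 0), c(0, 8), c(8, 0)),
                      list(diag(2), diag(2), diag(2)), n = 900, seed = 31)
  fit <- fit_bgmm(x, opt = 6, seed = 31) # gamma = exp(-6)
  expect_lte(sum(fit$weights > 0.01), 4) # true clusters + at most 1
})

test_that("sampling respects size, determinism and the scaler round trip", {
  x <- sample_mixture(1, list(c(40, 7)), list(diag(c(4, 1))), n = 300, seed = 9)
  fit <- fit_bgmm(x, opt = 1, seed = 9)

  empty <- generate_cohort(fit, 0, seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty), fit$features)

  big <- generate_cohort(fit, 50000, seed = 2)
  mu <- fit$scaler$center + fit$scaler$scale * fit$means[1, ]
  Sigma <- chol2inv(chol(fit$nu[1] * fit$W[[1]])) * (fit$beta[1] + 1) / fit$beta[1]
  sds <- fit$scaler$scale * sqrt(diag(Sigma))
  se <- sds / sqrt(50000)
  expect_true(all(abs(colMeans(big) - mu) < 3 * se + 1e-9))

  again <- generate_cohort(fit, 50000, seed = 2)
  expect_identical(big, again)
  other <- generate_cohort(fit, 50000, seed = 3)
  expect_false(identical(as.matrix(big), as.matrix(other)))

  # original-units output re-scales onto the internal draw exactly
  z <- scale_transform(fit$scaler, big)
  back <- scale_inverse(fit$scaler, z)
  expect_lt(max(abs(back - as.matrix(big))), 1e-10)

  expect_error(generate_cohort(fit, -1), "non-negative")
})

test_that("sampling moments converge to the mixture moments", {
  x <- sample_mixture(c(.4, .6), list(c(-4, 1), c(3, -2)),
                      list(diag(2), 0.5 * diag(2)), n = 800, seed = 14)
  fit <- fit_bgmm(x, opt = 2, seed = 14)
  s <- generate_cohort(fit, 1e5, seed = 4, weight_mode = "expected")
  # model mixture mean in original units
  mus <- t(apply(fit$means, 1, function(m) fit$scaler$center + fit$scaler$scale * m))
  mix_mean <- colSums(fit$weights * mus)
  span <- apply(as.matrix(x), 2, function(v) diff(range(v)))
  expect_lt(max(abs(colMeans(s) - mix_mean) / span), 0.02)
})

test_that("a saved model reloads and regenerates identical cohorts", {
  x <- sample_mixture(c(.5, .5), list(c(-3, 0), c(3, 0)),
                      list(diag(2), diag(2)), n = 250, seed = 6)
  fit <- fit_bgmm(x, opt = 2, seed = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_bgmm(fit, f)
  back <- read_bgmm(f)
  expect_equal(back$means, fit$means, tolerance = 1e-12)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
  expect_equal(back$priors$gamma, fit$priors$gamma)
  s1 <- generate_cohort(fit, 100, seed = 8)
  s2 <- generate_cohort(back, 100, seed = 8)
  expect_equal(as.matrix(s1), as.matrix(s2), tolerance = 1e-9)
})
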