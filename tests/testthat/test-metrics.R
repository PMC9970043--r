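fixture_cohort <- function(n, seed) {
  sample_mixture(c(.5, .3, .2),
                 list(c(0, 5, -2), c(4, 0, 1), c(-3, -4, 3)),
                 list(diag(3), 0.5 * diag(3), 2 * diag(3)),
                 n = n, seed = seed)
}

test_that("all indicators vanish when the cohorts are identical", {
  x <- fixture_cohort(1000, seed = 2)
  expect_equal(as.numeric(cv_difference(x, x)), 0)
  expect_equal(inter_correlation_difference(x, x), 0)
  expect_equal(intra_correlation_difference(x, x), 0)
  expect_equal(goodness_of_fit(x, x), 0)
  expect_lte(kl_divergence(x, x), 1e-3) # smoothing floor at n >= 1000
  g <- glance(cohort_fidelity(x, x))
  expect_equal(g$cv_diff + g$inter_corr_diff + g$intra_corr_diff + g$gof, 0)
})

test_that("cV difference matches the hand-computed example", {
  real <- tibble::tibble(v = c(2, 4))
  synth <- tibble::tibble(v = c(3, 3))
  got <- cv_difference(real, synth)
  expect_equal(as.numeric(got), sqrt(2) / 3, tolerance = 1e-12) # ~0.4714
  per <- attr(got, "per_feature")
  expect_equal(per$cv_real, sqrt(2) / 3, tolerance = 1e-12)
  expect_equal(per$cv_synth, 0)
})

test_that("inter-correlation difference detects broken feature coupling", {
  set.seed(6)
  u <- rnorm(10000)
  real <- tibble::tibble(x = u, y = u)             # corr 1
  synth <- tibble::tibble(x = rnorm(10000), y = rnorm(10000)) # corr ~ 0
  expect_equal(inter_correlation_difference(real, synth), 1, tolerance = 0.05)

  # identical feature permutation of both cohorts changes nothing
  r2 <- real[c("y", "x")]
  s2 <- synth[c("y", "x")]
  expect_equal(inter_correlation_difference(r2, s2),
               inter_correlation_difference(real, synth))
  expect_error(inter_correlation_difference(real["x"], synth["x"]), "at least 2")
})

test_that("intra-correlation difference is small for same-distribution cohorts", {
  a <- fixture_cohort(600, seed = 3)
  b <- fixture_cohort(600, seed = 4)
  expect_lt(intra_correlation_difference(a, b), 0.05)
})

test_that("goodness of fit spans [0, 1] and matches the analytic shift case", {
  real <- tibble::tibble(a = c(1, 2, 3, 4))
  synth <- tibble::tibble(a = c(11, 12, 13, 14))
  expect_equal(goodness_of_fit(real, synth), 1) # disjoint supports

  set.seed(7)
  u1 <- tibble::tibble(a = runif(5000))
  u2 <- tibble::tibble(a = runif(5000) + 0.5)
  expect_lt(abs(goodness_of_fit(u1, u2) - 0.5), 0.03) # analytic sup distance

  # symmetric in its arguments
  expect_equal(goodness_of_fit(u1, u2), goodness_of_fit(u2, u1))
})

test_that("histogram KL tracks the closed-form Gaussian divergence", {
  set.seed(9)
  real <- tibble::tibble(a = rnorm(50000))
  synth <- tibble::tibble(a = rnorm(50000, mean = 1))
  kl <- kl_divergence(real, synth)
  expect_lt(abs(kl - 0.5) / 0.5, 0.15) # closed form: 0.5 * delta_mu^2

  # duplicating rows leaves the histogram estimate unchanged exactly
  expect_equal(
    kl_divergence(dplyr::bind_rows(real, real), dplyr::bind_rows(synth, synth)),
    kl, tolerance = 1e-12
  )
  # asymmetric by construction
  expect_false(isTRUE(all.equal(kl, kl_divergence(synth, real), tolerance = 1e-4)))
})

test_that("shared affine maps leave correlation and GOF indicators unchanged", {
  a <- fixture_cohort(400, seed = 11)
  b <- fixture_cohort(500, seed = 12)
  shift <- c(10, -5, 100)
  scale <- c(2, 0.3, 7)
  fa <- sweep(sweep(as.matrix(a), 2, scale, "*"), 2, shift, "+")
  fb <- sweep(sweep(as.matrix(b), 2, scale, "*"), 2, shift, "+")
  expect_equal(inter_correlation_difference(fa, fb),
               inter_correlation_difference(a, b), tolerance = 1e-10)
  expect_equal(intra_correlation_difference(fa, fb),
               intra_correlation_difference(a, b), tolerance = 1e-10)
  expect_equal(goodness_of_fit(fa, fb), goodness_of_fit(a, b))
})

test_that("the blocked intra-correlation summary equals the direct computation", {
  set.seed(13)
  x <- matrix(rnorm(90 * 4), 90, 4)
  direct <- {
    z <- scale(x)
    r <- cor(t(z))
    mean(abs(r[row(r) != col(r)]))
  }
  expect_equal(virtualcohort:::mean_abs_row_cor(x, block = 7), direct,
               tolerance = 1e-12)
})

test_that("density overlays are normalized and match the analytic density", {
  set.seed(15)
  real <- tibble::tibble(a = rnorm(10000))
  ov <- kde_overlay(real, real, "a")
  at0 <- ov$density_real[which.min(abs(ov$grid))]
  expect_lt(abs(at0 - 1 / sqrt(2 * pi)) / (1 / sqrt(2 * pi)), 0.10)
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trap(ov$grid, ov$density_real), 1, tolerance = 0.01)
  expect_equal(ov$density_real, ov$density_synth)

  const <- tibble::tibble(a = rep(3, 50))
  w <- testthat::capture_warnings(ovc <- kde_overlay(const, const, "a"))
  expect_match(w, "[Dd]egenerate", all = TRUE) # once per cohort
  expect_equal(trap(ovc$grid, ovc$density_real), 1, tolerance = 0.01)
})

test_that("fidelity reports serialize with per-feature detail", {
  a <- fixture_cohort(300, seed = 21)
  b <- fixture_cohort(300, seed = 22)
  rep <- cohort_fidelity(a, b)
  expect_equal(nrow(tidy(rep)), 3L)
  f <- withr::local_tempfile(fileext = ".json")
  write_fidelity_report(rep, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$indicators$kl, rep$kl, tolerance = 1e-12)
  expect_equal(nrow(back$per_feature), 3L)
})
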