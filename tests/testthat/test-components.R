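test_that("a singleton range selects its only k", {
  blobs <- make_blobs(90, list(c(0, 0), c(8, 0), c(0, 8)), sd = 0.3, seed = 3)
  scan <- select_components(blobs, k_range = c(4, 4), rule = "min", seed = 3)
  expect_equal(scan$opt, 4L)
  expect_equal(nrow(scan$entries), 1L)
})

test_that("the minimum-DB rule recovers the true blob count", {
  blobs <- make_blobs(600, list(c(-10, 0), c(0, 10), c(10, 0)), sd = 1, seed = 21)
  scan <- select_components(blobs, k_range = c(2, 6), rule = "min", seed = 21)
  expect_equal(scan$opt, 3L)
  expect_true(all(diff(scan$entries$k) == 1))
})

test_that("early termination returns the full scan's optimum when the best comes early", {
  blobs <- make_blobs(400, list(c(-9, 0), c(0, 9), c(9, 0)), sd = 0.8, seed = 33)
  full <- select_components(blobs, k_range = c(2, 9), rule = "min",
                            patience = 50, seed = 33)
  expect_false(full$terminated_early)
  early <- select_components(blobs, k_range = c(2, 9), rule = "min",
                             patience = 3, seed = 33)
  # soundness precondition: the full best occurs >= patience before k_max
  expect_lte(full$opt + 3, 9)
  expect_equal(early$opt, full$opt)
  expect_true(early$terminated_early)
  expect_lt(nrow(early$entries), nrow(full$entries))
})

test_that("per-feature rescaling of the input changes neither labels nor scores", {
  blobs <- make_blobs(150, list(c(0, 0), c(7, 7)), sd = 0.5, seed = 10)
  x <- as.matrix(blobs)
  y <- x
  y[, 1] <- y[, 1] * 1000
  s1 <- select_components(x, k_range = c(2, 4), rule = "min", seed = 10)
  s2 <- select_components(y, k_range = c(2, 4), rule = "min", seed = 10)
  expect_equal(s1$entries$dbs, s2$entries$dbs, tolerance = 1e-9)
  expect_identical(s1$entries$labels, s2$entries$labels)
  expect_equal(s1$opt, s2$opt)
})

test_that("both selection rules are honoured and ties break to smaller k", {
  blobs <- make_blobs(200, list(c(0, 0), c(9, 0)), sd = 0.4, seed = 5)
  smin <- select_components(blobs, k_range = c(2, 5), rule = "min", seed = 5)
  smax <- select_components(blobs, k_range = c(2, 5), rule = "max", seed = 5)
  expect_equal(smin$opt, unlist(smin$entries$k[which.min(smin$entries$dbs)]))
  expect_equal(smax$opt, unlist(smax$entries$k[which.max(smax$entries$dbs)]))
  expect_error(select_components(blobs, k_range = c(1, 4)), "k_min")
})
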