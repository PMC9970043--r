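test_that("mixture sampling honours weights, size and seed", {
  x <- sample_mixture(1, list(rep(0, 3)), list(diag(3)), n = 10000, seed = 4)
  expect_true(all(abs(colMeans(x)) < 3 / sqrt(10000)))

  empty <- sample_mixture(c(.5, .5), list(c(0, 0), c(1, 1)),
                          list(diag(2), diag(2)), n = 0, seed = 1)
  expect_equal(dim(empty), c(0L, 2L))

  a <- sample_mixture(c(.3, .7), list(c(0, 0), c(5, 5)),
                      list(diag(2), diag(2)), n = 50, seed = 1)
  b <- sample_mixture(c(.3, .7), list(c(0, 0), c(5, 5)),
                      list(diag(2), diag(2)), n = 50, seed = 1)
  c_ <- sample_mixture(c(.3, .7), list(c(0, 0), c(5, 5)),
                       list(diag(2), diag(2)), n = 50, seed = 2)
  expect_identical(a, b)
  expect_false(identical(as.matrix(a), as.matrix(c_)))
  expect_length(attr(a, "components"), 50L)

  expect_error(sample_mixture(c(.6, .6), list(0, 1), list(matrix(1), matrix(1)), 5),
               "sum to 1")
})

test_that("the default simulated cohort has the reference shape and annotations", {
  sim <- simulate_cohort(seed = 17)
  expect_equal(dim(sim$table), c(648L, 22L)) # 20 base + duplicate + twin
  ann <- sim$annotations

  # duplicate column is an exact copy; twin shares only the casefolded name
  dup <- ann$duplicate_columns
  expect_equal(nrow(dup), 2L)
  val <- dup[dup$kind == "duplicate_value", ]
  expect_identical(sim$table[[val$name]], sim$table[[val$source]])
  twin <- dup[dup$kind == "duplicate_name", ]
  expect_identical(tolower(twin$name), tolower(twin$source))
  expect_false(identical(sim$table[[twin$name]], sim$table[[twin$source]]))

  # missingness matches the mask and the default per-feature pattern
  base <- sim$table[seq_len(20)]
  expect_identical(unname(is.na(as.matrix(base))), unname(ann$missing_mask))
  miss_frac <- colMeans(ann$missing_mask)
  expect_gte(miss_frac[1], 0.30) # the heavy feature crosses the threshold
  expect_true(all(miss_frac[-1] < 0.30))

  # displaced rows are complete so the flagging stage can see all of them
  expect_equal(length(ann$outlier_rows), ceiling(0.05 * 648))
  expect_false(any(ann$missing_mask[ann$outlier_rows, ]))
})

test_that("cohort simulation is reproducible and writable", {
  s1 <- simulate_cohort(n_patients = 60, n_features = 5, seed = 9)
  s2 <- simulate_cohort(n_patients = 60, n_features = 5, seed = 9)
  expect_identical(s1, s2)

  f <- withr::local_tempfile(fileext = ".csv")
  g <- withr::local_tempfile(fileext = ".json")
  write_cohort_fixture(s1, f, g)
  back <- read_cohort(f)
  expect_identical(names(back), names(s1$table))
  expect_equal(nrow(back), 60L)
  expect_equal(sum(is.na(back)), sum(is.na(s1$table)))
  ann <- jsonlite::fromJSON(g)
  expect_equal(ann$seed, 9L)
})
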