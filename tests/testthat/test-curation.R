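test_that("eligibility split applies the strict missingness bound", {
  tbl <- tibble::tibble(
    full = rnorm(10),
    forty = c(rnorm(6), rep(NA, 4)),   # 40% missing
    thirty = c(rnorm(7), rep(NA, 3)),  # exactly 30%: still excluded
    label = letters[1:10]
  )
  p <- partition_features(tbl, missing_threshold = 0.30)
  expect_identical(p$eligible, "full")
  expect_identical(
    p$excluded$reason[match(c("forty", "thirty", "label"), p$excluded$feature)],
    c("missingness", "missingness", "non_numeric")
  )

  clean <- tibble::tibble(a = rnorm(5), b = rnorm(5))
  expect_identical(partition_features(clean)$eligible, c("a", "b"))
  expect_error(partition_features(tibble::tibble(x = rep(NA_real_, 5))),
               "No eligible")
})

test_that("raising the missing threshold never shrinks the eligible set", {
  set.seed(31)
  for (rep in 1:5) {
    tbl <- as.data.frame(matrix(rnorm(200), 20))
    for (j in seq_along(tbl)) {
      tbl[[j]][sample(20, sample(0:12, 1))] <- NA
    }
    prev <- character()
    for (th in c(0.1, 0.3, 0.5, 0.7)) {
      el <- tryCatch(partition_features(tbl, th)$eligible,
                     error = function(e) character())
      expect_true(all(prev %in% el))
      prev <- el
    }
  }
})

test_that("duplicate features are dropped by value and by name, once each", {
  set.seed(7)
  x <- rnorm(50)
  tbl <- tibble::tibble(x = x, x_copy = x, Age = rnorm(50), age = rnorm(50))
  dups <- find_duplicate_features(tbl)
  expect_identical(dups$reason[dups$feature == "x_copy"], "duplicate_value")
  expect_identical(dups$reason[dups$feature == "age"], "duplicate_name")
  expect_equal(nrow(dups), 2L)
  expect_false(any(duplicated(dups$feature)))

  # independent columns with dissimilar names survive: sample |r| is far
  # below the threshold
  set.seed(11)
  ind <- tibble::tibble(alpha = rnorm(500), zeta_v = rnorm(500))
  expect_true(abs(cor(ind$alpha, ind$zeta_v)) < 0.2) # oracle for the fixture
  expect_equal(nrow(find_duplicate_features(ind)), 0L)
})

test_that("kNN imputation fills cells with neighbour means and flags them", {
  # identity on complete data
  full <- tibble::tibble(a = rnorm(6), b = rnorm(6))
  res <- impute_knn(full, k = 2)
  expect_equal(as.data.frame(res$data), as.data.frame(full))
  expect_false(any(res$imputed_mask))

  # k = 1: twin row donates its value
  twin <- tibble::tibble(a = c(1, 1, 50), b = c(2, NA, 60))
  expect_equal(impute_knn(twin, k = 1)$data$b[2], 2)

  # k = 2: mean of the two nearest donors, hand-computed on a toy matrix
  toy <- rbind(
    c(0.0, NA),
    c(0.1, 4),
    c(-0.1, 6),
    c(10, 100)
  )
  colnames(toy) <- c("p", "q")
  out <- impute_knn(toy, k = 2)
  expect_equal(out$data$q[1], 5)
  expect_equal(which(out$imputed_mask), 5L) # column-major position (1, 2)

  expect_error(impute_knn(rbind(c(NA, NA), c(1, 2), c(3, 4)), k = 1), "Row 1")
  expect_error(impute_knn(rbind(c(1, NA), c(2, NA), c(3, 5)), k = 2),
               "fewer than k")
})

test_that("imputation is idempotent", {
  set.seed(5)
  x <- matrix(rnorm(40), 10)
  x[c(3, 17)] <- NA
  once <- impute_knn(x, k = 3)$data
  twice <- impute_knn(once, k = 3)
  expect_equal(as.data.frame(twice$data), as.data.frame(once))
  expect_false(any(twice$imputed_mask))
})

test_that("isolation forest flags the quantile cut and extreme points", {
  set.seed(2)
  ball <- matrix(rnorm(400, sd = 0.3), 200, 2)
  far <- c(100, 100)
  x <- rbind(ball, far)
  scores <- isolation_scores(x, seed = 4)
  expect_equal(which.max(scores), 201L) # extreme point is most isolated
  flags1 <- detect_outliers(x, contamination = 0.004, seed = 4)
  expect_true(flags1[201])
  expect_equal(sum(flags1), 1L)

  flags <- detect_outliers(ball, contamination = 0.05, seed = 4)
  expect_equal(sum(flags), 10L) # ceiling(0.05 * 200)
  expect_identical(flags, detect_outliers(ball, contamination = 0.05, seed = 4))

  # degenerate input: identical rows do not crash
  same <- matrix(1, 200, 3)
  expect_equal(length(detect_outliers(same, seed = 1)), 200L)
  expect_error(detect_outliers(ball[1:5, ]), "at least 10")
})

test_that("curate partitions every feature exactly once and logs deterministically", {
  sim <- simulate_cohort(n_patients = 120, n_features = 8, seed = 13)
  cur <- curate(sim$table, curation_config(seed = 13))
  all_feats <- names(sim$table)
  expect_setequal(c(cur$eligible_features, cur$excluded_features$feature), all_feats)
  expect_equal(length(cur$eligible_features) + nrow(cur$excluded_features),
               length(all_feats))
  expect_false(any(is.na(cur$data)))
  # imputed mask marks exactly the raw missing cells of eligible features
  raw_elig <- as.matrix(sim$table[cur$eligible_features])
  expect_identical(unname(cur$imputed_mask), unname(is.na(raw_elig)))

  cur2 <- curate(sim$table, curation_config(seed = 13))
  expect_identical(
    jsonlite::toJSON(cur$log), jsonlite::toJSON(cur2$log)
  )
  expect_identical(cur$data, cur2$data)
})
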