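# Ground-truth generators: a labelled Gaussian-mixture sampler (the test
# oracle for parameter recovery) and a clinical-table emulator producing
# cohorts with the shape the pipeline is meant to digest - mixed
# unimodal/multimodal continuous features in correlated blocks, injected
# missingness, displaced outlier rows and duplicated columns - together
# with full annotations of everything injected.

#' Sample from a known Gaussian mixture
#'
#' Draws `n` points from the mixture defined by `weights`, `means` and
#' `covariances`; component counts are multinomial in the weights.
#' Deterministic for a fixed seed.
#'
#' @param weights Simplex vector (must sum to 1 within 1e-12).
#' @param means List of d-vectors.
#' @param covariances List of d-by-d SPD matrices.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return Tibble of `n` rows and `d` feature columns (`f1..fd`), with
#'   attribute `components` giving the true labels.
#' @export
sample_mixture <- function(weights, means, covariances, n, seed = 1L) {
  stopifnot(length(means) == length(weights), length(covariances) == length(weights))
  if (abs(sum(weights) - 1) > 1e-12) abort("`weights` must sum to 1.")
  if (any(weights < 0)) abort("`weights` must be non-negative.")
  d <- length(means[[1]])
  chols <- lapply(covariances, function(S) {
    tryCatch(chol((S + t(S)) / 2),
             error = function(e) abort("Covariance is not positive definite."))
  })
  n <- check_scalar_int(n, "n", min = 0L)
  out <- with_seed_offset(seed, 7L, {
    counts <- if (n > 0) as.integer(rmultinom(1L, n, weights)) else integer(length(weights))
    z <- rep(seq_along(weights), counts)
    X <- matrix(0, n, d)
    pos <- 0L
    for (k in seq_along(weights)) {
      if (counts[k] == 0L) next
      E <- matrix(rnorm(counts[k] * d), counts[k], d)
      X[pos + seq_len(counts[k]), ] <- E %*% chols[[k]] +
        matrix(means[[k]], counts[k], d, byrow = TRUE)
      pos <- pos + counts[k]
    }
    perm <- if (n > 0) sample.int(n) else integer()
    list(X = X[perm, , drop = FALSE], z = z[perm])
  })
  colnames(out$X) <- paste0("f", seq_len(d))
  res <- as_tibble(as.data.frame(out$X, check.names = FALSE))
  attr(res, "components") <- out$z
  res
}

#' Simulate a raw clinical cohort table
#'
#' Emulates the shape of a clinical registry so every pipeline stage can be
#' exercised and verified against known ground truth. Base features are
#' organized in correlated blocks, each driven by a latent categorical mode
#' (2-4 modes per block), giving a mix of unimodal and multimodal marginals
#' on feature-specific scales. On top of the base table the generator
#' injects, and records in the annotations:
#' \itemize{
#'   \item missingness, completely at random per feature at `missing_rate`
#'     (default: feature 1 at 0.40, features 2-5 at 0.01, rest complete) -
#'     only in non-displaced rows, so the outlier-flagging stage (which runs
#'     on complete cases) sees every displaced profile;
#'   \item `ceiling(outlier_rate * n)` displaced rows, with about half of
#'     the features shifted by 8-12 standard deviations each;
#'   \item `n_duplicate_features` exact copies of base columns (named
#'     `<base>_copy`), and `n_name_twins` columns with case-variant names of
#'     base columns but independent values.
#' }
#'
#' @param n_patients,n_features Cohort dimensions (defaults 648 and 20).
#' @param missing_rate `NULL` for the default pattern, or a scalar/vector of
#'   per-feature missing fractions in `[0, 1]`.
#' @param outlier_rate Fraction of displaced rows, in `[0, 1)`.
#' @param n_duplicate_features,n_name_twins Numbers of appended duplicate
#'   columns of each kind.
#' @param seed Integer seed; output is byte-identical per (spec, seed).
#' @return List with `table` (tibble, possibly with `NA` cells) and
#'   `annotations`: `outlier_rows` (integer), `duplicate_columns` (tibble of
#'   name, source, kind), `missing_mask` (logical matrix over the base
#'   features), `block` (feature-to-block map), `n_modes` (per block).
#' @export
simulate_cohort <- function(n_patients = 648L, n_features = 20L,
                            missing_rate = NULL, outlier_rate = 0.05,
                            n_duplicate_features = 1L, n_name_twins = 1L,
                            seed = 1L) {
  n <- check_scalar_int(n_patients, "n_patients", min = 20L)
  d <- check_scalar_int(n_features, "n_features", min = 2L)
  stopifnot(outlier_rate >= 0, outlier_rate < 1)
  n_dup <- check_scalar_int(n_duplicate_features, "n_duplicate_features", min = 0L)
  n_twin <- check_scalar_int(n_name_twins, "n_name_twins", min = 0L)
  if (is.null(missing_rate)) {
    missing_rate <- numeric(d)
    missing_rate[1L] <- 0.40
    if (d >= 5L) missing_rate[2:5] <- 0.01
  }
  missing_rate <- rep_len(missing_rate, d)
  stopifnot(all(missing_rate >= 0), all(missing_rate <= 1))

  # clinical-style names with pairwise edit distance >= 2, so only injected
  # twins trip the name-deduplication rule
  pool <- c("age", "bmi", "sys_bp", "dia_bp", "heart_rate", "lvef", "la_diam",
            "ivs_thick", "pw_thick", "lv_end_dia", "lv_end_sys", "qrs_dur",
            "qtc_int", "creatinine", "sodium", "potassium", "hemoglobin",
            "glucose", "cholesterol", "triglyc", "crp_level", "troponin",
            "nt_probnp", "e_a_ratio", "max_lv_wall", "gfr_est")
  nms <- if (d <= length(pool)) pool[seq_len(d)] else {
    c(pool, sprintf("marker_%02d%02d", seq_len(d - length(pool)),
                    seq_len(d - length(pool))))
  }
  with_seed_offset(seed, 3L, {
    # correlated blocks of ~4 features, each with its own latent mode
    n_blocks <- max(1L, ceiling(d / 4L))
    block <- sort(rep(seq_len(n_blocks), length.out = d))
    n_modes <- sample(2:4, n_blocks, replace = TRUE)
    centers <- runif(d, 10, 100)         # clinical-looking locations
    scales <- runif(d, 1, 12)            # per-feature dispersion
    x <- matrix(0, n, d)
    for (b in seq_len(n_blocks)) {
      feats <- which(block == b)
      z <- sample.int(n_modes[b], n, replace = TRUE)
      shared <- rnorm(n)                 # within-block correlation driver
      for (f in feats) {
        offsets <- seq(-1.2, 1.2, length.out = n_modes[b]) * scales[f] * runif(1, 1.5, 2.5)
        x[, f] <- centers[f] + offsets[z] + 0.6 * scales[f] * shared +
          0.8 * scales[f] * rnorm(n)
      }
    }

    n_out <- ceiling(outlier_rate * n)
    outlier_rows <- sort(sample.int(n, n_out))
    sds <- apply(x, 2L, sd)
    for (i in outlier_rows) {
      hit <- sample.int(d, max(1L, floor(d / 2)))
      x[i, hit] <- x[i, hit] +
        sample(c(-1, 1), length(hit), replace = TRUE) * runif(length(hit), 8, 12) * sds[hit]
    }

    missing_mask <- matrix(FALSE, n, d)
    clean_rows <- setdiff(seq_len(n), outlier_rows)
    for (f in seq_len(d)) {
      if (missing_rate[f] <= 0) next
      k <- round(missing_rate[f] * n)
      k <- min(k, length(clean_rows))
      if (k > 0L) missing_mask[sample(clean_rows, k), f] <- TRUE
    }
    x[missing_mask] <- NA_real_

    colnames(x) <- nms
    tbl <- as_tibble(as.data.frame(x, check.names = FALSE))

    dup_pool <- setdiff(seq_len(d), 1L) # never the heavy-missing feature
    dup_info <- list()
    if (n_dup > 0L) {
      src <- sample(dup_pool, n_dup)
      for (s in src) {
        nm <- paste0(nms[s], "_copy")
        tbl[[nm]] <- tbl[[nms[s]]]
        dup_info[[length(dup_info) + 1L]] <-
          tibble(name = nm, source = nms[s], kind = "duplicate_value")
      }
      dup_pool <- setdiff(dup_pool, src)
    }
    if (n_twin > 0L) {
      src <- sample(dup_pool, n_twin)
      for (s in src) {
        # case twin: identical after casefolding (edit distance 0)
        nm <- sub("^(.)", "\\U\\1", nms[s], perl = TRUE)
        tbl[[nm]] <- centers[s] + scales[s] * rnorm(n)
        dup_info[[length(dup_info) + 1L]] <-
          tibble(name = nm, source = nms[s], kind = "duplicate_name")
      }
    }

    list(
      table = tbl,
      annotations = list(
        outlier_rows = outlier_rows,
        duplicate_columns = if (length(dup_info)) dplyr::bind_rows(dup_info) else
          tibble(name = character(), source = character(), kind = character()),
        missing_mask = missing_mask,
        block = setNames(block, nms),
        n_modes = n_modes,
        seed = as.integer(seed)
      )
    )
  })
}

#' Write a simulated cohort to disk
#'
#' Writes the table as CSV and the annotations as a JSON sidecar.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param csv_path,json_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_cohort_fixture <- function(cohort, csv_path, json_path = NULL) {
  readr::write_csv(cohort$table, csv_path, na = "")
  if (!is.null(json_path)) {
    ann <- cohort$annotations
    jsonlite::write_json(
      list(
        outlier_rows = ann$outlier_rows,
        duplicate_columns = ann$duplicate_columns,
        missing_cells = which(ann$missing_mask, arr.ind = TRUE),
        block = as.list(ann$block),
        n_modes = ann$n_modes,
        seed = ann$seed
      ),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  invisible(csv_path)
}
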