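#' Curation settings
#'
#' Collects the tunable parameters of the data-diagnostics stage.
#'
#' @param missing_threshold Features with a missing fraction `>=` this value
#'   are non-eligible. The eligibility rule is strict: a feature is kept only
#'   if its missing fraction is strictly below the threshold. Default 0.30.
#' @param contamination Expected outlier fraction for isolation-forest
#'   flagging, in (0, 0.5).
#' @param knn_k Number of neighbours for missing-value imputation.
#' @param dup_corr_threshold Absolute Pearson correlation at or above which
#'   the later of two features is dropped as a value duplicate.
#' @param dup_name_distance Maximum case-insensitive Levenshtein distance at
#'   which the later of two feature names is dropped as a name duplicate.
#' @param seed Integer seed for the stochastic outlier stage.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(missing_threshold = 0.30,
                            contamination = 0.05,
                            knn_k = 5L,
                            dup_corr_threshold = 0.999,
                            dup_name_distance = 1L,
                            seed = 1L) {
  stopifnot(
    missing_threshold >= 0, missing_threshold <= 1,
    contamination > 0, contamination < 0.5,
    dup_corr_threshold > 0, dup_corr_threshold <= 1,
    dup_name_distance >= 0
  )
  structure(
    list(
      missing_threshold = missing_threshold,
      contamination = contamination,
      knn_k = check_scalar_int(knn_k, "knn_k"),
      dup_corr_threshold = dup_corr_threshold,
      dup_name_distance = as.integer(dup_name_distance),
      seed = as.integer(seed)
    ),
    class = "curation_config"
  )
}

#' Split features into eligible and non-eligible sub-spaces
#'
#' A feature is eligible when it is numeric and its missing fraction is
#' strictly below `missing_threshold`. Non-numeric features are excluded with
#' reason `"non_numeric"`, over-missing ones with reason `"missingness"`.
#'
#' @param data Raw cohort tibble (from [read_cohort()] or in memory).
#' @param missing_threshold Strict upper bound on the missing fraction.
#' @return A list with `eligible` (character vector, input order) and
#'   `excluded` (tibble with columns `feature`, `reason`).
#' @export
partition_features <- function(data, missing_threshold = 0.30) {
  if (!is.data.frame(data) || nrow(data) == 0L || ncol(data) == 0L) {
    abort("`data` must be a non-empty data frame.")
  }
  reasons <- vapply(data, function(col) {
    if (!is.numeric(col)) return("non_numeric")
    if (mean(is.na(col)) >= missing_threshold) return("missingness")
    ""
  }, character(1))
  eligible <- names(data)[reasons == ""]
  if (length(eligible) == 0L) abort("No eligible features remain after partitioning.")
  list(
    eligible = eligible,
    excluded = tibble(
      feature = names(data)[reasons != ""],
      reason = unname(reasons[reasons != ""])
    )
  )
}

#' Drop duplicated features
#'
#' Two de-duplication passes over the eligible features, in input order:
#' value duplicates (absolute Pearson correlation on shared non-missing rows
#' at or above `dup_corr_threshold`; the later column is dropped) and name
#' duplicates (case-insensitive Levenshtein distance at most
#' `dup_name_distance`; the later column is dropped). A feature is excluded
#' at most once, with the value reason taking precedence.
#'
#' @param data Data frame restricted to candidate features (may contain NA).
#' @param dup_corr_threshold,dup_name_distance See [curation_config()].
#' @return Tibble of `feature`, `reason` additions (possibly empty).
#' @export
find_duplicate_features <- function(data, dup_corr_threshold = 0.999,
                                    dup_name_distance = 1L) {
  nms <- names(data)
  d <- length(nms)
  if (d < 2L) {
    return(tibble(feature = character(), reason = character()))
  }
  x <- as_feature_matrix(data, "data")
  dropped <- character()
  reason <- character()
  mark <- function(f, why) {
    if (!(f %in% dropped)) {
      dropped <<- c(dropped, f)
      reason <<- c(reason, why)
    }
  }
  for (i in seq_len(d - 1L)) {
    if (nms[i] %in% dropped) next
    for (j in seq(i + 1L, d)) {
      if (nms[j] %in% dropped) next
      shared <- !is.na(x[, i]) & !is.na(x[, j])
      if (sum(shared) >= 3L) {
        r <- suppressWarnings(cor(x[shared, i], x[shared, j]))
        if (!is.na(r) && abs(r) >= dup_corr_threshold) mark(nms[j], "duplicate_value")
      }
    }
  }
  lowered <- tolower(nms)
  for (i in seq_len(d - 1L)) {
    if (nms[i] %in% dropped) next
    for (j in seq(i + 1L, d)) {
      if (nms[j] %in% dropped) next
      if (adist(lowered[i], lowered[j]) <= dup_name_distance) {
        mark(nms[j], "duplicate_name")
      }
    }
  }
  tibble(feature = dropped, reason = reason)
}

#' Impute missing values by k-nearest neighbours
#'
#' Each missing cell is replaced by the mean of the feature's values among
#' the `k` nearest rows, by Euclidean distance over mutually observed
#' features rescaled by `sqrt(d / n_shared)` so distances with different
#' overlap are comparable. Only rows with the target feature observed are
#' candidate neighbours. Observed cells are never changed.
#'
#' @param data Data frame or numeric matrix with missing cells.
#' @param k Number of neighbours.
#' @return A list with `data` (complete tibble) and `imputed_mask` (logical
#'   matrix, `TRUE` where a value was imputed).
#' @examples
#' x <- tibble::tibble(a = c(1, 1, 10), b = c(2, NA, 20))
#' impute_knn(x, k = 1)$data
#' @export
impute_knn <- function(data, k = 5L) {
  k <- check_scalar_int(k, "k")
  x <- as_feature_matrix(data, "data")
  n <- nrow(x)
  d <- ncol(x)
  mask <- is.na(x)
  all_missing <- which(rowSums(mask) == d)
  if (length(all_missing) > 0L) {
    abort(sprintf("Row %d has every cell missing; cannot impute.", all_missing[1]))
  }
  short <- which(colSums(!mask) < k)
  if (length(short) > 0L) {
    abort(sprintf(
      "Feature '%s' has fewer than k = %d observed values.",
      colnames(x)[short[1]] %||% as.character(short[1]), k
    ))
  }
  if (any(mask)) {
    obs <- !mask
    for (i in which(rowSums(mask) > 0L)) {
      # overlap-rescaled squared distance from row i to every other row
      shared <- obs & rep(obs[i, ], each = n)
      n_shared <- rowSums(shared)
      diff2 <- (x - rep(x[i, ], each = n))^2
      diff2[!shared] <- 0
      dist2 <- ifelse(n_shared > 0L, rowSums(diff2) * d / n_shared, Inf)
      dist2[i] <- Inf
      for (j in which(mask[i, ])) {
        cand <- which(obs[, j] & is.finite(dist2))
        if (length(cand) < k) cand <- which(obs[, j] & seq_len(n) != i)
        nb <- cand[order(dist2[cand], cand)][seq_len(min(k, length(cand)))]
        x[i, j] <- mean(x[nb, j])
      }
    }
  }
  out <- as_tibble(as.data.frame(x, check.names = FALSE))
  list(data = out, imputed_mask = mask)
}

#' Curate a raw clinical cohort
#'
#' Runs the full data-diagnostics stage: eligibility split by missingness
#' (strictly below 30% by default) and numeric parsability, duplicate-feature
#' removal by value correlation and by name similarity, isolation-forest
#' outlier flagging on the complete-case rows, and k-nearest-neighbour
#' imputation of the remaining missing cells. Flagged patients are retained
#' in the curated table but marked so that model fitting can skip them.
#'
#' @param data Raw cohort tibble (mixed character/numeric columns allowed).
#' @param config A [curation_config()].
#' @return An object of class `curated_cohort`: a list with
#'   \describe{
#'     \item{data}{complete tibble of eligible features, all patients,}
#'     \item{eligible_features, excluded_features}{the feature partition,}
#'     \item{outlier_flag}{logical per patient,}
#'     \item{imputed_mask}{logical matrix over `data`,}
#'     \item{log}{tibble of curation events (stage, target, action, reason).}
#'   }
#' @examples
#' tbl <- simulate_cohort(n_patients = 120, n_features = 6, seed = 7)$table
#' cur <- curate(tbl, curation_config(seed = 7))
#' glance(cur)
#' @export
curate <- function(data, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort("`data` must be a non-empty data frame.")
  }
  log <- list()
  note <- function(stage, target, action, reason) {
    log[[length(log) + 1L]] <<- tibble(
      stage = stage, target = target, action = action, reason = reason
    )
  }

  part <- partition_features(data, config$missing_threshold)
  excluded <- part$excluded
  for (i in seq_len(nrow(excluded))) {
    note("partition", excluded$feature[i], "exclude_feature", excluded$reason[i])
  }

  work <- data[part$eligible]
  dups <- find_duplicate_features(
    work, config$dup_corr_threshold, config$dup_name_distance
  )
  for (i in seq_len(nrow(dups))) {
    note("deduplicate", dups$feature[i], "exclude_feature", dups$reason[i])
  }
  excluded <- dplyr::bind_rows(excluded, dups)
  eligible <- setdiff(part$eligible, dups$feature)
  if (length(eligible) == 0L) abort("No eligible features remain after de-duplication.")
  work <- work[eligible]

  x <- as_feature_matrix(work, "data")
  complete <- stats::complete.cases(x)
  outlier_flag <- rep(FALSE, nrow(x))
  if (sum(complete) < 10L) {
    note("outliers", "all", "skip", "fewer than 10 complete rows")
    warn("Outlier stage skipped: fewer than 10 complete-case rows.")
  } else {
    flags <- detect_outliers(
      x[complete, , drop = FALSE],
      contamination = config$contamination, seed = config$seed
    )
    outlier_flag[which(complete)[flags]] <- TRUE
    if (sum(stats::dist(x[complete, , drop = FALSE][seq_len(min(50, sum(complete))), ])) == 0) {
      note("outliers", "all", "flag", "degenerate input: identical rows")
    }
    for (i in which(outlier_flag)) {
      note("outliers", as.character(i), "flag_row", "isolation_forest")
    }
  }

  imp <- impute_knn(work, k = config$knn_k)
  n_imp <- sum(imp$imputed_mask)
  if (n_imp > 0) note("impute", "matrix", "impute_cells", sprintf("knn_k=%d cells=%d", config$knn_k, n_imp))

  structure(
    list(
      data = imp$data,
      eligible_features = eligible,
      excluded_features = excluded,
      outlier_flag = outlier_flag,
      imputed_mask = imp$imputed_mask,
      log = if (length(log)) dplyr::bind_rows(log) else
        tibble(stage = character(), target = character(),
               action = character(), reason = character()),
      config = config
    ),
    class = "curated_cohort"
  )
}

#' @export
print.curated_cohort <- function(x, ...) {
  cat(sprintf(
    "<curated_cohort> %d patients x %d eligible features (%d excluded, %d outliers flagged, %d cells imputed)\n",
    nrow(x$data), length(x$eligible_features), nrow(x$excluded_features),
    sum(x$outlier_flag), sum(x$imputed_mask)
  ))
  invisible(x)
}

#' @describeIn curate Excluded features and flagged rows as a tibble of events.
#' @param x A `curated_cohort`.
#' @param ... Unused.
#' @method tidy curated_cohort
#' @export
tidy.curated_cohort <- function(x, ...) x$log

#' @describeIn curate One-row curation summary.
#' @method glance curated_cohort
#' @export
glance.curated_cohort <- function(x, ...) {
  tibble(
    n_patients = nrow(x$data),
    n_features_raw = length(x$eligible_features) + nrow(x$excluded_features),
    n_eligible = length(x$eligible_features),
    n_excluded = nrow(x$excluded_features),
    n_outliers = sum(x$outlier_flag),
    n_imputed_cells = sum(x$imputed_mask)
  )
}

# rows used for model fitting: curated, outlier-free
modeling_rows <- function(curated) {
  stopifnot(inherits(curated, "curated_cohort"))
  curated$data[!curated$outlier_flag, , drop = FALSE]
}
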