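#' Select the number of Gaussian components by spectral clustering
#'
#' Robust-scales the cohort, then for each candidate cluster count `k` in
#' `k_range` (ascending) computes a spectral embedding ([spectral_embed()]),
#' clusters it with k-means ([cluster_embedding()]) and scores the partition
#' with the Davies-Bouldin index on the scaled feature matrix. The running
#' best under `rule` is tracked and the scan terminates early once
#' `patience` consecutive evaluations fail to improve it. The selected
#' optimum `opt` seeds the mixture truncation and the weight-concentration
#' parameter `exp(-opt)` of [fit_bgmm()].
#'
#' The scored index is the standard Davies-Bouldin statistic, for which
#' lower values mean better-separated clusters; `rule = "min"` therefore
#' picks the statistically best partition. `rule = "max"` (the default)
#' instead keeps the scan's published behaviour of selecting the highest
#' score; both are exposed because the two disagree on which `k` wins. Ties
#' resolve toward smaller `k`.
#'
#' @param data Data frame or matrix of complete numeric features (original
#'   units; scaling is internal). Typically the outlier-free rows of a
#'   [curate()] result.
#' @param k_range Integer vector `c(k_min, k_max)` with `k_min >= 2`.
#' @param rule `"max"` or `"min"`: whether the highest or lowest
#'   Davies-Bouldin score wins.
#' @param patience Consecutive non-improving evaluations before early stop.
#' @param seed Integer seed (embedding and k-means).
#' @param n_neighbors,bandwidth Affinity overrides passed to
#'   [spectral_embed()].
#' @return An object of class `component_scan` with fields `entries`
#'   (tibble: k, dbs, labels list-column), `opt`, `rule`, `k_range`,
#'   `patience`, `terminated_early`, `scaler`.
#' @examples
#' x <- sample_mixture(
#'   weights = c(.5, .5), means = list(c(-4, 0), c(4, 0)),
#'   covariances = list(diag(2), diag(2)), n = 200, seed = 2
#' )
#' scan <- select_components(x[1:2], k_range = c(2, 4), rule = "min", seed = 2)
#' scan$opt
#' @export
select_components <- function(data, k_range = c(2L, 20L),
                              rule = c("max", "min"), patience = 5L,
                              seed = 1L, n_neighbors = NULL, bandwidth = NULL) {
  rule <- match.arg(rule)
  x <- as_feature_matrix(data, "data")
  if (anyNA(x)) abort("`data` must be complete; curate/impute first.")
  if (length(k_range) != 2L || any(k_range != round(k_range)) ||
      k_range[1] > k_range[2]) {
    abort("`k_range` must be c(k_min, k_max) with k_min <= k_max.")
  }
  k_min <- as.integer(k_range[1])
  k_max <- as.integer(k_range[2])
  if (k_min < 2L) abort("`k_min` must be at least 2.")
  if (k_max >= nrow(x)) abort("`k_max` must be smaller than the number of rows.")
  patience <- check_scalar_int(patience, "patience")

  scaler <- fit_robust_scaler(x)
  scaled <- scale_transform(scaler, x)
  # the affinity graph does not depend on k: build the Laplacian once
  L <- normalized_laplacian(affinity_graph(scaled, n_neighbors, bandwidth))

  ks <- integer()
  scores <- numeric()
  labels_list <- list()
  best_score <- if (rule == "max") -Inf else Inf
  best_k <- NA_integer_
  since_best <- 0L
  terminated_early <- FALSE
  for (k in k_min:k_max) {
    emb <- embed_laplacian(L, k, seed = seed)
    labels <- cluster_embedding(emb, k, seed = seed)
    score <- davies_bouldin(scaled, labels)
    ks <- c(ks, k)
    scores <- c(scores, score)
    labels_list[[length(labels_list) + 1L]] <- labels
    improved <- if (rule == "max") score > best_score else score < best_score
    if (improved) {
      best_score <- score
      best_k <- k
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    if (since_best >= patience && k < k_max) {
      terminated_early <- TRUE
      break
    }
  }
  structure(
    list(
      entries = tibble(k = ks, dbs = scores, labels = labels_list),
      opt = best_k,
      rule = rule,
      k_range = c(k_min, k_max),
      patience = patience,
      terminated_early = terminated_early,
      seed = as.integer(seed),
      scaler = scaler
    ),
    class = "component_scan"
  )
}

#' @export
print.component_scan <- function(x, ...) {
  cat(sprintf(
    "<component_scan> k in [%d, %d], rule = %s: opt = %d (DBS %.4f)%s\n",
    x$k_range[1], x$k_range[2], x$rule, x$opt,
    x$entries$dbs[x$entries$k == x$opt],
    if (x$terminated_early) sprintf(", stopped early after k = %d", max(x$entries$k)) else ""
  ))
  invisible(x)
}

#' @describeIn select_components Per-k Davies-Bouldin scores as a tibble.
#' @param x A `component_scan`.
#' @param ... Unused.
#' @method tidy component_scan
#' @export
tidy.component_scan <- function(x, ...) {
  dplyr::mutate(
    x$entries[c("k", "dbs")],
    selected = .data$k == x$opt
  )
}

#' @describeIn select_components One-row scan summary.
#' @method glance component_scan
#' @export
glance.component_scan <- function(x, ...) {
  tibble(
    opt = x$opt,
    rule = x$rule,
    k_min = x$k_range[1],
    k_max = x$k_range[2],
    n_evaluated = nrow(x$entries),
    terminated_early = x$terminated_early,
    best_dbs = x$entries$dbs[x$entries$k == x$opt]
  )
}

#' @describeIn select_components Davies-Bouldin score against k with the
#'   selected optimum highlighted.
#' @param object A `component_scan`.
#' @method autoplot component_scan
#' @export
autoplot.component_scan <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$dbs)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "#c0392b"),
                                 guide = "none") +
    ggplot2::labs(
      x = "number of clusters k",
      y = "Davies-Bouldin score",
      title = sprintf("Component scan (rule = %s): opt = %d", object$rule, object$opt)
    ) +
    ggplot2::theme_minimal()
}

#' Serialize a component scan to JSON
#'
#' @param scan A `component_scan`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_component_scan <- function(scan, path) {
  stopifnot(inherits(scan, "component_scan"))
  jsonlite::write_json(
    list(
      k_range = scan$k_range,
      rule = scan$rule,
      patience = scan$patience,
      entries = purrr::map2(scan$entries$k, scan$entries$dbs,
                            function(k, s) list(k = k, dbs = s)),
      opt = scan$opt,
      terminated_early = scan$terminated_early
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
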