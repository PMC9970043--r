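# Five synthetic-vs-real fidelity indicators plus kernel-density overlays.
# All comparisons are made in original feature units on matched columns.

check_cohort_pair <- function(real, synth, min_d = 1L) {
  r <- as_feature_matrix(real, "real")
  s <- as_feature_matrix(synth, "synth")
  if (ncol(r) != ncol(s)) abort("Cohorts have different numbers of features.")
  if (!is.null(colnames(r)) && !is.null(colnames(s)) &&
      !identical(colnames(r), colnames(s))) {
    if (!setequal(colnames(r), colnames(s))) abort("Cohort feature names differ.")
    s <- s[, colnames(r), drop = FALSE]
  }
  if (ncol(r) < min_d) abort(sprintf("Need at least %d features.", min_d))
  list(real = r, synth = s)
}

#' Coefficient-of-variation difference
#'
#' Per feature, `cV = sd / |mean|` (sample standard deviation); the
#' indicator is the mean over features of `|cV_real - cV_synth|`. Features
#' whose mean magnitude is below `eps` in either cohort are skipped with a
#' warning (the ratio is unstable there).
#'
#' @param real,synth Data frames or matrices with matching features.
#' @param eps Mean-magnitude floor below which a feature is skipped.
#' @return The indicator, with attribute `per_feature` (tibble of feature,
#'   cv_real, cv_synth, diff).
#' @export
cv_difference <- function(real, synth, eps = 1e-8) {
  p <- check_cohort_pair(real, synth)
  cv <- function(x) apply(x, 2L, sd) / abs(colMeans(x))
  mr <- abs(colMeans(p$real))
  ms <- abs(colMeans(p$synth))
  usable <- mr > eps & ms > eps
  if (!all(usable)) {
    warn(sprintf("%d feature(s) skipped in cV (near-zero mean).", sum(!usable)))
  }
  if (!any(usable)) abort("No feature has a usable (non-zero) mean for cV.")
  cvr <- cv(p$real)
  cvs <- cv(p$synth)
  per <- tibble(
    feature = colnames(p$real) %||% paste0("V", seq_len(ncol(p$real))),
    cv_real = unname(cvr), cv_synth = unname(cvs),
    diff = unname(ifelse(usable, abs(cvr - cvs), NA_real_))
  )
  structure(mean(per$diff[usable]), per_feature = per)
}

# correlation matrix with constant columns contributing zero correlation
safe_cor <- function(x) {
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    warn("Constant feature(s): correlation taken as 0.")
  }
  r <- suppressWarnings(cor(x))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

#' Inter-correlation difference
#'
#' Mean absolute entrywise difference between the feature-feature Pearson
#' correlation matrices of the two cohorts, over the strict upper triangle.
#'
#' @inheritParams cv_difference
#' @return Non-negative scalar.
#' @export
inter_correlation_difference <- function(real, synth) {
  p <- check_cohort_pair(real, synth, min_d = 2L)
  dr <- safe_cor(p$real) - safe_cor(p$synth)
  mean(abs(dr[upper.tri(dr)]))
}

# mean absolute off-diagonal entry of the patient-patient correlation
# matrix, computed blockwise so large cohorts never materialize n x n.
mean_abs_row_cor <- function(x, block = 512L) {
  n <- nrow(x)
  if (n < 2L) abort("Need at least 2 rows for patient-patient correlation.")
  # standardize features, then center+normalize each patient vector
  mu <- colMeans(x)
  sds <- apply(x, 2L, sd)
  sds[sds == 0] <- 1
  z <- sweep(sweep(x, 2L, mu), 2L, sds, "/")
  z <- z - rowMeans(z)
  rn <- sqrt(rowSums(z^2))
  rn[rn == 0] <- 1
  v <- z / rn
  total <- 0
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    g <- tcrossprod(v[idx, , drop = FALSE], v)
    g[cbind(seq_along(idx), idx)] <- 0
    total <- total + sum(abs(g))
  }
  total / (n * (n - 1))
}

#' Intra-correlation difference
#'
#' For each cohort, features are standardized and the patient-patient
#' Pearson correlation matrix over feature vectors is summarized as the
#' mean absolute off-diagonal correlation; the indicator is the absolute
#' difference of the two summaries, so cohorts of different sizes remain
#' comparable.
#'
#' @inheritParams cv_difference
#' @return Non-negative scalar.
#' @export
intra_correlation_difference <- function(real, synth) {
  p <- check_cohort_pair(real, synth, min_d = 2L)
  abs(mean_abs_row_cor(p$real) - mean_abs_row_cor(p$synth))
}

# two-sample Kolmogorov-Smirnov statistic (tie-safe sup of ECDF distance)
ks_statistic <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- findInterval(grid, sort(a)) / length(a)
  fb <- findInterval(grid, sort(b)) / length(b)
  max(abs(fa - fb))
}

#' Goodness of fit (mean Kolmogorov-Smirnov statistic)
#'
#' Per feature, the two-sample Kolmogorov-Smirnov statistic (supremum
#' distance between empirical CDFs); the indicator is the mean over
#' features, in `[0, 1]` with lower meaning closer marginals.
#'
#' @inheritParams cv_difference
#' @return Scalar in `[0, 1]`.
#' @export
goodness_of_fit <- function(real, synth) {
  p <- check_cohort_pair(real, synth)
  if (nrow(p$real) == 0L || nrow(p$synth) == 0L) abort("Empty cohort.")
  mean(vapply(seq_len(ncol(p$real)), function(j) {
    ks_statistic(p$real[, j], p$synth[, j])
  }, numeric(1)))
}

#' Histogram Kullback-Leibler divergence
#'
#' Per feature, both cohorts are binned on shared equal-width bins spanning
#' the union range and the divergence is
#' `KL(real || synth) = sum p log(p / q)` in nats; the indicator is the
#' mean over features. Smoothing keeps the ratio finite on empty bins:
#' the default (`"floor"`) adds a small constant `eps` to the bin
#' frequencies and renormalizes, which makes the estimate invariant under
#' row duplication and lets it converge as the synthetic cohort grows with
#' the real one fixed; `"laplace"` instead adds one to the raw counts
#' (whose floor then depends on the cohort sizes). Asymmetric by
#' construction: it penalizes real-data mass falling where the synthetic
#' cohort is sparse. A feature constant in both cohorts contributes 0 with
#' a warning.
#'
#' @inheritParams cv_difference
#' @param bins Number of shared bins (default 50).
#' @param smoothing `"floor"` (default) or `"laplace"`.
#' @param eps Frequency floor used by `smoothing = "floor"`.
#' @return Non-negative scalar (nats).
#' @export
kl_divergence <- function(real, synth, bins = 50L,
                          smoothing = c("floor", "laplace"), eps = 1e-6) {
  p <- check_cohort_pair(real, synth)
  bins <- check_scalar_int(bins, "bins", min = 2L)
  smoothing <- match.arg(smoothing)
  if (nrow(p$real) == 0L || nrow(p$synth) == 0L) abort("Empty cohort.")
  per <- vapply(seq_len(ncol(p$real)), function(j) {
    a <- p$real[, j]
    b <- p$synth[, j]
    lo <- min(a, b)
    hi <- max(a, b)
    if (hi <= lo) {
      warn("Constant feature in both cohorts: KL contribution 0.")
      return(0)
    }
    brk <- seq(lo, hi, length.out = bins + 1L)
    ca <- tabulate(pmin(pmax(findInterval(a, brk, rightmost.closed = TRUE), 1L), bins), bins)
    cb <- tabulate(pmin(pmax(findInterval(b, brk, rightmost.closed = TRUE), 1L), bins), bins)
    if (smoothing == "laplace") {
      pa <- (ca + 1) / (sum(ca) + bins)
      pb <- (cb + 1) / (sum(cb) + bins)
    } else {
      pa <- (ca / sum(ca) + eps) / (1 + bins * eps)
      pb <- (cb / sum(cb) + eps) / (1 + bins * eps)
    }
    sum(pa * log(pa / pb))
  }, numeric(1))
  mean(per)
}

#' Kernel-density overlay for one feature
#'
#' Gaussian kernel density estimates (Silverman's rule-of-thumb bandwidth)
#' of the real and synthetic marginals of one feature, evaluated on a
#' shared 512-point grid spanning the union range. A constant feature is
#' rendered as a narrow Gaussian spike at the constant, with a warning.
#'
#' @inheritParams cv_difference
#' @param feature Column name (or index) present in both cohorts.
#' @param n_grid Number of grid points.
#' @return Tibble with columns `feature`, `grid`, `density_real`,
#'   `density_synth`; each curve integrates to 1 (trapezoid rule) within
#'   0.01.
#' @export
kde_overlay <- function(real, synth, feature, n_grid = 512L) {
  p <- check_cohort_pair(real, synth)
  nms <- colnames(p$real) %||% paste0("V", seq_len(ncol(p$real)))
  j <- if (is.character(feature)) match(feature, nms) else as.integer(feature)
  if (is.na(j) || j < 1L || j > ncol(p$real)) {
    abort(sprintf("Feature '%s' not present in both cohorts.", as.character(feature)))
  }
  a <- p$real[, j]
  b <- p$synth[, j]
  bw_of <- function(x) {
    if (diff(range(x)) == 0) {
      # constant sample: render a narrow Gaussian spike at the constant
      warn(sprintf("Degenerate density for '%s': constant sample.", nms[j]))
      return(max(abs(x[1]), 1) * 1e-3)
    }
    bw <- tryCatch(bw.nrd0(x), error = function(e) 0)
    if (!is.finite(bw) || bw <= 0) bw <- max(diff(range(x)), 1) * 1e-3
    bw
  }
  bwa <- bw_of(a)
  bwb <- bw_of(b)
  lo <- min(a, b) - 3 * max(bwa, bwb)
  hi <- max(a, b) + 3 * max(bwa, bwb)
  da <- density(a, bw = bwa, n = n_grid, from = lo, to = hi)
  db <- density(b, bw = bwb, n = n_grid, from = lo, to = hi)
  tibble(
    feature = nms[j],
    grid = da$x,
    density_real = da$y,
    density_synth = db$y
  )
}

#' Score synthetic-cohort fidelity
#'
#' Computes the five quality indicators comparing a synthetic cohort with
#' the real one it was generated from: mean absolute per-feature
#' coefficient-of-variation difference ([cv_difference()]), inter- and
#' intra-correlation differences ([inter_correlation_difference()],
#' [intra_correlation_difference()]), goodness of fit as the mean
#' Kolmogorov-Smirnov statistic ([goodness_of_fit()]) and mean histogram
#' Kullback-Leibler divergence ([kl_divergence()]); plus a per-feature
#' breakdown. Lower is better for every indicator.
#'
#' @inheritParams kl_divergence
#' @return Object of class `cohort_fidelity` with the five indicators,
#'   `per_feature` tibble (feature, cv_real, cv_synth, ks, kl), and cohort
#'   sizes. The `real` and `synth` cohorts are kept (for [autoplot()]
#'   overlays).
#' @examples
#' real <- tibble::as_tibble(matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c"))))
#' glance(cohort_fidelity(real, real))
#' @export
cohort_fidelity <- function(real, synth, bins = 50L) {
  p <- check_cohort_pair(real, synth, min_d = 2L)
  cvd <- cv_difference(p$real, p$synth)
  per_cv <- attr(cvd, "per_feature")
  nms <- per_cv$feature
  per <- dplyr::mutate(
    per_cv,
    ks = vapply(seq_along(nms), function(j) ks_statistic(p$real[, j], p$synth[, j]), numeric(1)),
    kl = vapply(seq_along(nms), function(j) {
      suppressWarnings(kl_divergence(p$real[, j, drop = FALSE], p$synth[, j, drop = FALSE], bins))
    }, numeric(1))
  )
  structure(
    list(
      cv_diff = as.numeric(cvd),
      inter_corr_diff = inter_correlation_difference(p$real, p$synth),
      intra_corr_diff = intra_correlation_difference(p$real, p$synth),
      gof = goodness_of_fit(p$real, p$synth),
      kl = kl_divergence(p$real, p$synth, bins),
      per_feature = per,
      n_real = nrow(p$real),
      n_synth = nrow(p$synth),
      bins = bins,
      real = p$real,
      synth = p$synth
    ),
    class = "cohort_fidelity"
  )
}

#' @export
print.cohort_fidelity <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cohort_fidelity> real n = %d vs synthetic n = %d\n",
      "  cV difference        %.4f\n",
      "  inter-correlation    %.4f\n",
      "  intra-correlation    %.4f\n",
      "  goodness of fit (KS) %.4f\n",
      "  KL divergence        %.4f\n"
    ),
    x$n_real, x$n_synth, x$cv_diff, x$inter_corr_diff,
    x$intra_corr_diff, x$gof, x$kl
  ))
  invisible(x)
}

#' @describeIn cohort_fidelity Per-feature fidelity table.
#' @param x A `cohort_fidelity` object.
#' @param ... Unused.
#' @method tidy cohort_fidelity
#' @export
tidy.cohort_fidelity <- function(x, ...) x$per_feature

#' @describeIn cohort_fidelity One-row summary with the five indicators.
#' @method glance cohort_fidelity
#' @export
glance.cohort_fidelity <- function(x, ...) {
  tibble(
    cv_diff = x$cv_diff,
    inter_corr_diff = x$inter_corr_diff,
    intra_corr_diff = x$intra_corr_diff,
    gof = x$gof,
    kl = x$kl,
    n_real = x$n_real,
    n_synth = x$n_synth
  )
}

#' @describeIn cohort_fidelity Faceted real-vs-synthetic density overlays.
#' @param object A `cohort_fidelity` object.
#' @param features Optional subset of feature names to draw.
#' @method autoplot cohort_fidelity
#' @export
autoplot.cohort_fidelity <- function(object, features = NULL, ...) {
  nms <- features %||% object$per_feature$feature
  curves <- purrr::map_dfr(nms, function(f) {
    suppressWarnings(kde_overlay(object$real, object$synth, f))
  })
  long <- tidyr::pivot_longer(curves, c("density_real", "density_synth"),
                              names_to = "cohort", values_to = "density")
  long$cohort <- ifelse(long$cohort == "density_real", "real", "synthetic")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$grid, y = .data$density,
                                     colour = .data$cohort)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::scale_colour_manual(values = c(real = "black", synthetic = "magenta3")) +
    ggplot2::labs(x = NULL, y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize a fidelity report to JSON
#'
#' @param report A `cohort_fidelity` object.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_fidelity_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_fidelity"))
  jsonlite::write_json(
    list(
      schema = "virtualcohort/quality-report",
      version = 1L,
      indicators = list(
        cv_diff = report$cv_diff,
        inter_corr_diff = report$inter_corr_diff,
        intra_corr_diff = report$intra_corr_diff,
        gof = report$gof,
        kl = report$kl
      ),
      n_real = report$n_real,
      n_synth = report$n_synth,
      bins = report$bins,
      per_feature = report$per_feature
    ),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
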