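#' Robust feature scaling by median and interquartile range
#'
#' Centers every feature at its median and scales by the interquartile range
#' (Q3 - Q1, linear-interpolation quantiles, `type = 7`), so the scaling is
#' insensitive to outliers hidden in the tails. Features with zero IQR are
#' flagged degenerate and only centered (scale 1).
#'
#' @param data Numeric data frame or matrix, at least 4 rows.
#' @return An object of class `robust_scaler` with fields `center`, `scale`,
#'   `degenerate` and `features`.
#' @examples
#' sc <- fit_robust_scaler(data.frame(x = c(1, 2, 3, 4, 100)))
#' sc$center; sc$scale
#' @export
fit_robust_scaler <- function(data) {
  x <- as_feature_matrix(data, "data")
  if (nrow(x) < 4L) abort("Robust scaling needs at least 4 rows.")
  if (anyNA(x)) abort("`data` must be complete (impute first).")
  qs <- apply(x, 2L, quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
  center <- qs[2L, ]
  iqr <- qs[3L, ] - qs[1L, ]
  degenerate <- iqr <= 0
  scale <- ifelse(degenerate, 1, iqr)
  structure(
    list(
      center = setNames(center, colnames(x)),
      scale = setNames(scale, colnames(x)),
      degenerate = setNames(degenerate, colnames(x)),
      features = colnames(x)
    ),
    class = "robust_scaler"
  )
}

#' @describeIn fit_robust_scaler Apply the fitted scaling; returns a matrix.
#' @param scaler A fitted `robust_scaler`.
#' @export
scale_transform <- function(scaler, data) {
  stopifnot(inherits(scaler, "robust_scaler"))
  x <- as_feature_matrix(data, "data")
  if (!is.null(colnames(x)) && !is.null(scaler$features) &&
      !identical(colnames(x), scaler$features)) {
    if (!setequal(colnames(x), scaler$features)) {
      abort("`data` features do not match the fitted scaler.")
    }
    x <- x[, scaler$features, drop = FALSE]
  }
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' @describeIn fit_robust_scaler Map scaled values back to original units.
#' @export
scale_inverse <- function(scaler, data) {
  stopifnot(inherits(scaler, "robust_scaler"))
  x <- if (is.matrix(data)) data else as_feature_matrix(data, "data")
  sweep(sweep(x, 2L, scaler$scale, "*"), 2L, scaler$center, "+")
}
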