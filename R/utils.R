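# Internal helpers shared across stages.

# Run `expr` under a locally-seeded RNG stream; the caller's RNG state is
# untouched. Offsets keep per-stage streams distinct while derived from one
# user seed; all derived seeds stay below 2^31.
with_seed_offset <- function(seed, offset, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  derived <- (as.integer(seed) + as.integer(offset)) %% 2147483629L
  withr::with_seed(derived, expr)
}

# Coerce a data frame (or matrix) of numeric features to a plain numeric
# matrix, keeping column names. Errors on non-numeric columns.
as_feature_matrix <- function(data, arg = "data") {
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    return(data)
  }
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame or numeric matrix.", arg))
  }
  bad <- names(data)[!vapply(data, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` has non-numeric columns: %s.", arg, paste(bad, collapse = ", ")
    ))
  }
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  m
}

# Row-wise log-sum-exp.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Squared Euclidean cross-distances between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

check_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}
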