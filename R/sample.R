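#' Sample virtual patients from a fitted mixture
#'
#' Draws `n` virtual patient profiles from the posterior of a [fit_bgmm()]
#' model. Mixture weights are composed from the stick-breaking posterior:
#' either one Beta draw per stick (`weight_mode = "posterior_draw"`, the
#' default, so every generated cohort carries Dirichlet-process weight
#' uncertainty) or the expected sticks (`weight_mode = "expected"`). The
#' last stick always absorbs the remaining mass. Component assignments are
#' drawn categorically; each profile is drawn from the Gaussian with the
#' component's posterior-expected mean and moment-matched covariance
#' `(nu_t W_t)^{-1} (beta_t + 1) / beta_t`, then mapped back to original
#' feature units through the robust scaler fitted during training.
#'
#' @param fit A `bgmm` object.
#' @param n Number of virtual patients (`>= 0`).
#' @param seed Integer seed; output is deterministic given
#'   `(fit, n, seed, weight_mode)`.
#' @param weight_mode `"posterior_draw"` or `"expected"`.
#' @return A tibble with the model's feature columns and `n` rows, in
#'   original units, with attributes `components` (integer assignments),
#'   `weights` (the weights used) and `seed`.
#' @examples
#' x <- sample_mixture(
#'   weights = 1, means = list(c(0, 0)),
#'   covariances = list(diag(2)), n = 200, seed = 9
#' )
#' fit <- fit_bgmm(x[1:2], opt = 1, seed = 9)
#' synth <- generate_cohort(fit, n = 100, seed = 9)
#' dim(synth)
#' @export
generate_cohort <- function(fit, n, seed = 1L,
                            weight_mode = c("posterior_draw", "expected")) {
  stopifnot(inherits(fit, "bgmm"))
  weight_mode <- match.arg(weight_mode)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != round(n)) {
    abort("`n` must be a single non-negative integer.")
  }
  n <- as.integer(n)
  T_ <- fit$priors$T
  d <- fit$d
  out <- with_seed_offset(seed, 101L, {
    if (weight_mode == "posterior_draw" && T_ > 1L) {
      V <- rbeta(T_ - 1L, fit$sticks$a[seq_len(T_ - 1L)],
                 fit$sticks$b[seq_len(T_ - 1L)])
      w <- c(V, 1) * cumprod(c(1, 1 - V))
    } else {
      w <- fit$weights
    }
    w <- pmax(w, 0)
    w <- w / sum(w)
    z <- if (n > 0) sample.int(T_, n, replace = TRUE, prob = w) else integer()
    E <- matrix(rnorm(n * d), n, d)
    X <- matrix(0, n, d)
    for (t in seq_len(T_)) {
      idx <- which(z == t)
      if (length(idx) == 0L) next
      Sigma <- chol2inv(chol(fit$nu[t] * fit$W[[t]])) * (fit$beta[t] + 1) / fit$beta[t]
      U <- chol((Sigma + t(Sigma)) / 2)
      X[idx, ] <- E[idx, , drop = FALSE] %*% U +
        matrix(fit$means[t, ], length(idx), d, byrow = TRUE)
    }
    list(X = X, z = z, w = w)
  })
  orig <- scale_inverse(fit$scaler, out$X)
  colnames(orig) <- fit$features
  synth <- as_tibble(as.data.frame(orig, check.names = FALSE))
  attr(synth, "components") <- out$z
  attr(synth, "weights") <- out$w
  attr(synth, "seed") <- as.integer(seed)
  synth
}
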