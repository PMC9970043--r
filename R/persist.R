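#' Save and restore a fitted mixture as JSON
#'
#' Persists the full variational posterior (sticks, Normal-Wishart
#' parameters with matrices flattened row-major), the priors, the robust
#' scaler and the ELBO trace, so a saved model regenerates identical virtual
#' cohorts after [read_bgmm()].
#'
#' @param fit A `bgmm` object.
#' @param path Output JSON file.
#' @return `path` invisibly (`write_bgmm`); a `bgmm` object (`read_bgmm`).
#' @export
write_bgmm <- function(fit, path) {
  stopifnot(inherits(fit, "bgmm"))
  flat_rm <- function(m) as.numeric(t(m)) # row-major
  payload <- list(
    format = "virtualcohort/bgmm",
    version = 1L,
    priors = list(
      T = fit$priors$T,
      gamma = fit$priors$gamma,
      gamma_mode = fit$priors$gamma_mode,
      m0 = as.numeric(fit$priors$m0),
      beta0 = fit$priors$beta0,
      nu0 = fit$priors$nu0,
      W0 = flat_rm(fit$priors$W0),
      d = fit$priors$d
    ),
    posterior = list(
      stick_a = fit$sticks$a,
      stick_b = fit$sticks$b,
      means = flat_rm(fit$means),
      beta = fit$beta,
      nu = fit$nu,
      W = lapply(fit$W, flat_rm),
      weights = fit$weights
    ),
    scaler = list(
      center = as.numeric(fit$scaler$center),
      scale = as.numeric(fit$scaler$scale),
      degenerate = as.logical(fit$scaler$degenerate),
      features = fit$scaler$features
    ),
    elbo_trace = fit$elbo_trace,
    converged = fit$converged,
    n = fit$n,
    d = fit$d,
    seed = fit$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bgmm
#' @export
read_bgmm <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(p$format, "virtualcohort/bgmm")) {
    abort("Not a saved mixture model file.")
  }
  d <- p$d
  T_ <- p$priors$T
  unflat <- function(v, nr, nc) matrix(v, nr, nc, byrow = TRUE)
  features <- p$scaler$features
  scaler <- structure(
    list(
      center = setNames(p$scaler$center, features),
      scale = setNames(p$scaler$scale, features),
      degenerate = setNames(p$scaler$degenerate, features),
      features = features
    ),
    class = "robust_scaler"
  )
  priors <- structure(
    list(
      T = T_, gamma = p$priors$gamma, gamma_mode = p$priors$gamma_mode,
      m0 = p$priors$m0, beta0 = p$priors$beta0, nu0 = p$priors$nu0,
      W0 = unflat(p$priors$W0, d, d), d = d
    ),
    class = "bgmm_priors"
  )
  W <- if (is.list(p$posterior$W)) {
    lapply(p$posterior$W, unflat, nr = d, nc = d)
  } else {
    lapply(seq_len(T_), function(t) unflat(p$posterior$W[t, ], d, d))
  }
  structure(
    list(
      priors = priors,
      sticks = tibble(a = p$posterior$stick_a, b = p$posterior$stick_b),
      means = unflat(p$posterior$means, T_, d),
      beta = p$posterior$beta,
      nu = p$posterior$nu,
      W = W,
      logdetW = vapply(W, function(m) determinant(m, TRUE)$modulus[1], numeric(1)),
      weights = p$posterior$weights,
      responsibilities = NULL,
      elbo_trace = p$elbo_trace,
      converged = p$converged,
      n_iter = length(p$elbo_trace),
      scaler = scaler,
      features = features,
      n = p$n,
      d = d,
      seed = p$seed
    ),
    class = "bgmm"
  )
}
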