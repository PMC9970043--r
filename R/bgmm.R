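# Truncated stick-breaking Dirichlet-process Gaussian mixture, fitted by
# coordinate-ascent variational inference with Normal-Wishart conjugate
# priors. Sticks 1..T-1 carry Beta(1, gamma) priors; the last stick is fixed
# at 1 so the final component absorbs the remaining weight mass.

#' Mixture priors from the data
#'
#' Builds the prior block of the truncated Dirichlet-process Gaussian
#' mixture: truncation `T = opt` components, weight concentration
#' `gamma = exp(-opt)` (the default, capturing the non-linear decay of
#' surplus-component mass as the component count grows) or `gamma = 1/opt`
#' (the linear alternative, kept for comparison), and data-driven
#' Normal-Wishart hyperparameters: prior mean = data mean, mean-precision
#' scale `beta0 = 1`, Wishart degrees of freedom `nu0 = d`, Wishart scale
#' `W0 = inverse(d * diag(cov(data)))` so the prior expected precision
#' `nu0 * W0` matches the per-feature data precision.
#'
#' @param data Numeric matrix or data frame the mixture will be fitted to
#'   (in the space of fitting, i.e. robust-scaled inside [fit_bgmm()]).
#' @param opt Number of mixture components (the truncation level).
#' @param gamma_mode `"exp"` for `exp(-opt)`, `"inverse"` for `1/opt`.
#' @return List of class `bgmm_priors`.
#' @examples
#' bgmm_priors(matrix(rnorm(60), 30), opt = 3)$gamma # exp(-3)
#' @export
bgmm_priors <- function(data, opt, gamma_mode = c("exp", "inverse")) {
  gamma_mode <- match.arg(gamma_mode)
  opt <- check_scalar_int(opt, "opt")
  x <- as_feature_matrix(data, "data")
  d <- ncol(x)
  v <- apply(x, 2L, stats::var)
  v[!is.finite(v) | v <= 0] <- 1
  structure(
    list(
      T = opt,
      gamma = if (gamma_mode == "exp") exp(-opt) else 1 / opt,
      gamma_mode = gamma_mode,
      m0 = colMeans(x),
      beta0 = 1,
      nu0 = max(d, 1 + 1e-8),
      W0 = diag(1 / (max(d, 1) * v), d),
      d = d
    ),
    class = "bgmm_priors"
  )
}

# log normalizer of the Wishart distribution, via log|W|
log_wishart_B <- function(logdetW, nu, d) {
  -0.5 * nu * logdetW - 0.5 * nu * d * log(2) -
    0.25 * d * (d - 1) * log(pi) - sum(lgamma(0.5 * (nu + 1 - seq_len(d))))
}

# responsibility-weighted statistics
vb_stats <- function(X, r) {
  T_ <- ncol(r)
  d <- ncol(X)
  N <- colSums(r)
  Ns <- pmax(N, 1e-12)
  xbar <- crossprod(r, X) / Ns
  S <- vector("list", T_)
  for (t in seq_len(T_)) {
    Xc <- sweep(X, 2L, xbar[t, ])
    S[[t]] <- crossprod(Xc * r[, t], Xc) / Ns[t]
  }
  list(N = N, xbar = xbar, S = S)
}

# closed-form coordinate updates of the variational posterior
vb_mstep <- function(stats, priors) {
  T_ <- priors$T
  d <- priors$d
  N <- stats$N
  W0inv <- chol2inv(chol(priors$W0))
  a <- b <- numeric(max(T_ - 1L, 0L))
  if (T_ > 1L) {
    tail_mass <- rev(cumsum(rev(N)))
    a <- 1 + N[seq_len(T_ - 1L)]
    b <- priors$gamma + tail_mass[seq_len(T_ - 1L) + 1L]
  }
  beta <- priors$beta0 + N
  nu <- priors$nu0 + N
  m <- matrix(0, T_, d)
  W <- vector("list", T_)
  logdetW <- numeric(T_)
  ridged <- FALSE
  for (t in seq_len(T_)) {
    m[t, ] <- (priors$beta0 * priors$m0 + N[t] * stats$xbar[t, ]) / beta[t]
    dx <- stats$xbar[t, ] - priors$m0
    Winv <- W0inv + N[t] * stats$S[[t]] +
      (priors$beta0 * N[t] / (priors$beta0 + N[t])) * tcrossprod(dx)
    Winv <- (Winv + t(Winv)) / 2
    ch <- tryCatch(chol(Winv), error = function(e) NULL)
    if (is.null(ch)) {
      ridged <- TRUE
      ch <- chol(Winv + diag(1e-6, d))
    }
    W[[t]] <- chol2inv(ch)
    logdetW[t] <- -2 * sum(log(diag(ch)))
  }
  if (ridged) warn("Degenerate component covariance; ridge 1e-6 added.")
  list(a = a, b = b, beta = beta, nu = nu, m = m, W = W,
       logdetW = logdetW, N = N)
}

# expectations of log stick weights, length T (last stick fixed at 1)
vb_elog_weights <- function(post, T_) {
  if (T_ == 1L) return(list(Elogw = 0, ElogV = numeric(), Elog1mV = numeric()))
  dig_ab <- digamma(post$a + post$b)
  ElogV <- digamma(post$a) - dig_ab
  Elog1mV <- digamma(post$b) - dig_ab
  Elogw <- c(ElogV, 0) + c(0, cumsum(Elog1mV))
  list(Elogw = Elogw, ElogV = ElogV, Elog1mV = Elog1mV)
}

# E[log |Lambda_t|] under the Wishart posterior
vb_elogdet <- function(post, d) {
  vapply(seq_along(post$nu), function(t) {
    sum(digamma(0.5 * (post$nu[t] + 1 - seq_len(d)))) + d * log(2) + post$logdetW[t]
  }, numeric(1))
}

# responsibility update; returns the n-by-T matrix of normalized r
vb_estep <- function(X, post, priors) {
  n <- nrow(X)
  d <- ncol(X)
  T_ <- priors$T
  ew <- vb_elog_weights(post, T_)
  Elogdet <- vb_elogdet(post, d)
  logrho <- matrix(0, n, T_)
  for (t in seq_len(T_)) {
    U <- chol((post$W[[t]] + t(post$W[[t]])) / 2)
    Z <- sweep(X, 2L, post$m[t, ]) %*% t(U)
    quad <- d / post$beta[t] + post$nu[t] * rowSums(Z^2)
    logrho[, t] <- ew$Elogw[t] + 0.5 * Elogdet[t] -
      0.5 * d * log(2 * pi) - 0.5 * quad
  }
  r <- exp(logrho - row_logsumexp(logrho))
  r / rowSums(r)
}

# full evidence lower bound for the current (r, posterior) pair
vb_elbo <- function(X, r, post, priors) {
  n <- nrow(X)
  d <- ncol(X)
  T_ <- priors$T
  stats <- vb_stats(X, r)
  ew <- vb_elog_weights(post, T_)
  Elogdet <- vb_elogdet(post, d)
  W0inv <- chol2inv(chol(priors$W0))
  logdetW0 <- determinant(priors$W0, logarithm = TRUE)$modulus[1]
  logB0 <- log_wishart_B(logdetW0, priors$nu0, d)

  t1 <- 0
  t5 <- 0
  t6 <- 0
  for (t in seq_len(T_)) {
    Wt <- post$W[[t]]
    dxb <- stats$xbar[t, ] - post$m[t, ]
    t1 <- t1 + 0.5 * stats$N[t] * (
      Elogdet[t] - d / post$beta[t] -
        post$nu[t] * sum(stats$S[[t]] * Wt) -
        post$nu[t] * drop(dxb %*% Wt %*% dxb) -
        d * log(2 * pi)
    )
    dm <- post$m[t, ] - priors$m0
    t5 <- t5 + 0.5 * (d * log(priors$beta0 / (2 * pi)) + Elogdet[t] -
                        d * priors$beta0 / post$beta[t] -
                        priors$beta0 * post$nu[t] * drop(dm %*% Wt %*% dm)) +
      logB0 + 0.5 * (priors$nu0 - d - 1) * Elogdet[t] -
      0.5 * post$nu[t] * sum(W0inv * Wt)
    H_wish <- -log_wishart_B(post$logdetW[t], post$nu[t], d) -
      0.5 * (post$nu[t] - d - 1) * Elogdet[t] + 0.5 * post$nu[t] * d
    t6 <- t6 - (0.5 * Elogdet[t] + 0.5 * d * log(post$beta[t] / (2 * pi)) -
                  0.5 * d - H_wish)
  }
  t2 <- sum(stats$N * ew$Elogw)
  t3 <- -sum(r[r > 0] * log(r[r > 0]))
  t4 <- 0
  if (T_ > 1L) {
    t4 <- sum((priors$gamma - 1) * ew$Elog1mV + log(priors$gamma)) -
      sum((post$a - 1) * ew$ElogV + (post$b - 1) * ew$Elog1mV -
            lbeta(post$a, post$b))
  }
  t1 + t2 + t3 + t4 + t5 + t6
}

# hard or k-means initial responsibilities
vb_init_resp <- function(X, T_, seed, init) {
  n <- nrow(X)
  if (T_ == 1L) return(matrix(1, n, 1L))
  with_seed_offset(seed, 41L, {
    labels <- NULL
    if (init == "kmeans") {
      km <- tryCatch(
        suppressWarnings(kmeans(X, centers = T_, nstart = 5L, iter.max = 50L)),
        error = function(e) NULL
      )
      if (!is.null(km)) labels <- km$cluster
    }
    if (is.null(labels)) labels <- sample.int(T_, n, replace = TRUE)
    r <- matrix(1e-8, n, T_)
    r[cbind(seq_len(n), labels)] <- 1
    r / rowSums(r)
  })
}

#' Fit a Dirichlet-process Gaussian mixture by variational inference
#'
#' Robust-scales the cohort, then alternates closed-form coordinate updates
#' of the truncated stick-breaking posterior (Beta sticks with prior
#' `Beta(1, gamma)`, Normal-Wishart component posteriors) with
#' responsibility updates until the evidence lower bound (ELBO) changes by
#' less than `tol` or `max_iter` is reached. The ELBO is checked to be
#' non-decreasing at every step; a decrease beyond `1e-8` raises an internal
#' consistency error.
#'
#' @param data Data frame or matrix of complete numeric features in original
#'   units; typically the outlier-free rows of a [curate()] result.
#' @param opt Number of components (truncation level), e.g. the `opt` of a
#'   [select_components()] scan; a `component_scan` may be passed directly.
#' @param gamma_mode `"exp"` (`gamma = exp(-opt)`, default) or `"inverse"`
#'   (`gamma = 1/opt`).
#' @param priors Optional [bgmm_priors()] overriding the defaults (built on
#'   the scaled data when `NULL`).
#' @param tol Convergence tolerance on the ELBO change.
#' @param max_iter Maximum iterations.
#' @param seed Integer seed (initialization).
#' @param init `"kmeans"` (default) or `"random"` responsibilities.
#' @return An object of class `bgmm`: posterior parameters (`sticks`,
#'   `means`, `beta`, `nu`, `W` in the scaled space), expected `weights`
#'   (summing to 1, remainder mass on the last stick), `responsibilities`,
#'   `elbo_trace`, the fitted `scaler`, `priors` and bookkeeping fields.
#' @examples
#' x <- sample_mixture(
#'   weights = c(.5, .5), means = list(c(-5, 0), c(5, 0)),
#'   covariances = list(diag(2), diag(2)), n = 300, seed = 4
#' )
#' fit <- fit_bgmm(x[1:2], opt = 2, seed = 4)
#' glance(fit)
#' @export
fit_bgmm <- function(data, opt, gamma_mode = c("exp", "inverse"),
                     priors = NULL, tol = 1e-5, max_iter = 500L,
                     seed = 1L, init = c("kmeans", "random")) {
  gamma_mode <- match.arg(gamma_mode)
  init <- match.arg(init)
  if (inherits(opt, "component_scan")) opt <- opt$opt
  opt <- check_scalar_int(opt, "opt")
  x <- as_feature_matrix(data, "data")
  if (anyNA(x)) abort("`data` must be complete; curate/impute first.")
  n <- nrow(x)
  d <- ncol(x)
  if (n <= d) abort("Need more rows than features to fit the mixture.")
  scaler <- fit_robust_scaler(x)
  X <- scale_transform(scaler, x)
  if (is.null(priors)) {
    priors <- bgmm_priors(X, opt, gamma_mode)
  } else {
    stopifnot(inherits(priors, "bgmm_priors"))
  }
  T_ <- priors$T

  r <- vb_init_resp(X, T_, seed, init)
  elbo_trace <- numeric()
  post <- NULL
  for (iter in seq_len(as.integer(max_iter))) {
    post <- vb_mstep(vb_stats(X, r), priors)
    r <- vb_estep(X, post, priors)
    elbo <- vb_elbo(X, r, post, priors)
    if (length(elbo_trace) > 0) {
      if (elbo < tail(elbo_trace, 1) - 1e-8) {
        abort(sprintf(
          "Internal consistency error: ELBO decreased from %.10f to %.10f.",
          tail(elbo_trace, 1), elbo
        ))
      }
    }
    elbo_trace <- c(elbo_trace, elbo)
    if (length(elbo_trace) > 1 &&
        abs(diff(tail(elbo_trace, 2))) < tol) break
  }
  converged <- length(elbo_trace) > 1 && abs(diff(tail(elbo_trace, 2))) < tol

  # expected stick weights; the last component absorbs the remainder
  if (T_ == 1L) {
    weights <- 1
    sticks <- tibble(a = 1 + post$N, b = priors$gamma)
  } else {
    Ev <- post$a / (post$a + post$b)
    weights <- c(Ev, 1) * cumprod(c(1, 1 - Ev))
    sticks <- tibble(
      a = c(post$a, 1 + post$N[T_]),
      b = c(post$b, priors$gamma)
    )
  }

  structure(
    list(
      priors = priors,
      sticks = sticks,
      means = post$m,
      beta = post$beta,
      nu = post$nu,
      W = post$W,
      logdetW = post$logdetW,
      weights = as.numeric(weights),
      responsibilities = r,
      elbo_trace = elbo_trace,
      converged = converged,
      n_iter = length(elbo_trace),
      scaler = scaler,
      features = scaler$features,
      n = n,
      d = d,
      seed = as.integer(seed)
    ),
    class = "bgmm"
  )
}

#' @export
print.bgmm <- function(x, ...) {
  cat(sprintf(
    "<bgmm> %d components (gamma = %.3g), %d x %d data, ELBO %.4f after %d iterations%s\n",
    x$priors$T, x$priors$gamma, x$n, x$d, tail(x$elbo_trace, 1), x$n_iter,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' @describeIn fit_bgmm Per component-feature posterior summary: expected
#'   weight, posterior mean and marginal variance, in original feature units.
#' @param x A `bgmm` fit.
#' @param ... Unused.
#' @method tidy bgmm
#' @export
tidy.bgmm <- function(x, ...) {
  sc <- x$scaler
  purrr::map_dfr(seq_len(x$priors$T), function(t) {
    Sigma <- chol2inv(chol(x$nu[t] * x$W[[t]])) * (x$beta[t] + 1) / x$beta[t]
    tibble(
      component = t,
      weight = x$weights[t],
      feature = x$features,
      mean = as.numeric(sc$center + sc$scale * x$means[t, ]),
      sd = as.numeric(sc$scale * sqrt(diag(Sigma)))
    )
  })
}

#' @describeIn fit_bgmm One-row fit summary; `n_effective` counts components
#'   with expected weight above 0.01.
#' @method glance bgmm
#' @export
glance.bgmm <- function(x, ...) {
  tibble(
    n = x$n,
    d = x$d,
    n_components = x$priors$T,
    gamma = x$priors$gamma,
    n_effective = sum(x$weights > 0.01),
    elbo = tail(x$elbo_trace, 1),
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' @describeIn fit_bgmm ELBO trace across iterations.
#' @param object A `bgmm` fit.
#' @method autoplot bgmm
#' @export
autoplot.bgmm <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$elbo_trace), elbo = object$elbo_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$elbo)) +
    ggplot2::geom_line(colour = "#2c3e50") +
    ggplot2::geom_point(size = 0.8, colour = "#2c3e50") +
    ggplot2::labs(x = "iteration", y = "evidence lower bound",
                  title = "Variational inference convergence") +
    ggplot2::theme_minimal()
}
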