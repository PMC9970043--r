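# Independent oracles and small data builders shared across tests. The
# oracles are deliberately written as plain loops straight from the
# defining formulas, independent of the package's vectorized paths.

# Davies-Bouldin index, straight from the definition.
db_oracle <- function(x, labels) {
  lv <- unique(labels)
  k <- length(lv)
  cent <- list()
  scat <- numeric(k)
  for (i in seq_len(k)) {
    pts <- x[labels == lv[i], , drop = FALSE]
    cent[[i]] <- colMeans(pts)
    s <- 0
    for (r in seq_len(nrow(pts))) s <- s + sqrt(sum((pts[r, ] - cent[[i]])^2))
    scat[i] <- s / nrow(pts)
  }
  total <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (j == i) next
      m <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (scat[i] + scat[j]) / m)
    }
    total <- total + best
  }
  total / k
}

# One variational responsibility step computed element by element from the
# digamma expectations, looping over points and components.
estep_oracle <- function(X, post, priors) {
  n <- nrow(X)
  d <- ncol(X)
  T_ <- priors$T
  logr <- matrix(0, n, T_)
  for (t in seq_len(T_)) {
    if (T_ == 1L) {
      elogw <- 0
    } else {
      elogw <- 0
      if (t < T_) elogw <- digamma(post$a[t]) - digamma(post$a[t] + post$b[t])
      if (t > 1L) {
        for (s in seq_len(t - 1L)) {
          elogw <- elogw + digamma(post$b[s]) - digamma(post$a[s] + post$b[s])
        }
      }
    }
    elogdet <- d * log(2) + post$logdetW[t]
    for (i in seq_len(d)) elogdet <- elogdet + digamma((post$nu[t] + 1 - i) / 2)
    W <- post$W[[t]]
    for (r in seq_len(n)) {
      dx <- X[r, ] - post$m[t, ]
      quad <- d / post$beta[t] + post$nu[t] * drop(t(dx) %*% W %*% dx)
      logr[r, t] <- elogw + 0.5 * elogdet - 0.5 * d * log(2 * pi) - 0.5 * quad
    }
  }
  out <- matrix(0, n, T_)
  for (r in seq_len(n)) {
    w <- exp(logr[r, ] - max(logr[r, ]))
    out[r, ] <- w / sum(w)
  }
  out
}

# Well-separated Gaussian blobs (separation in units of the within-SD).
make_blobs <- function(n, centers, sd = 1, seed = 1) {
  k <- length(centers)
  w <- rep(1 / k, k)
  covs <- lapply(centers, function(m) diag(sd^2, length(m)))
  sample_mixture(w, centers, covs, n = n, seed = seed)
}

# best label agreement over all cluster-label permutations
perm_agreement <- function(labels, truth) {
  k <- length(unique(truth))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    best <- max(best, mean(p[labels] == truth))
  }
  best
}
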