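# Locally Optimal Block Preconditioned Conjugate Gradient (LOBPCG)
# eigensolver for the k smallest eigenpairs of a symmetric (sparse or dense)
# matrix, solved as a minimum-trace Rayleigh-Ritz iteration over the block
# [X, W, P] (current iterate, preconditioned residual, previous direction).

# Orthonormal basis of the columns of m; rank-deficient columns dropped.
orth_basis <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d[1], .Machine$double.eps)
  s$u[, keep, drop = FALSE]
}

#' LOBPCG eigensolver for the smallest eigenpairs
#'
#' Computes the `k` smallest eigenvalues and eigenvectors of a symmetric
#' positive semi-definite matrix by block preconditioned conjugate-gradient
#' iteration with Rayleigh-Ritz on the subspace spanned by the iterate, the
#' preconditioned residuals and the previous search directions. This solves
#' the minimum-trace problem min tr(X' A X) over orthonormal blocks X.
#'
#' @param A Symmetric matrix (base or `Matrix` sparse).
#' @param k Number of smallest eigenpairs.
#' @param X0 Optional n-by-k start block; random orthonormal if `NULL`.
#' @param tol Convergence tolerance on residual norms:
#'   `||A x - lambda x|| <= tol * max(1, |lambda|)`.
#' @param max_iter Maximum iterations.
#' @param precond Optional vector of Jacobi (diagonal) preconditioner values
#'   applied as `w = r / precond`; `NULL` for none.
#' @param seed Seed for the random start block.
#' @return List with `values` (ascending), `vectors` (n-by-k), `converged`
#'   (logical) and `iterations`.
#' @export
lobpcg <- function(A, k, X0 = NULL, tol = 1e-8, max_iter = 2000L,
                   precond = NULL, seed = 1L) {
  n <- nrow(A)
  k <- check_scalar_int(k, "k")
  if (k >= n) abort("`k` must be smaller than the matrix dimension.")
  with_seed_offset(seed, 17L, lobpcg_run(A, n, k, X0, tol, max_iter, precond))
}

lobpcg_run <- function(A, n, k, X0, tol, max_iter, precond) {
  mult <- function(x) as.matrix(A %*% x)
  if (is.null(X0)) X0 <- matrix(rnorm(n * k), n, k)
  refill <- function(X) {
    if (ncol(X) < k) {
      X <- orth_basis(cbind(X, matrix(rnorm(n * (k - ncol(X))), n)))
    }
    X
  }
  X <- refill(orth_basis(X0))
  P <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    AX <- mult(X)
    H <- crossprod(X, AX)
    H <- (H + t(H)) / 2
    e <- eigen(H, symmetric = TRUE)
    ord <- order(e$values)[seq_len(k)]
    theta <- e$values[ord]
    Y <- e$vectors[, ord, drop = FALSE]
    X <- X %*% Y
    AX <- AX %*% Y
    R <- AX - X %*% diag(theta, k)
    rnorms <- sqrt(colSums(R^2))
    if (all(rnorms <= tol * pmax(1, abs(theta)))) {
      converged <- TRUE
      break
    }
    W <- if (is.null(precond)) R else R / precond
    # Rayleigh-Ritz basis: X plus the components of [W, P] orthogonal to X
    aug <- cbind(W, P)
    aug <- aug - X %*% crossprod(X, aug)
    B <- cbind(X, orth_basis(aug))
    B <- orth_basis(B)
    AB <- mult(B)
    G <- crossprod(B, AB)
    G <- (G + t(G)) / 2
    eg <- eigen(G, symmetric = TRUE)
    ordg <- order(eg$values)[seq_len(k)]
    Yg <- eg$vectors[, ordg, drop = FALSE]
    Xnew <- B %*% Yg
    # conjugate direction: the part of the new iterate outside span(X)
    P <- Xnew - X %*% crossprod(X, Xnew)
    pn <- sqrt(colSums(P^2))
    P <- P[, pn > 1e-12, drop = FALSE]
    if (ncol(P) == 0L) P <- NULL
    X <- refill(orth_basis(Xnew))
  }
  # final Rayleigh-Ritz for clean output
  AX <- mult(X)
  H <- crossprod(X, AX)
  H <- (H + t(H)) / 2
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values)[seq_len(k)]
  list(
    values = e$values[ord],
    vectors = X %*% e$vectors[, ord, drop = FALSE],
    converged = converged,
    iterations = it
  )
}
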