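# Independent oracles used to cross-check the package's solvers.  These are
# deliberately different algorithms from the implementation: proximal
# gradient for the row-sparse solve, generic quasi-Newton minimization for
# the ridge and mixed-prior objectives, and naive per-column least squares
# for the gene loadings.

# Proximal-gradient (FISTA) solver for  min ||Y2 - XB||_F^2 + lambda ||B||_{2,1}.
# The prox of the row-grouped penalty is a group soft-threshold.
prox_grad_l21 <- function(Y2, X, lambda, iters = 20000L, tol = 1e-14) {
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y2)
  L <- 2 * max(eigen(XtX, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / L
  shrink <- function(B) {
    rn <- sqrt(rowSums(B^2))
    fac <- pmax(0, 1 - (lambda * step) / pmax(rn, 1e-300))
    B * fac
  }
  B <- matrix(0, ncol(X), ncol(Y2))
  Z <- B
  tk <- 1
  obj <- function(B) sum((Y2 - X %*% B)^2) + lambda * sum(sqrt(rowSums(B^2)))
  f_prev <- obj(B)
  for (i in seq_len(iters)) {
    Bn <- shrink(Z - step * 2 * (XtX %*% Z - XtY))
    f_new <- obj(Bn)
    if (f_new > f_prev) {        # restart momentum
      tk <- 1
      Bn <- shrink(B - step * 2 * (XtX %*% B - XtY))
      f_new <- obj(Bn)
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- Bn + ((tk - 1) / tn) * (Bn - B)
    done <- abs(f_prev - f_new) <= tol * max(1, f_prev)
    B <- Bn; tk <- tn; f_prev <- f_new
    if (done && i > 50) break
  }
  B
}

# Generic numeric minimizer of a matrix objective via BFGS on the
# vectorized coefficients.
optim_matrix_min <- function(fn, K, G, start = NULL) {
  if (is.null(start)) start <- rep(0, K * G)
  res <- stats::optim(start, function(v) fn(matrix(v, K, G)),
                      method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 2000))
  matrix(res$par, K, G)
}

# Naive masked per-gene least squares: loops entries, uses qr-based
# minimum-norm solve via svd explicitly.
naive_gene_loadings <- function(Y1, X, L1, mask = NULL) {
  if (is.null(mask)) mask <- (!is.na(Y1)) + 0
  K <- nrow(L1)
  B <- matrix(0, K, ncol(Y1))
  for (q in seq_len(ncol(Y1))) {
    s <- which(L1[, q] == 1)
    if (!length(s)) next
    obs <- which(mask[, q] == 1)
    A <- X[obs, s, drop = FALSE]
    y <- Y1[obs, q]
    sv <- svd(A)
    pos <- sv$d > max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
    if (!any(pos)) next
    B[s, q] <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  }
  B
}

# Small random problem generator for solver cross-checks.
random_l21_instance <- function(seed) {
  set.seed(seed)
  n <- sample(10:30, 1)
  k <- sample(2:6, 1)
  g2 <- sample(2:10, 1)
  X <- matrix(rnorm(n * k), n, k)
  X <- sweep(X, 2, pmax(sqrt(colSums(X^2)), 1), "/")
  Y2 <- matrix(rnorm(n * g2), n, g2)
  lmax <- lambda_max(X, Y2)
  list(X = X, Y2 = Y2, lambda = runif(1, 0.05, 0.95) * lmax)
}
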