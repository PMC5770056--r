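# Internal helpers shared across the package.

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_matrix <- function(M, name, allow_na = FALSE) {
  if (!is.matrix(M) || !is.numeric(M))
    stop_invalid(name, " must be a numeric matrix")
  if (!allow_na && any(!is.finite(M)))
    stop_invalid(name, " contains non-finite entries")
  invisible(M)
}

check_binary <- function(M, name) {
  if (!is.matrix(M) || !all(M %in% c(0, 1)))
    stop_invalid(name, " must be a binary (0/1) matrix")
  invisible(M)
}

# Minimum-norm least-squares solve of A b = y via the SVD pseudo-inverse.
# Returns a matrix when y has several columns.
pinv_solve <- function(A, y) {
  y <- as.matrix(y)
  if (ncol(A) == 0L) return(matrix(0, 0L, ncol(y)))
  if (nrow(A) == 0L) return(matrix(0, ncol(A), ncol(y)))
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), ncol(y)))
  u <- sv$u[, pos, drop = FALSE]
  v <- sv$v[, pos, drop = FALSE]
  v %*% ((crossprod(u, y)) / sv$d[pos])
}

# Solve (XtX + lam * W) B = XtY for diagonal weights w (length K), by
# Cholesky with a pseudo-inverse fallback for the unpenalized singular case.
# The system is positive definite whenever lam > 0 and w > 0.
ridge_sys_solve <- function(XtX, XtY, lam, w = NULL) {
  K <- nrow(XtX)
  G <- XtX
  if (lam > 0) {
    if (is.null(w)) w <- rep(1, K)
    diag(G) <- diag(G) + lam * w
    ch <- chol(G)
    return(backsolve(ch, backsolve(ch, XtY, transpose = TRUE)))
  }
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < 1e-7 * max(diag(ch))) {
    B <- pinv_solve(G, XtY)
    attr(B, "min_norm") <- TRUE
    return(B)
  }
  backsolve(ch, backsolve(ch, XtY, transpose = TRUE))
}

# Least-squares solve with a Cholesky fast path and a minimum-norm
# pseudo-inverse fallback for (near-)rank-deficient designs.
ls_solve <- function(A, y) {
  AtA <- crossprod(A)
  ch <- tryCatch(chol(AtA), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < 1e-7 * max(diag(ch)))
    return(pinv_solve(A, y))
  backsolve(ch, backsolve(ch, crossprod(A, y), transpose = TRUE))
}
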