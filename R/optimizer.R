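#' Project the columns of a matrix into the unit ball
#'
#' Euclidean projection onto the feasible set of the pathway-activity
#' matrix: every column whose squared norm exceeds 1 is rescaled to unit
#' norm; feasible columns are returned unchanged.  The operation is
#' idempotent and acts on each column independently.
#'
#' @param X numeric matrix (samples x pathways).
#' @return A matrix of the same shape with all column norms at most 1.
#' @export
project_columns_unit_ball <- function(X) {
  X <- as.matrix(X)
  check_matrix(X, "X")
  nrm2 <- colSums(X^2)
  over <- nrm2 > 1
  if (any(over))
    X[, over] <- sweep(X[, over, drop = FALSE], 2L, sqrt(nrm2[over]), "/")
  X
}

#' Update the pathway-activity matrix by accelerated projected gradient
#'
#' Minimizes \eqn{\|Y - XB\|_F^2} over X subject to unit-ball column
#' constraints, by projected gradient descent with Nesterov acceleration and
#' a monotone safeguard: whenever an accelerated step increases the
#' objective the momentum is restarted from the best iterate, so the
#' returned X never has a larger objective than `X0`.  The gradient is
#' \eqn{2(XBB^T - YB^T)}; in `"auto"` step mode the step size is the inverse
#' Lipschitz constant \eqn{1/(2\sigma_{max}(BB^T))}.
#'
#' @param Y complete (no missing entries) data matrix, typically the
#'   column-concatenation of the completed expression and response blocks.
#' @param B current loadings, the column-concatenation of gene and drug
#'   loadings (K x ncol(Y)).
#' @param X0 feasible starting value (N x K).
#' @param control an [ipad_control()] list.
#' @return A feasible N x K matrix.
#' @export
update_activity <- function(Y, B, X0, control = ipad_control()) {
  Y <- as.matrix(Y); B <- as.matrix(B); X0 <- as.matrix(X0)
  check_matrix(Y, "Y"); check_matrix(B, "B"); check_matrix(X0, "X0")
  if (ncol(X0) != nrow(B) || nrow(X0) != nrow(Y) || ncol(B) != ncol(Y))
    stop_invalid("incompatible shapes in update_activity")
  if (is.numeric(control$step) && control$step <= 0)
    stop_invalid("fixed step size must be positive")

  BBt <- tcrossprod(B)               # K x K
  YBt <- Y %*% t(B)                  # N x K
  cY2 <- sum(Y^2)
  fval <- function(X) cY2 - 2 * sum(X * YBt) + sum((X %*% BBt) * X)
  gradient <- function(X) 2 * (X %*% BBt - YBt)

  L <- 2 * max(eigen(BBt, symmetric = TRUE, only.values = TRUE)$values, 0)
  if (L <= 0) return(X0)             # B = 0: objective does not depend on X
  mu <- if (identical(control$step, "auto")) 1 / L else control$step

  X <- project_columns_unit_ball(X0)
  fX <- fval(X)
  Z <- X
  tk <- 1
  for (it in seq_len(control$max_inner_x)) {
    Xn <- project_columns_unit_ball(Z - mu * gradient(Z))
    fn <- fval(Xn)
    if (fn > fX) {                   # safeguard: restart momentum at X
      tk <- 1
      Xn <- project_columns_unit_ball(X - mu * gradient(X))
      fn <- fval(Xn)
      if (fn > fX) break             # cannot improve: X is (near) stationary
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- Xn + ((tk - 1) / tn) * (Xn - X)
    done <- abs(fX - fn) <= control$rel_tol * max(1, abs(fX))
    X <- Xn; fX <- fn; tk <- tn
    if (done) break
  }
  X
}

#' Update the gene loadings by masked per-gene least squares
#'
#' Solves one ordinary least-squares problem per gene: the loading
#' subvector on the gene's pathway support (the nonzero rows of its
#' membership column) is regressed on the corresponding pathway-activity
#' columns; entries off the support are exactly zero, and rows with
#' unobserved expression for that gene are dropped from its regression.
#' Rank-deficient designs get the minimum-norm solution.
#'
#' @param Y1 expression matrix (N x G1), `NA` allowed at unobserved entries.
#' @param X pathway-activity matrix (N x K).
#' @param L1 binary membership matrix (K x G1).
#' @param mask optional binary observation matrix for `Y1`; defaults to
#'   observed wherever `Y1` is not `NA`.
#' @param pattern_key optional precomputed support signature per gene
#'   column (as produced by `apply(L1, 2, paste, collapse = "")`), reused
#'   across repeated calls with the same membership matrix.
#' @return The K x G1 gene-loading matrix.
#' @export
update_gene_loadings <- function(Y1, X, L1, mask = NULL,
                                 pattern_key = NULL) {
  Y1 <- as.matrix(Y1); X <- as.matrix(X); L1 <- as.matrix(L1)
  check_binary(L1, "L1")
  if (nrow(X) != nrow(Y1) || ncol(L1) != ncol(Y1))
    stop_invalid("incompatible shapes in update_gene_loadings")
  if (is.null(mask)) mask <- (!is.na(Y1)) + 0
  mask <- as.matrix(mask)
  K <- nrow(L1); G1 <- ncol(Y1)
  B1 <- matrix(0, K, G1)
  full <- colSums(mask) == nrow(Y1)

  # Complete columns sharing a support pattern are solved in one batch.
  key <- if (is.null(pattern_key)) apply(L1, 2L, paste, collapse = "")
         else pattern_key
  for (k in unique(key[full])) {
    cols <- which(full & key == k)
    s <- which(L1[, cols[1L]] == 1)
    if (length(s) == 0L) next
    B1[s, cols] <- ls_solve(X[, s, drop = FALSE], Y1[, cols, drop = FALSE])
  }
  for (q in which(!full)) {
    s <- which(L1[, q] == 1)
    if (length(s) == 0L) next
    obs <- which(mask[, q] == 1)
    B1[s, q] <- ls_solve(X[obs, s, drop = FALSE], Y1[obs, q])
  }
  B1
}

#' Ridge-penalized multiresponse regression (closed form)
#'
#' Exact minimizer \eqn{(X^TX + \lambda I)^{-1} X^T Y_2} of
#' \eqn{\|Y_2 - XB\|_F^2 + \lambda \|B\|_2^2}, used for drug-pathway
#' entries carrying a nonzero prior.  At `lambda = 0` with a singular
#' design the minimum-norm least-squares solution is returned, flagged with
#' attribute `"min_norm"`.
#'
#' @param Y2 response matrix (N x G2).
#' @param X design matrix (N x K).
#' @param lambda non-negative ridge penalty.
#' @return The K x G2 coefficient matrix.
#' @export
ridge_solve <- function(Y2, X, lambda) {
  Y2 <- as.matrix(Y2); X <- as.matrix(X)
  check_matrix(Y2, "Y2"); check_matrix(X, "X")
  if (nrow(Y2) != nrow(X)) stop_invalid("X and Y2 must have the same rows")
  if (lambda < 0) stop_invalid("lambda must be non-negative")
  ridge_sys_solve(crossprod(X), crossprod(X, Y2), lambda)
}

#' Row-sparse multiresponse regression by iteratively reweighted ridge
#'
#' Minimizes \eqn{\|Y_2 - XB\|_F^2 + \lambda \|B\|_{2,1}} by repeatedly
#' solving the weighted ridge system \eqn{B \leftarrow (X^TX + \lambda
#' D)^{-1} X^T Y_2} with \eqn{d_{ii} = 1/(2 \max(\|b^i\|_2, \epsilon))},
#' each solve being the exact minimizer of a quadratic majorizer of the
#' L2,1 term, so the penalized objective is non-increasing across
#' reweighting iterations.  Because the reweighting never reaches exact
#' zero, rows whose norm falls below `row_zero_tol` times the largest row
#' norm are zeroed on output.
#'
#' @inheritParams ridge_solve
#' @param lambda non-negative L2,1 penalty.
#' @param control an [ipad_control()] list (`irls_tol`, `max_inner_irls`,
#'   `reweight_eps`, `row_zero_tol`).
#' @return The K x G2 coefficient matrix, with sub-threshold rows exactly
#'   zero.
#' @seealso [lambda_max()] for the smallest penalty at which the solution
#'   is entirely zero.
#' @export
irls_solve_l21 <- function(Y2, X, lambda, control = ipad_control(),
                           init = NULL) {
  Y2 <- as.matrix(Y2); X <- as.matrix(X)
  check_matrix(Y2, "Y2"); check_matrix(X, "X")
  if (nrow(Y2) != nrow(X)) stop_invalid("X and Y2 must have the same rows")
  if (lambda < 0) stop_invalid("lambda must be non-negative")
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y2)
  if (lambda == 0) return(pinv_solve(X, Y2))
  # KKT condition at B = 0: the zero matrix is the exact minimizer when
  # every row of 2 * XtY is within the penalty's subgradient ball.
  if (lambda >= 2 * sqrt(max(rowSums(XtY^2), 0)))
    return(matrix(0, ncol(X), ncol(Y2)))

  B <- irls_init(XtX, XtY, lambda, init)
  fobj <- function(B) sum((Y2 - X %*% B)^2) + lambda * l21_norm(B)
  f0 <- fobj(B)
  for (it in seq_len(control$max_inner_irls)) {
    rn <- pmax(sqrt(rowSums(B^2)), control$reweight_eps)
    B <- ridge_sys_solve(XtX, XtY, lambda, w = 1 / (2 * rn))
    if (irls_kkt_ok(B, XtX, XtY, lambda, control)) break
  }
  B <- threshold_rows(B, control$row_zero_tol)
  # A reinflated warm start can transiently raise the objective; under a
  # tight iteration budget fall back to the (feasible) warm start so the
  # caller's objective never increases.
  if (!is.null(init) && all(dim(init) == dim(XtY)) && fobj(init) < fobj(B))
    B <- init
  B
}

# IRLS starting value: the warm start if given, with exactly-zero rows
# re-inflated from the plain ridge solution so previously inactive rows can
# re-activate (the reweighting escape from the epsilon floor is otherwise
# slower than the iteration budget).
irls_init <- function(XtX, XtY, lambda, init) {
  ridge <- ridge_sys_solve(XtX, XtY, lambda)
  if (is.null(init) || !all(dim(init) == dim(XtY)) || all(init == 0))
    return(ridge)
  B <- init
  zr <- rowSums(B^2) == 0
  if (any(zr)) B[zr, ] <- ridge[zr, , drop = FALSE]
  B
}

# First-order optimality of the L2,1 problem: active rows must satisfy the
# stationarity equation, (near-)zero rows the subgradient bound.  The
# tolerance is relative to lambda, the natural scale of both conditions.
irls_kkt_ok <- function(B, XtX, XtY, lambda, control) {
  G <- 2 * (XtX %*% B - XtY)           # gradient of the residual term
  rn <- sqrt(rowSums(B^2))
  tol <- max(control$irls_tol, 1e-10)
  zero <- rn <= control$row_zero_tol * max(rn, 1)
  ok <- TRUE
  if (any(!zero)) {
    S <- G[!zero, , drop = FALSE] +
      lambda * B[!zero, , drop = FALSE] / rn[!zero]
    ok <- max(sqrt(rowSums(S^2))) <= 10 * tol * lambda
  }
  if (ok && any(zero))
    ok <- max(sqrt(rowSums(G[zero, , drop = FALSE]^2))) <=
      lambda * (1 + tol)
  ok
}

# Zero rows whose norm is below tol * (largest row norm).
threshold_rows <- function(B, tol) {
  rn <- sqrt(rowSums(B^2))
  mx <- max(rn)
  if (mx > 0) B[rn < tol * mx, ] <- 0
  B
}

#' Smallest penalty zeroing the entire drug-loading matrix
#'
#' The subgradient condition at B = 0 gives \eqn{\lambda_{max} = 2 \max_i
#' \|(X^T Y_2)^i\|_2}: for all penalties at or above this value the
#' row-sparse solve returns the all-zero matrix, while strictly below it at
#' least one row is active.  It anchors the upper end of the penalty grid.
#'
#' @inheritParams ridge_solve
#' @return A non-negative scalar.
#' @export
lambda_max <- function(X, Y2) {
  X <- as.matrix(X); Y2 <- as.matrix(Y2)
  check_matrix(X, "X"); check_matrix(Y2, "Y2")
  if (nrow(Y2) != nrow(X)) stop_invalid("X and Y2 must have the same rows")
  2 * sqrt(max(rowSums(crossprod(X, Y2)^2), 0))
}

# Full drug-loading update honoring a (possibly mixed) drug-pathway prior:
# prior-0 entries carry the row-grouped L2,1 penalty, prior-1 entries a
# ridge penalty.  Implemented as entrywise-weighted reweighted ridge solved
# per unique prior column pattern; with an all-zero prior this is exactly
# irls_solve_l21, with an all-one column it is the ridge closed form.
update_drug_loadings <- function(Y2c, X, lambda, L2, control,
                                 init = NULL) {
  if (is.null(L2) || all(L2 == 0))
    return(irls_solve_l21(Y2c, X, lambda, control, init = init))
  if (all(L2 == 1)) return(ridge_solve(Y2c, X, lambda))
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y2c)
  K <- nrow(L2)
  pat <- apply(L2, 2L, paste, collapse = "")
  groups <- split(seq_len(ncol(L2)), pat)

  B <- irls_init(XtX, XtY, lambda, init)
  fobj <- function(B) sum((Y2c - X %*% B)^2) + lambda * b2_penalty(B, L2)
  for (it in seq_len(control$max_inner_irls)) {
    Bnp <- B; Bnp[L2 == 1] <- 0
    rn <- pmax(sqrt(rowSums(Bnp^2)), control$reweight_eps)
    d <- 1 / (2 * rn)
    Bn <- B
    for (cols in groups) {
      p <- L2[, cols[1L]]
      w <- ifelse(p == 1, 1, d)
      Bn[, cols] <- ridge_sys_solve(XtX, XtY[, cols, drop = FALSE], lambda,
                                    w = w)
    }
    done <- max(abs(Bn - B)) <= control$irls_tol * max(1, max(abs(Bn)))
    B <- Bn
    if (done) break
  }
  # Zero out sub-threshold rows of the penalized (prior-0) part only.
  Bnp <- B; Bnp[L2 == 1] <- 0
  rn <- sqrt(rowSums(Bnp^2))
  mx <- max(rn)
  if (mx > 0) {
    for (i in which(rn < control$row_zero_tol * mx)) B[i, L2[i, ] == 0] <- 0
  }
  if (!is.null(init) && all(dim(init) == dim(XtY)) && fobj(init) < fobj(B))
    B <- init
  B
}
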