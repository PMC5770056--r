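test_that("unit-ball projection rescales only infeasible columns", {
  expect_equal(project_columns_unit_ball(matrix(c(2, 0), 2)),
               matrix(c(1, 0), 2))
  feas <- matrix(c(0.3, 0.4), 2)
  expect_identical(project_columns_unit_ball(feas), feas)
  X <- cbind(c(0.3, 0.4), c(3, 4))
  P <- project_columns_unit_ball(X)
  expect_identical(P[, 1], X[, 1])
  expect_equal(sum(P[, 2]^2), 1)
  # idempotent, never increases a column norm
  set.seed(31)
  for (i in 1:10) {
    X <- matrix(rnorm(12, sd = 2), 4, 3)
    P <- project_columns_unit_ball(X)
    expect_equal(project_columns_unit_ball(P), P)
    expect_true(all(colSums(P^2) <= colSums(X^2) + 1e-12))
    expect_true(all(colSums(P^2) <= 1 + 1e-12))
  }
})

test_that("activity update solves the constrained least-squares problem", {
  # identity loadings, feasible optimum: X converges to Y
  set.seed(32)
  Y <- matrix(rnorm(12, sd = 0.3), 4, 3)
  Y <- sweep(Y, 2, pmax(sqrt(colSums(Y^2)), 1), "/")
  X <- update_activity(Y, diag(3), matrix(0, 4, 3),
                       ipad_control(max_inner_x = 200))
  expect_lt(max(abs(X - Y)), 1e-6)
  # zero data pulls X to zero
  B <- matrix(rnorm(6), 2, 3)
  X <- update_activity(matrix(0, 5, 3), B, matrix(rnorm(10, sd = 0.1), 5, 2),
                       ipad_control(max_inner_x = 300, rel_tol = 1e-14))
  expect_lt(max(abs(X)), 1e-4)
  # active constraint: minimize (3 - x1)^2 + x2^2 on the unit disc -> (1, 0)
  X <- update_activity(rbind(c(3, 0), c(0, 0)), rbind(c(1, 0)),
                       matrix(0, 2, 1), ipad_control(max_inner_x = 100))
  expect_equal(X, matrix(c(1, 0), 2), tolerance = 1e-6)
})

test_that("activity update is monotone and respects step configuration", {
  set.seed(33)
  Y <- matrix(rnorm(40), 8, 5)
  B <- matrix(rnorm(15), 3, 5)
  X0 <- project_columns_unit_ball(matrix(rnorm(24), 8, 3))
  f <- function(X) sum((Y - X %*% B)^2)
  X1 <- update_activity(Y, B, X0)
  expect_lte(f(X1), f(X0) + 1e-10)
  expect_true(all(colSums(X1^2) <= 1 + 1e-9))
  expect_error(update_activity(Y, B, X0, ipad_control(step = -0.1)), "step")
})

test_that("gene-loading update is masked per-gene least squares", {
  # identity design reproduces observations on the support
  X <- diag(2)
  expect_equal(update_gene_loadings(matrix(c(5, 7), 2), X,
                                    matrix(c(1, 1), 2)),
               matrix(c(5, 7), 2))
  expect_equal(update_gene_loadings(matrix(c(5, 7), 2), X,
                                    matrix(c(1, 0), 2)),
               matrix(c(5, 0), 2))
  # single regressor of ones: sample mean
  expect_equal(update_gene_loadings(matrix(c(1, 3), 2),
                                    matrix(c(1, 1), 2), matrix(1)),
               matrix(2))
  # empty support leaves the column at zero
  B <- update_gene_loadings(matrix(c(1, 2), 2), X, matrix(c(0, 0), 2))
  expect_equal(B, matrix(0, 2, 1))
})

test_that("gene-loading update matches a naive least-squares oracle", {
  set.seed(34)
  for (i in 1:8) {
    n <- sample(6:15, 1); k <- sample(2:4, 1); g1 <- sample(3:8, 1)
    X <- matrix(rnorm(n * k), n, k)
    L1 <- matrix(rbinom(k * g1, 1, 0.6), k, g1)
    Y1 <- matrix(rnorm(n * g1), n, g1)
    Y1[sample(length(Y1), 3)] <- NA
    expect_equal(update_gene_loadings(Y1, X, L1),
                 naive_gene_loadings(Y1, X, L1), tolerance = 1e-10)
  }
  # rank-deficient design: minimum-norm solution
  Xd <- cbind(c(1, 1), c(1, 1))
  B <- update_gene_loadings(matrix(c(2, 2), 2), Xd, matrix(c(1, 1), 2))
  expect_equal(B, matrix(c(1, 1), 2), tolerance = 1e-10)
})

test_that("ridge solve matches its closed form and normal equations", {
  expect_equal(ridge_solve(matrix(c(2, 4), 2), diag(2), 0),
               matrix(c(2, 4), 2))
  expect_equal(ridge_solve(matrix(c(2, 4), 2), diag(2), 1),
               matrix(c(1, 2), 2))
  set.seed(35)
  X <- matrix(rnorm(30), 10, 3)
  Y2 <- matrix(rnorm(40), 10, 4)
  B <- ridge_solve(Y2, X, 0.5)
  # normal equations to near machine precision
  lhs <- (crossprod(X) + 0.5 * diag(3)) %*% B
  expect_lt(frobenius_norm(lhs - crossprod(X, Y2)),
            1e-10 * frobenius_norm(crossprod(X, Y2)))
  # generic numeric minimizer agrees
  Bopt <- optim_matrix_min(function(B) sum((Y2 - X %*% B)^2) + 0.5 * sum(B^2),
                           3, 4, start = as.numeric(B) + 0.1)
  expect_lt(max(abs(B - Bopt)), 1e-6)
  # lam = 0 on a singular design falls back to the minimum-norm solution
  Xs <- cbind(c(1, 1), c(1, 1))
  Bs <- ridge_solve(matrix(c(2, 2), 2), Xs, 0)
  expect_true(isTRUE(attr(Bs, "min_norm")))
  # fitting x1 + x2 = 2 with minimum norm gives (1, 1)
  expect_equal(unname(Bs)[, 1], c(1, 1), tolerance = 1e-10)
})

test_that("row-sparse solve reproduces closed forms", {
  X <- matrix(c(1, 0), 2)
  Y2 <- rbind(c(3, 4), c(0, 0))
  expect_equal(irls_solve_l21(Y2, X, 0), rbind(c(3, 4)))
  # single-group shrinkage: (1 - lam / (2 ||XtY||)) * XtY with ||XtY|| = 5
  expect_equal(irls_solve_l21(Y2, X, 2), rbind(c(2.4, 3.2)),
               tolerance = 1e-8)
  expect_equal(irls_solve_l21(Y2, X, 10), rbind(c(0, 0)))
  expect_error(irls_solve_l21(Y2, X, -1), "non-negative")
})

test_that("row-sparse solve agrees with a proximal-gradient oracle", {
  for (seed in 1:6) {
    inst <- random_l21_instance(seed)
    B <- irls_solve_l21(inst$Y2, inst$X, inst$lambda)
    Bo <- prox_grad_l21(inst$Y2, inst$X, inst$lambda)
    expect_lt(max(abs(B - Bo)), 1e-5)
  }
})

test_that("IRLS objective never increases with more reweighting steps", {
  inst <- random_l21_instance(42)
  obj <- function(B) sum((inst$Y2 - inst$X %*% B)^2) +
    inst$lambda * l21_norm(B)
  vals <- vapply(1:10, function(m)
    obj(irls_solve_l21(inst$Y2, inst$X, inst$lambda,
                       ipad_control(max_inner_irls = m))), numeric(1))
  expect_true(all(diff(vals) <= 1e-10))
})

test_that("lambda_max marks the exact activation boundary", {
  X <- matrix(c(1, 0), 2)
  Y2 <- rbind(c(3, 4), c(0, 0))
  expect_equal(lambda_max(X, Y2), 10)
  expect_equal(lambda_max(X, Y2 * 0), 0)
  inst <- random_l21_instance(7)
  lmax <- lambda_max(inst$X, inst$Y2)
  expect_true(all(irls_solve_l21(inst$Y2, inst$X, 1.01 * lmax) == 0))
  expect_true(any(irls_solve_l21(inst$Y2, inst$X, 0.99 * lmax) != 0))
})

test_that("mixed drug-prior update minimizes the split penalty", {
  set.seed(36)
  n <- 12; k <- 3; g2 <- 4
  X <- matrix(rnorm(n * k), n, k)
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  Y2 <- matrix(rnorm(n * g2), n, g2)
  L2 <- matrix(0, k, g2)
  L2[2, c(1, 3)] <- 1
  lam <- 0.8
  ctrl <- ipad_control()
  B <- ipad21:::update_drug_loadings(Y2, X, lam, L2, ctrl)
  fn <- function(B) {
    Bnp <- B; Bnp[L2 == 1] <- 0
    sum((Y2 - X %*% B)^2) + lam * (l21_norm(Bnp) + sum(B[L2 == 1]^2))
  }
  Bopt <- optim_matrix_min(fn, k, g2, start = as.numeric(B))
  expect_lte(fn(B), fn(Bopt) + 1e-6)
  # all-one prior reduces to the ridge closed form
  expect_equal(ipad21:::update_drug_loadings(Y2, X, lam,
                                             matrix(1, k, g2), ctrl),
               ridge_solve(Y2, X, lam), tolerance = 1e-12)
  # all-zero prior reduces to the L2,1 solve
  expect_equal(ipad21:::update_drug_loadings(Y2, X, lam,
                                             matrix(0, k, g2), ctrl),
               irls_solve_l21(Y2, X, lam, ctrl), tolerance = 1e-12)
})
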