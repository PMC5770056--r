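test_that("frobenius_norm matches its definition", {
  expect_equal(frobenius_norm(matrix(c(3, 4), 1)), 5)
  expect_equal(frobenius_norm(matrix(0, 3, 3)), 0)
  set.seed(11)
  M <- matrix(rnorm(12), 4, 3)
  brute <- 0
  for (i in 1:4) for (j in 1:3) brute <- brute + M[i, j]^2
  expect_equal(frobenius_norm(M), sqrt(brute))
  expect_error(frobenius_norm(matrix(c(1, NA), 1)), "non-finite")
  expect_error(frobenius_norm(matrix(c(1, Inf), 1)), "non-finite")
})

test_that("l21_norm sums row norms", {
  expect_equal(l21_norm(rbind(c(3, 4), c(0, 0))), 5)
  expect_equal(l21_norm(diag(2)), 2)
  set.seed(12)
  M <- matrix(rnorm(20), 5, 4)
  brute <- 0
  for (i in 1:5) brute <- brute + sqrt(sum(M[i, ]^2))
  expect_equal(l21_norm(M), brute)
  expect_error(l21_norm(matrix(c(1, NaN), 1)), "non-finite")
})

test_that("l21 norm dominates the Frobenius norm, equal iff one row", {
  set.seed(13)
  for (i in 1:20) {
    nr <- sample(2:6, 1)
    M <- matrix(rnorm(nr * 4), nr)
    expect_gte(l21_norm(M) - frobenius_norm(M), -1e-12)
  }
  one_row <- matrix(rnorm(6), 1)
  expect_equal(l21_norm(one_row), frobenius_norm(one_row))
  two_rows <- rbind(c(1, 0), c(0, 1))
  expect_gt(l21_norm(two_rows), frobenius_norm(two_rows))
})

make_instance <- function(seed = 20, n = 8, k = 3, g1 = 10, g2 = 5,
                          missing = FALSE) {
  set.seed(seed)
  X <- qr.Q(qr(matrix(rnorm(n * k), n, k)))
  L1 <- matrix(rbinom(k * g1, 1, 0.5), k, g1)
  L1[1, colSums(L1) == 0] <- 1
  B1 <- L1 * matrix(rnorm(k * g1), k, g1)
  B2 <- matrix(rnorm(k * g2), k, g2)
  Y1 <- X %*% B1 + 0.1 * matrix(rnorm(n * g1), n, g1)
  Y2 <- X %*% B2 + 0.1 * matrix(rnorm(n * g2), n, g2)
  if (missing) {
    Y1[sample(length(Y1), 5)] <- NA
    Y2[sample(length(Y2), 3)] <- NA
  }
  list(data = ipad_data(Y1, Y2),
       prior = ipad_prior(L1, matrix(0, k, g2)),
       model = list(activity = X, gene_loadings = B1, drug_loadings = B2))
}

test_that("objective evaluates residuals plus penalty", {
  inst <- make_instance()
  # perfect fit at lambda 0, using noiseless reconstruction
  d0 <- ipad_data(inst$model$activity %*% inst$model$gene_loadings,
                  inst$model$activity %*% inst$model$drug_loadings)
  expect_equal(ipad_objective(d0, inst$prior, inst$model, 0), 0)
  # zero model: objective is the total energy plus no penalty
  zero <- list(activity = inst$model$activity * 0,
               gene_loadings = inst$model$gene_loadings * 0,
               drug_loadings = inst$model$drug_loadings * 0)
  expect_equal(ipad_objective(inst$data, inst$prior, zero, 1),
               frobenius_norm(inst$data$expression)^2 +
                 frobenius_norm(inst$data$response)^2)
  # term-by-term oracle on a seeded instance
  lam <- 0.7
  r1 <- inst$data$expression - inst$model$activity %*% inst$model$gene_loadings
  r2 <- inst$data$response - inst$model$activity %*% inst$model$drug_loadings
  oracle <- sum(r1^2) + sum(r2^2) + lam * l21_norm(inst$model$drug_loadings)
  expect_equal(ipad_objective(inst$data, inst$prior, inst$model, lam), oracle)
  expect_error(ipad_objective(inst$data, inst$prior,
                              list(activity = inst$model$activity[, -1],
                                   gene_loadings = inst$model$gene_loadings,
                                   drug_loadings = inst$model$drug_loadings),
                              1), "dimensions")
})

test_that("objective ignores masked entries and is permutation invariant", {
  inst <- make_instance(seed = 21, missing = TRUE)
  # lambda = 0: objective equals the masked residual sum exactly
  r1 <- inst$data$expression - inst$model$activity %*% inst$model$gene_loadings
  r2 <- inst$data$response - inst$model$activity %*% inst$model$drug_loadings
  expect_equal(ipad_objective(inst$data, inst$prior, inst$model, 0),
               sum(r1[inst$data$expression_mask == 1]^2) +
                 sum(r2[inst$data$response_mask == 1]^2))
  # simultaneous sample permutation leaves the objective unchanged
  set.seed(1)
  p <- sample(nrow(inst$data$expression))
  dp <- ipad_data(inst$data$expression[p, ], inst$data$response[p, ])
  mp <- inst$model
  mp$activity <- mp$activity[p, ]
  expect_equal(ipad_objective(dp, inst$prior, mp, 0.3),
               ipad_objective(inst$data, inst$prior, inst$model, 0.3))
})

test_that("mixed drug-pathway priors split the penalty into L21 and ridge", {
  inst <- make_instance(seed = 22)
  L2 <- matrix(0, 3, 5)
  L2[1, c(2, 4)] <- 1
  L2[3, 1] <- 1
  prior <- ipad_prior(inst$prior$gene_pathway, L2)
  B2 <- inst$model$drug_loadings
  Bnp <- B2; Bnp[L2 == 1] <- 0
  pen <- l21_norm(Bnp) + sum(B2[L2 == 1]^2)
  expect_equal(ipad_objective(inst$data, prior, inst$model, 2) -
                 ipad_objective(inst$data, prior, inst$model, 0), 2 * pen)
})

test_that("data and prior constructors validate their invariants", {
  expect_error(ipad_data(matrix(1, 3, 2), matrix(1, 4, 2)), "same number")
  expect_error(ipad_data(matrix(1, 2, 2), matrix(1, 2, 2),
                         sample_ids = c("a", "a")), "duplicate")
  expect_error(ipad_data(matrix(1, 2, 2), matrix(1, 2, 2),
                         expression_mask = matrix(1, 3, 2)), "shape")
  expect_error(ipad_prior(matrix(c(1, 0, 0, 0), 2, 2)), "member gene")
  expect_error(ipad_prior(matrix(2, 1, 2)), "binary")
  expect_error(ipad_prior(matrix(1, 2, 3), matrix(0, 3, 4)), "same rows")
  # NA entries enter the mask
  d <- ipad_data(matrix(c(1, NA, 3, 4), 2), matrix(1, 2, 1))
  expect_equal(sum(d$expression_mask), 3)
})

test_that("solver control validates tolerances and step", {
  expect_error(ipad_control(rel_tol = 0), "positive")
  expect_error(ipad_control(step = -1), "step")
  expect_error(ipad_control(reweight_eps = 1e-3, row_zero_tol = 1e-6),
               "smaller")
  ctrl <- ipad_control(step = 0.1)
  expect_equal(ctrl$step, 0.1)
})
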