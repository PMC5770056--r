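#' Fit the joint penalized pathway decomposition
#'
#' Decomposes a gene-expression matrix and a drug-response matrix observed
#' on the same samples as \eqn{Y^{(1)} = XB^{(1)} + E^{(1)}},
#' \eqn{Y^{(2)} = XB^{(2)} + E^{(2)}}, where X holds per-sample pathway
#' activities (columns constrained to the unit ball), the gene loadings
#' \eqn{B^{(1)}} are supported only on the known pathway-gene membership,
#' and the drug loadings \eqn{B^{(2)}} carry an L2,1 row-sparsity penalty
#' with weight `lambda`, so entire pathways drop out of the drug block at
#' once.  The objective is minimized by alternating: soft-impute completion
#' of missing entries, masked per-gene least squares for the gene loadings,
#' (re)weighted ridge solves for the drug loadings, and accelerated
#' projected gradient for the activities.  The masked objective is
#' non-increasing across outer iterations.
#'
#' @param data an [ipad_data] object.
#' @param prior an [ipad_prior] object whose membership matrix has as many
#'   gene columns as `data` has genes.
#' @param lambda non-negative sparsity penalty on the drug loadings.
#' @param control an [ipad_control()] list of solver settings.
#' @param init optional warm start: a list with elements `activity`,
#'   `gene_loadings`, `drug_loadings` (e.g. the `model` of a previous fit).
#' @return An object of class `"ipad_fit"`: a list with elements `model`
#'   (the three matrices), `objective` (the objective trace, initial value
#'   first), `n_iterations`, `converged`, `lambda`, plus the inputs' labels.
#' @examples
#' sim <- ipad_simulate(n = 30, k = 3, g1 = 40, g2 = 8, seed = 1)
#' fit <- ipad(sim$dataset, sim$prior, lambda = 1)
#' fit
#' @seealso [ipad_cv()] to select `lambda`, [ipad_path()] for the
#'   regularization path, [ipad_permute()] for significance.
#' @export
ipad <- function(data, prior, lambda, control = ipad_control(),
                 init = NULL) {
  stopifnot(inherits(data, "ipad_data"), inherits(prior, "ipad_prior"))
  if (!inherits(control, "ipad_control"))
    stop_invalid("control must come from ipad_control()")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop_invalid("lambda must be a single non-negative number")
  Y1 <- data$expression; Y2 <- data$response
  M1 <- data$expression_mask; M2 <- data$response_mask
  G1 <- ncol(Y1); G2 <- ncol(Y2); N <- nrow(Y1)
  L1 <- prior$gene_pathway
  if (ncol(L1) != G1)
    stop_invalid("prior has ", ncol(L1), " genes but data has ", G1)
  L2 <- drug_prior_matrix(prior, G2)
  K <- nrow(L1)

  if (is.null(init)) {
    X <- init_activity(Y1, Y2, M1, M2, K, L1)
    B1 <- matrix(0, K, G1)
    B2 <- matrix(0, K, G2)
  } else {
    X <- project_columns_unit_ball(as.matrix(init$activity))
    B1 <- as.matrix(init$gene_loadings)
    B2 <- as.matrix(init$drug_loadings)
    if (nrow(X) != N || ncol(X) != K || !all(dim(B1) == c(K, G1)) ||
        !all(dim(B2) == c(K, G2)))
      stop_invalid("init has incompatible dimensions")
  }

  model <- list(activity = X, gene_loadings = B1, drug_loadings = B2)
  trace <- ipad_objective(data, prior, model, lambda)
  converged <- FALSE
  iter <- 0L
  l1key <- apply(L1, 2L, paste, collapse = "")
  # Inside the outer loop a handful of reweighting steps per drug-loading
  # update suffice (each reweight descends); a final full-budget pass below
  # polishes the drug loadings to first-order optimality.
  loop_control <- control
  loop_control$max_inner_irls <- min(control$max_inner_irls, 25L)
  one_pass <- function(ctrl) {
    Y2c <- complete_matrix(Y2, X, B2, M2)
    B1 <<- update_gene_loadings(Y1, X, L1, M1, pattern_key = l1key)
    B2 <<- update_drug_loadings(Y2c, X, lambda, L2, ctrl, init = B2)
    # Refresh completions at the current loadings so the complete-data
    # objective majorizes the masked objective for the X step.
    Yc <- cbind(complete_matrix(Y1, X, B1, M1),
                complete_matrix(Y2, X, B2, M2))
    X <<- update_activity(Yc, cbind(B1, B2), X, control)
    model <- list(activity = X, gene_loadings = B1, drug_loadings = B2)
    ipad_objective(data, prior, model, lambda)
  }
  for (it in seq_len(control$max_outer)) {
    iter <- it
    obj <- one_pass(loop_control)
    if (!is.finite(obj))
      stop_invalid("objective became non-finite at outer iteration ", it,
                   "; the fit has diverged")
    prev <- trace[length(trace)]
    trace <- c(trace, obj)
    if (abs(prev - obj) <= control$rel_tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
  }
  if (converged && loop_control$max_inner_irls < control$max_inner_irls) {
    obj <- one_pass(control)
    iter <- iter + 1L
    trace <- c(trace, obj)
  }
  model <- list(activity = X, gene_loadings = B1, drug_loadings = B2)

  dimnames(model$activity) <- list(data$sample_ids, prior$pathway_ids)
  dimnames(model$gene_loadings) <- list(prior$pathway_ids, data$gene_ids)
  dimnames(model$drug_loadings) <- list(prior$pathway_ids, data$drug_ids)
  structure(list(model = model, objective = trace, n_iterations = iter,
                 converged = converged, lambda = lambda, control = control,
                 sample_ids = data$sample_ids, gene_ids = data$gene_ids,
                 drug_ids = data$drug_ids, pathway_ids = prior$pathway_ids,
                 call = match.call()),
            class = "ipad_fit")
}

# Deterministic pathway-anchored initialization: column k starts as the
# leading left singular vector (the "eigengene") of the mean-imputed
# expression of pathway k's member genes, so the initial rotation of the
# activity space already respects the membership constraints.  Columns are
# unit-norm, hence feasible; signs are fixed for reproducibility.
init_activity <- function(Y1, Y2, M1, M2, K, L1) {
  Y1c <- mean_impute(Y1, M1)
  N <- nrow(Y1c)
  X <- matrix(0, N, K)
  for (k in seq_len(K)) {
    s <- which(L1[k, ] == 1)
    block <- Y1c[, s, drop = FALSE]
    if (!any(block != 0)) next
    u <- svd(block, nu = 1, nv = 0)$u[, 1]
    if (sum(u * rowSums(block)) < 0) u <- -u
    X[, k] <- u
  }
  X
}

# Indices of pathways with a nonzero drug-loading row.
active_rows <- function(fit) which(rowSums(fit$model$drug_loadings^2) > 0)

#' @export
print.ipad_fit <- function(x, ...) {
  cat(sprintf(paste0("L2,1-penalized pathway decomposition\n",
                     "  %d samples, %d genes, %d drugs, %d pathways\n"),
              length(x$sample_ids), length(x$gene_ids), length(x$drug_ids),
              length(x$pathway_ids)))
  cat(sprintf("  lambda = %.6g, %d outer iterations (%s)\n", x$lambda,
              x$n_iterations,
              if (x$converged) "converged" else "iteration limit"))
  cat(sprintf("  objective %.6g -> %.6g\n", x$objective[1L],
              x$objective[length(x$objective)]))
  act <- active_rows(x)
  cat(sprintf("  active pathways (nonzero drug-loading rows): %d of %d\n",
              length(act), length(x$pathway_ids)))
  invisible(x)
}

#' @export
summary.ipad_fit <- function(object, ...) {
  B2 <- object$model$drug_loadings
  rn <- sqrt(rowSums(B2^2))
  out <- list(fit = object,
              row_norms = stats::setNames(rn, object$pathway_ids),
              n_active = sum(rn > 0),
              n_pairs = sum(B2 != 0))
  class(out) <- "summary.ipad_fit"
  out
}

#' @export
print.summary.ipad_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  nonzero drug-pathway coefficients: %d\n", x$n_pairs))
  act <- sort(x$row_norms[x$row_norms > 0], decreasing = TRUE)
  if (length(act)) {
    cat("  drug-loading row norms (active pathways):\n")
    print(round(act, 4))
  }
  invisible(x)
}

#' Extract coefficient matrices from a fit
#'
#' @param object an `"ipad_fit"` object.
#' @param matrix which matrix to return: the drug-pathway loadings
#'   (default), the gene loadings, or the pathway activities.
#' @param ... unused.
#' @return The requested matrix with dimnames.
#' @export
coef.ipad_fit <- function(object,
                          matrix = c("drug", "gene", "activity"), ...) {
  switch(match.arg(matrix),
         drug = object$model$drug_loadings,
         gene = object$model$gene_loadings,
         activity = object$model$activity)
}

#' Fitted values of a pathway decomposition
#'
#' @param object an `"ipad_fit"` object.
#' @param block `"expression"`, `"response"`, or `"both"` (column-bound).
#' @param ... unused.
#' @return The reconstruction `X %*% B` for the requested block(s).
#' @export
fitted.ipad_fit <- function(object,
                            block = c("both", "expression", "response"),
                            ...) {
  block <- match.arg(block)
  X <- object$model$activity
  e <- X %*% object$model$gene_loadings
  r <- X %*% object$model$drug_loadings
  switch(block, expression = e, response = r, both = cbind(e, r))
}

#' @export
predict.ipad_fit <- function(object,
                             block = c("both", "expression", "response"),
                             ...) {
  fitted.ipad_fit(object, block = match.arg(block))
}

#' Residuals of a pathway decomposition
#'
#' Observed minus fitted for the requested block; entries unobserved in the
#' original data are `NA`.  Requires the fitting data.
#'
#' @param object an `"ipad_fit"` object.
#' @param data the [ipad_data] object the model was fitted to.
#' @param block `"expression"`, `"response"`, or `"both"`.
#' @param ... unused.
#' @return A residual matrix (or column-bound pair of matrices).
#' @export
residuals.ipad_fit <- function(object, data,
                               block = c("both", "expression", "response"),
                               ...) {
  stopifnot(inherits(data, "ipad_data"))
  block <- match.arg(block)
  e <- data$expression - fitted(object, "expression")
  r <- data$response - fitted(object, "response")
  e[data$expression_mask == 0] <- NA_real_
  r[data$response_mask == 0] <- NA_real_
  switch(block, expression = e, response = r, both = cbind(e, r))
}

#' Plot the objective trace of a fit
#'
#' @param x an `"ipad_fit"` object.
#' @param ... passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.ipad_fit <- function(x, ...) {
  graphics::plot(seq_along(x$objective) - 1L, x$objective, type = "b",
                 xlab = "outer iteration", ylab = "penalized objective",
                 main = "Objective trace", ...)
  invisible(x)
}

#' Simulate data from a fitted decomposition
#'
#' Draws new expression/response pairs \eqn{XB + E} with homoscedastic
#' Gaussian noise whose standard deviation per block is estimated from the
#' observed residuals of the fit.
#'
#' @param object an `"ipad_fit"` object.
#' @param nsim number of datasets to draw.
#' @param seed optional integer seed.
#' @param data the [ipad_data] object the model was fitted to (for the
#'   residual scale).
#' @param ... unused.
#' @return A list of `nsim` lists, each with `expression` and `response`.
#' @export
simulate.ipad_fit <- function(object, nsim = 1, seed = NULL, data, ...) {
  stopifnot(inherits(data, "ipad_data"))
  res <- residuals(object, data, "both")
  n1 <- length(object$gene_ids)
  sd1 <- stats::sd(res[, seq_len(n1)], na.rm = TRUE)
  sd2 <- stats::sd(res[, -seq_len(n1)], na.rm = TRUE)
  e <- fitted(object, "expression")
  r <- fitted(object, "response")
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    list(expression = e + matrix(stats::rnorm(length(e), 0, sd1), nrow(e)),
         response = r + matrix(stats::rnorm(length(r), 0, sd2), nrow(r)))
  }))
}
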