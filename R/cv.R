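#' Held-out residual sum of squares on the response block
#'
#' Sum of squared residuals \eqn{(Y^{(2)} - XB^{(2)})^2} over the entries
#' selected by `holdout`.  Every held-out entry must have been observed in
#' the data.
#'
#' @param data an [ipad_data] object holding the true response values.
#' @param model a fitted model list (`activity`, `drug_loadings`, ...).
#' @param holdout binary matrix of the response shape marking the entries
#'   to evaluate (1 = held out).
#' @return A non-negative scalar.
#' @export
heldout_rss <- function(data, model, holdout) {
  stopifnot(inherits(data, "ipad_data"))
  holdout <- as.matrix(holdout)
  check_binary(holdout, "holdout")
  if (!all(dim(holdout) == dim(data$response)))
    stop_invalid("holdout shape does not match the response block")
  if (any(holdout == 1 & data$response_mask == 0))
    stop_invalid("holdout selects entries missing in the data")
  P <- model$activity %*% model$drug_loadings
  sum(((data$response - P)[holdout == 1])^2)
}

#' Cross-validated selection of the sparsity penalty
#'
#' Ten-fold (by default) cross-validation over the observed entries of the
#' response matrix: the observed entries are partitioned at random into
#' folds, each fold in turn is marked missing, the decomposition is
#' refitted through its soft-impute machinery, and the held-out entries are
#' scored by the residual sum of squares of the response reconstruction.
#' The penalty minimizing the mean held-out RSS is selected, ties going to
#' the larger (sparser) penalty.  Entry-wise folds keep every sample
#' available for the activity estimate and reuse the missing-value
#' machinery unchanged.
#'
#' @inheritParams ipad
#' @param lambdas optional strictly decreasing penalty grid.  By default an
#'   initial fit at `lam_min` anchors the grid at 0.999 times its
#'   [lambda_max()] and [lambda_grid()] supplies `n_lambdas` log-spaced
#'   points down to `lam_min`.
#' @param n_lambdas grid size for the default grid.
#' @param lam_min lower grid endpoint for the default grid.
#' @param nfolds number of folds (default 10).
#' @param seed integer seed making the fold draw (and hence the whole
#'   procedure) reproducible.
#' @return An object of class `"ipad_cv"`: `lambdas`, `fold_rss`
#'   (n_lambdas x nfolds), `mean_rss`, `selected_lambda`, `seed`, `nfolds`.
#' @examples
#' sim <- ipad_simulate(n = 30, k = 3, g1 = 40, g2 = 8, seed = 1)
#' cv <- ipad_cv(sim$dataset, sim$prior, n_lambdas = 4, seed = 1)
#' cv$selected_lambda
#' @export
ipad_cv <- function(data, prior, lambdas = NULL, n_lambdas = 20L,
                    lam_min = 0.1, nfolds = 10L, control = ipad_control(),
                    seed = 1L) {
  stopifnot(inherits(data, "ipad_data"), inherits(prior, "ipad_prior"))
  obs <- which(data$response_mask == 1)
  if (length(obs) < nfolds)
    stop_invalid("need at least ", nfolds, " observed response entries")

  warm <- NULL
  if (is.null(lambdas)) {
    fit0 <- ipad(data, prior, lam_min, control)
    Y2c <- complete_matrix(data$response, fit0$model$activity,
                           fit0$model$drug_loadings, data$response_mask)
    lmax <- lambda_max(fit0$model$activity, Y2c)
    if (lmax <= lam_min)
      stop_invalid("lambda_max of the initial fit is not above lam_min")
    lambdas <- lambda_grid(0.999 * lmax, n_lambdas, lam_min)
    warm <- fit0$model
  }
  lambdas <- as.numeric(lambdas)
  if (any(diff(lambdas) >= 0))
    stop_invalid("lambdas must be strictly decreasing")

  folds <- draw_entry_folds(data$response_mask, nfolds, seed)
  fold_rss <- matrix(NA_real_, length(lambdas), nfolds)
  for (f in seq_len(nfolds)) {
    hold <- matrix(0, nrow(data$response), ncol(data$response))
    hold[folds[[f]]] <- 1
    resp <- data$response
    resp[hold == 1] <- NA_real_
    data_f <- ipad_data(data$expression, resp, data$sample_ids,
                        data$gene_ids, data$drug_ids,
                        expression_mask = data$expression_mask)
    init <- warm
    for (i in seq_along(lambdas)) {
      fit <- ipad(data_f, prior, lambdas[i], control, init = init)
      init <- fit$model
      fold_rss[i, f] <- heldout_rss(data, fit$model, hold)
    }
  }
  mean_rss <- rowMeans(fold_rss)
  sel <- which.min(mean_rss)   # first index = largest lambda on exact ties
  structure(list(lambdas = lambdas, fold_rss = fold_rss,
                 mean_rss = mean_rss, selected_lambda = lambdas[sel],
                 nfolds = as.integer(nfolds), seed = as.integer(seed)),
            class = "ipad_cv")
}

# Partition the observed entries of the response mask into `nfolds` random
# folds (linear indices).  Redraws (bounded) if a fold would wipe out all
# observations of some drug column or sample row.
draw_entry_folds <- function(mask, nfolds, seed, max_retry = 20L) {
  obs <- which(mask == 1)
  nr <- nrow(mask)
  with_seed(seed, {
    for (try in seq_len(max_retry)) {
      assign_f <- sample(rep_len(seq_len(nfolds), length(obs)))
      folds <- split(obs, assign_f)
      ok <- TRUE
      for (f in folds) {
        m <- mask
        m[f] <- 0
        if (any(colSums(m) == 0) || any(rowSums(m) == 0)) { ok <- FALSE; break }
      }
      if (ok) return(folds)
    }
    stop_invalid("could not draw folds leaving every drug and sample ",
                 "with observed entries")
  })
}

#' @export
print.ipad_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over %d penalties\n", x$nfolds,
              length(x$lambdas)))
  cat(sprintf("  grid [%.4g .. %.4g], seed %d\n", x$lambdas[1L],
              x$lambdas[length(x$lambdas)], x$seed))
  cat(sprintf("  selected lambda = %.6g (mean held-out RSS %.6g)\n",
              x$selected_lambda, min(x$mean_rss)))
  invisible(x)
}

#' Plot the cross-validation curve
#'
#' Mean held-out RSS against the penalty (log axis), with the selected
#' penalty marked.
#'
#' @param x an `"ipad_cv"` object.
#' @param ... passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.ipad_cv <- function(x, ...) {
  graphics::plot(x$lambdas, x$mean_rss, type = "b", log = "x",
                 xlim = rev(range(x$lambdas)), xlab = expression(lambda),
                 ylab = "mean held-out RSS", main = "Cross-validation", ...)
  graphics::abline(v = x$selected_lambda, lty = 2)
  invisible(x)
}
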