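#' Logarithmically spaced penalty grid
#'
#' Descending log-spaced grid from `lam_max` down to `lam_min`, both
#' endpoints included.  The default lower endpoint of 0.1 matches the
#' convention of scanning the penalty from the value producing the first
#' nonzero drug-pathway entries down to 0.1.
#'
#' @param lam_max upper endpoint (> `lam_min`).
#' @param n_points number of grid points (>= 2), default 20.
#' @param lam_min positive lower endpoint, default 0.1.
#' @return A strictly decreasing numeric vector of length `n_points`.
#' @export
lambda_grid <- function(lam_max, n_points = 20L, lam_min = 0.1) {
  if (!is.numeric(lam_max) || !is.numeric(lam_min) || lam_min <= 0 ||
      lam_max <= lam_min)
    stop_invalid("need lam_max > lam_min > 0")
  if (n_points < 2) stop_invalid("n_points must be at least 2")
  exp(seq(log(lam_max), log(lam_min), length.out = n_points))
}

#' Regularization path with activation-order ranking
#'
#' Fits the decomposition along a descending penalty grid with warm starts,
#' recording for every drug-pathway pair the largest penalty at which its
#' coefficient is nonzero (its activation penalty).  Pairs activating
#' earlier (at larger penalties) are ranked as more important: the sparsity
#' penalty releases the strongest associations first.
#'
#' @inheritParams ipad
#' @param lambdas strictly decreasing penalty grid, e.g. from
#'   [lambda_grid()].
#' @return An object of class `"ipad_path"`: `lambdas`,
#'   `activation_lambda` (K x G2 matrix, `NA` = never active on the grid),
#'   `activation_order` (data frame of activated pairs ranked by descending
#'   activation penalty, ties broken by descending absolute coefficient at
#'   activation), and `fits` (one `"ipad_fit"` per grid point).
#' @export
ipad_path <- function(data, prior, lambdas, control = ipad_control()) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 1L || any(diff(lambdas) >= 0))
    stop_invalid("lambdas must be strictly decreasing")
  K <- nrow(prior$gene_pathway)
  G2 <- ncol(data$response)
  act_lam <- matrix(NA_real_, K, G2,
                    dimnames = list(prior$pathway_ids, data$drug_ids))
  act_coef <- matrix(NA_real_, K, G2)
  fits <- vector("list", length(lambdas))
  init <- NULL
  for (i in seq_along(lambdas)) {
    fit <- ipad(data, prior, lambdas[i], control, init = init)
    init <- fit$model
    fits[[i]] <- fit
    B2 <- fit$model$drug_loadings
    newly <- is.na(act_lam) & abs(B2) >= control$row_zero_tol
    act_lam[newly] <- lambdas[i]
    act_coef[newly] <- B2[newly]
    }
  on <- which(!is.na(act_lam), arr.ind = TRUE)
  order_df <- data.frame(pathway = prior$pathway_ids[on[, 1L]],
                         drug = data$drug_ids[on[, 2L]],
                         activation_lambda = act_lam[on],
                         coefficient = act_coef[on],
                         stringsAsFactors = FALSE)
  order_df <- order_df[order(-order_df$activation_lambda,
                             -abs(order_df$coefficient)), , drop = FALSE]
  rownames(order_df) <- NULL
  structure(list(lambdas = lambdas, activation_lambda = act_lam,
                 activation_order = order_df, fits = fits),
            class = "ipad_path")
}

#' @export
print.ipad_path <- function(x, n = 10L, ...) {
  cat(sprintf("Regularization path over %d penalties [%.4g .. %.4g]\n",
              length(x$lambdas), x$lambdas[1L],
              x$lambdas[length(x$lambdas)]))
  cat(sprintf("  %d drug-pathway pairs activated\n",
              nrow(x$activation_order)))
  if (nrow(x$activation_order)) {
    cat("  first activations:\n")
    print(utils::head(x$activation_order, n))
  }
  invisible(x)
}

#' @export
plot.ipad_path <- function(x, ...) {
  norms <- vapply(x$fits, function(f)
    sqrt(rowSums(f$model$drug_loadings^2)), numeric(nrow(x$activation_lambda)))
  norms <- matrix(norms, ncol = length(x$lambdas))
  graphics::matplot(x$lambdas, t(norms), type = "l", log = "x",
                    xlim = rev(range(x$lambdas)),
                    xlab = expression(lambda),
                    ylab = "drug-loading row norm",
                    main = "Pathway activation along the penalty path", ...)
  invisible(x)
}
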