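# Empirical p-value counts: fraction of permuted magnitudes at or above the
# observed magnitude (ties count, so 0 is attainable and an observed zero
# coefficient always gets p = 1).
perm_pvalue <- function(observed_abs, permuted_abs) {
  counts <- Reduce(`+`, lapply(permuted_abs,
                               function(a) (a >= observed_abs) + 0))
  counts / length(permuted_abs)
}

#' Permutation test for drug-pathway associations
#'
#' Assesses every drug-pathway coefficient of a fit by a permutation null:
#' for each of `T` permutations the sample rows of the response matrix are
#' shuffled (breaking its link to the pathway activities while preserving
#' every drug's marginal distribution), the decomposition is refitted with
#' the identical penalty and settings, and the absolute refitted
#' coefficients are recorded.  The empirical p-value of a pair is the
#' fraction of permutations whose coefficient magnitude meets or exceeds
#' the observed one.  The penalty is held fixed at the supplied
#' (typically cross-validated) value, and each permutation draws from its
#' own derived seed, so runs are reproducible.
#'
#' @inheritParams ipad
#' @param lambda penalty at which both the observed and the permuted fits
#'   are computed.
#' @param n_perm number of permutations T (default 2000).
#' @param seed base integer seed; permutation t uses `seed + t`.
#' @param fit optional precomputed observed-data fit at `lambda` (saves one
#'   fit).
#' @return An object of class `"ipad_perm"`: `p_values` and `observed_abs`
#'   (K x G2 matrices), `drug_loadings` (observed coefficients),
#'   `n_permutations`, `lambda`, `seed`.
#' @seealso [significant_pairs()] to extract the association table.
#' @export
ipad_permute <- function(data, prior, lambda, n_perm = 2000L,
                         control = ipad_control(), seed = 1L, fit = NULL) {
  stopifnot(inherits(data, "ipad_data"), inherits(prior, "ipad_prior"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop_invalid("n_perm must be at least 1")
  if (is.null(fit)) fit <- ipad(data, prior, lambda, control)
  observed_abs <- abs(fit$model$drug_loadings)

  N <- length(data$sample_ids)
  one_perm <- function(t, reseed = 0L) {
    pfit <- with_seed(seed + t + reseed, {
      idx <- sample.int(N)
      data_t <- ipad_data(data$expression,
                          data$response[idx, , drop = FALSE],
                          data$sample_ids, data$gene_ids, data$drug_ids,
                          expression_mask = data$expression_mask)
      tryCatch(ipad(data_t, prior, lambda, control),
               error = function(e) e)
    })
    if (inherits(pfit, "error")) {
      if (reseed == 0L) return(one_perm(t, reseed = n_perm + 1L))
      stop_invalid("permutation ", t, " failed twice: ",
                   conditionMessage(pfit))
    }
    abs(pfit$model$drug_loadings)
  }
  permuted <- lapply(seq_len(n_perm), one_perm)
  p <- perm_pvalue(observed_abs, permuted)
  dimnames(p) <- dimnames(observed_abs)

  structure(list(p_values = p, observed_abs = observed_abs,
                 drug_loadings = fit$model$drug_loadings,
                 n_permutations = n_perm, lambda = lambda,
                 seed = as.integer(seed),
                 pathway_ids = prior$pathway_ids, drug_ids = data$drug_ids),
            class = "ipad_perm")
}

#' @export
print.ipad_perm <- function(x, ...) {
  cat(sprintf("Permutation test: %d permutations, lambda = %.6g\n",
              x$n_permutations, x$lambda))
  nz <- x$drug_loadings != 0
  cat(sprintf("  nonzero pairs: %d; with p <= 0.05: %d; with p <= 0.005: %d\n",
              sum(nz), sum(nz & x$p_values <= 0.05),
              sum(nz & x$p_values <= 0.005)))
  invisible(x)
}

#' Significant drug-pathway pairs from a permutation test
#'
#' Pairs with a nonzero observed coefficient and an empirical p-value at or
#' below `alpha`, sorted by ascending p-value with ties broken by
#' descending absolute coefficient.  Raw (uncorrected) p-values are used;
#' thresholds of 0.05 and 0.005 are the conventional reporting levels.
#'
#' @param result an `"ipad_perm"` object.
#' @param alpha significance level in (0, 1), default 0.05.
#' @return A data frame with columns `pathway`, `drug`, `coefficient`,
#'   `p_value`.
#' @export
significant_pairs <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "ipad_perm"))
  if (!(alpha > 0 && alpha < 1)) stop_invalid("alpha must be in (0, 1)")
  B2 <- result$drug_loadings
  sel <- which(B2 != 0 & result$p_values <= alpha, arr.ind = TRUE)
  out <- data.frame(pathway = result$pathway_ids[sel[, 1L]],
                    drug = result$drug_ids[sel[, 2L]],
                    coefficient = B2[sel],
                    p_value = result$p_values[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -abs(out$coefficient)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
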