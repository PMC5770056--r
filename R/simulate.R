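#' Generate a synthetic dataset with known pathway structure
#'
#' Draws a ground-truth model with the structure the decomposition assumes
#' and returns data simulated from it: pathway activities X with
#' independent standard-normal entries whose columns are normalized to
#' exactly unit norm (so the unit-ball constraint is active), a random
#' pathway-gene membership with every pathway nonempty (overlaps allowed),
#' gene loadings supported on the membership, a drug-loading matrix with
#' `n_active` nonzero rows and the remaining rows exactly zero, and
#' homoscedastic Gaussian noise added per block.  The drug-pathway prior is
#' the all-zero matrix.
#'
#' @param n,k,g1,g2 numbers of samples, pathways, genes and drugs.
#' @param genes_per_pathway genes assigned to each pathway (default 20,
#'   capped at `g1`).
#' @param n_active number of nonzero drug-loading rows (default 2, at most
#'   `k`).
#' @param signal_scale standard deviation of nonzero loading entries.
#' @param noise_sd standard deviation of the additive noise.
#' @param seed integer seed; the same seed reproduces the object exactly.
#' @return An object of class `"ipad_sim"`: `dataset` ([ipad_data]),
#'   `prior` ([ipad_prior]), `true_model` (list of `activity`,
#'   `gene_loadings`, `drug_loadings`), `active_rows`, `noise_sd`,
#'   `missing_rate` (0 until [inject_missing()] is used), `seed`.
#' @examples
#' sim <- ipad_simulate(n = 40, k = 4, g1 = 60, g2 = 10, seed = 7)
#' sim$active_rows
#' @export
ipad_simulate <- function(n, k, g1, g2, genes_per_pathway = 20L,
                          n_active = 2L, signal_scale = 1, noise_sd = 0.1,
                          seed = 1L) {
  if (n_active > k) stop_invalid("n_active cannot exceed k")
  if (genes_per_pathway < 1L) stop_invalid("genes_per_pathway must be >= 1")
  genes_per_pathway <- min(genes_per_pathway, g1)
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * k), n, k)
    X <- sweep(X, 2L, sqrt(colSums(X^2)), "/")   # exactly unit-norm columns

    L1 <- matrix(0, k, g1)
    for (i in seq_len(k))
      L1[i, sample.int(g1, genes_per_pathway)] <- 1

    B1 <- L1 * matrix(stats::rnorm(k * g1, 0, signal_scale), k, g1)
    B2 <- matrix(0, k, g2)
    act <- sort(sample.int(k, n_active))
    B2[act, ] <- stats::rnorm(n_active * g2, 0, signal_scale)

    Y1 <- X %*% B1 + matrix(stats::rnorm(n * g1, 0, noise_sd), n, g1)
    Y2 <- X %*% B2 + matrix(stats::rnorm(n * g2, 0, noise_sd), n, g2)

    dataset <- ipad_data(Y1, Y2)
    colnames(L1) <- dataset$gene_ids
    L2 <- matrix(0, k, g2, dimnames = list(NULL, dataset$drug_ids))
    prior <- ipad_prior(L1, drug_pathway = L2)
    dimnames(B1) <- list(prior$pathway_ids, dataset$gene_ids)
    dimnames(B2) <- list(prior$pathway_ids, dataset$drug_ids)
    dimnames(X) <- list(dataset$sample_ids, prior$pathway_ids)
    structure(list(dataset = dataset, prior = prior,
                   true_model = list(activity = X, gene_loadings = B1,
                                     drug_loadings = B2),
                   active_rows = act, noise_sd = noise_sd,
                   missing_rate = 0, seed = as.integer(seed)),
              class = "ipad_sim")
  })
}

#' @export
print.ipad_sim <- function(x, ...) {
  cat(sprintf(paste0("Synthetic dataset (seed %d): %d samples, %d genes, ",
                     "%d drugs, %d pathways\n"), x$seed,
              length(x$dataset$sample_ids), length(x$dataset$gene_ids),
              length(x$dataset$drug_ids), length(x$prior$pathway_ids)))
  cat(sprintf("  active drug-loading rows: %s; noise sd %.3g; missing %.0f%%\n",
              paste(x$active_rows, collapse = ", "), x$noise_sd,
              100 * x$missing_rate))
  invisible(x)
}

#' Remove entries completely at random from a synthetic dataset
#'
#' Marks an i.i.d. Bernoulli(`rate`) subset of the entries of both blocks
#' as missing (MCAR), while retaining the withheld true values for later
#' evaluation.  Draws are redone (a bounded number of times) if any sample
#' row or feature column would lose all its observations.
#'
#' @param truth an `"ipad_sim"` object.
#' @param rate missing probability in \[0, 1).
#' @param seed integer seed for the mask draw.
#' @return The modified `"ipad_sim"` object, with `dataset` masked, the
#'   complete matrices kept in `withheld$expression` / `withheld$response`,
#'   and the evaluation masks (1 = withheld) in `withheld$expression_mask`
#'   / `withheld$response_mask`.
#' @export
inject_missing <- function(truth, rate, seed = 1L) {
  stopifnot(inherits(truth, "ipad_sim"))
  if (!(rate >= 0 && rate < 1)) stop_invalid("rate must be in [0, 1)")
  ds <- truth$dataset
  full <- cbind(ds$expression, ds$response)
  g1 <- length(ds$gene_ids)
  if (rate == 0) return(truth)
  mask <- with_seed(seed, {
    for (try in seq_len(50L)) {
      m <- matrix(stats::rbinom(length(full), 1L, 1 - rate), nrow(full))
      if (all(rowSums(m[, seq_len(g1)]) > 0) &&
          all(rowSums(m[, -seq_len(g1)]) > 0) && all(colSums(m) > 0))
        break
      m <- NULL
    }
    if (is.null(m))
      stop_invalid("missing rate leaves rows or columns fully unobserved")
    m
  })
  m1 <- mask[, seq_len(g1), drop = FALSE]
  m2 <- mask[, -seq_len(g1), drop = FALSE]
  truth$withheld <- list(expression = ds$expression,
                         response = ds$response,
                         expression_mask = 1 - m1, response_mask = 1 - m2)
  truth$dataset <- ipad_data(ds$expression, ds$response, ds$sample_ids,
                             ds$gene_ids, ds$drug_ids,
                             expression_mask = m1, response_mask = m2)
  truth$missing_rate <- rate
  truth
}
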