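#' Frobenius norm of a matrix
#'
#' Square root of the sum of squared entries, \eqn{\|M\|_F =
#' \sqrt{\sum_{ij} m_{ij}^2}}.
#'
#' @param M a numeric matrix (or vector, treated as a one-row matrix) with
#'   finite entries.
#' @return A non-negative scalar; zero exactly when `M` is all-zero.
#' @seealso [l21_norm()]
#' @examples
#' frobenius_norm(matrix(c(3, 4), 1))  # 5
#' @export
frobenius_norm <- function(M) {
  if (!is.matrix(M)) M <- matrix(M, nrow = 1L)
  check_matrix(M, "M")
  sqrt(sum(M^2))
}

#' L2,1 norm of a matrix
#'
#' Sum over rows of each row's Euclidean norm, \eqn{\|M\|_{2,1} = \sum_i
#' \|m^i\|_2}.  Penalizing this norm drives entire rows to zero (row
#' sparsity), which is how the model discards whole pathways at once in the
#' drug-pathway loading matrix.  For a single-row matrix it coincides with
#' the Frobenius norm; for a single-column matrix it reduces to the L1 norm.
#'
#' @inheritParams frobenius_norm
#' @return A non-negative scalar.
#' @examples
#' l21_norm(rbind(c(3, 4), c(0, 0)))  # 5
#' l21_norm(diag(2))                  # 2
#' @export
l21_norm <- function(M) {
  if (!is.matrix(M)) M <- matrix(M, nrow = 1L)
  check_matrix(M, "M")
  sum(sqrt(rowSums(M^2)))
}

# Masked residual sum of squares of one data block: unobserved entries
# contribute nothing.
masked_rss <- function(Y, XB, mask) {
  R <- Y - XB
  R[mask == 0] <- 0
  sum(R^2)
}

# Penalty on the drug-pathway loadings: L2,1 over the prior-0 entries
# (grouped by row) plus a squared-L2 (ridge) term on prior-1 entries.
b2_penalty <- function(B2, L2) {
  if (is.null(L2) || all(L2 == 0)) return(l21_norm(B2))
  Bnp <- B2
  Bnp[L2 == 1] <- 0
  l21_norm(Bnp) + sum(B2[L2 == 1]^2)
}

#' Penalized objective of the joint decomposition
#'
#' Evaluates the objective minimized by [ipad()]: the masked squared
#' residuals of both data blocks plus `lambda` times the sparsity penalty on
#' the drug-pathway loadings.  Entries flagged unobserved in the data masks
#' contribute nothing to the residual terms.  With an all-zero drug-pathway
#' prior (the default experimental setting) the penalty is the plain L2,1
#' norm of the drug loadings; entries with prior 1 are instead penalized by
#' their squared L2 norm (ridge), with the L2,1 row groups restricted to the
#' prior-0 entries of each row.
#'
#' @param data an [ipad_data] object.
#' @param prior an [ipad_prior] object.
#' @param model a list with elements `activity` (N x K), `gene_loadings`
#'   (K x G1) and `drug_loadings` (K x G2), as stored in an [ipad()] fit.
#' @param lambda non-negative sparsity parameter.
#' @return The objective value, a non-negative scalar.
#' @export
ipad_objective <- function(data, prior, model, lambda) {
  stopifnot(inherits(data, "ipad_data"), inherits(prior, "ipad_prior"))
  if (lambda < 0) stop_invalid("lambda must be non-negative")
  X <- model$activity
  B1 <- model$gene_loadings
  B2 <- model$drug_loadings
  if (nrow(X) != nrow(data$expression) || ncol(X) != nrow(B1) ||
      ncol(B1) != ncol(data$expression) || ncol(B2) != ncol(data$response) ||
      nrow(B1) != nrow(B2))
    stop_invalid("model dimensions do not match the data")
  Y1 <- data$expression
  Y2 <- data$response
  Y1[data$expression_mask == 0] <- 0
  Y2[data$response_mask == 0] <- 0
  rss <- masked_rss(Y1, X %*% B1, data$expression_mask) +
    masked_rss(Y2, X %*% B2, data$response_mask)
  rss + lambda * b2_penalty(B2, prior$drug_pathway)
}
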