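#' Project a matrix onto an observation mask
#'
#' Entry-wise product with a binary mask: observed entries (mask 1) are kept,
#' the rest are set to 0.  `NA` entries under mask 0 become 0 as well, so the
#' result is always finite when the observed entries are.
#'
#' @param M numeric matrix.
#' @param mask binary matrix of the same shape (1 = observed).
#' @return A matrix of the same shape.
#' @export
apply_mask <- function(M, mask) {
  M <- as.matrix(M)
  mask <- as.matrix(mask)
  check_binary(mask, "mask")
  if (!all(dim(M) == dim(mask))) stop_invalid("mask shape does not match M")
  M[mask == 0] <- 0
  M
}

#' Soft-impute completion of a partially observed matrix
#'
#' Returns the observed entries of `Y` verbatim and fills the unobserved
#' entries with the current model prediction `X %*% B`.  Inside the
#' alternating fit this is the soft-impute step that lets the
#' pathway-activity update treat the data block as complete: plugging the
#' prediction into the missing cells makes the complete-data objective a
#' majorizer of the masked objective at the current iterate.
#'
#' @param Y numeric matrix, possibly with `NA` at unobserved entries.
#' @param X,B current factors; `X %*% B` must match the shape of `Y`.
#' @param mask binary observation matrix (1 = observed).
#' @return A complete (finite) matrix of the same shape as `Y`.
#' @export
complete_matrix <- function(Y, X, B, mask) {
  Y <- as.matrix(Y)
  mask <- as.matrix(mask)
  check_binary(mask, "mask")
  if (!all(dim(Y) == dim(mask))) stop_invalid("mask shape does not match Y")
  if (all(mask == 1)) return(Y)
  P <- X %*% B
  if (!all(dim(P) == dim(Y))) stop_invalid("X %*% B shape does not match Y")
  if (any(!is.finite(P)))
    stop_invalid("model prediction is non-finite; the fit has diverged")
  Y[mask == 0] <- P[mask == 0]
  Y
}

# Column-mean initial fill used before any model exists; fully missing
# columns are filled with zero.
mean_impute <- function(Y, mask) {
  if (all(mask == 1)) return(Y)
  mu <- colSums(apply_mask(Y, mask)) / pmax(colSums(mask), 1)
  mu[colSums(mask) == 0] <- 0
  idx <- which(mask == 0, arr.ind = TRUE)
  Y[idx] <- mu[idx[, 2L]]
  Y
}
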