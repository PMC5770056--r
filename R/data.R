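#' Paired expression / drug-response data container
#'
#' Bundles a gene-expression matrix and a drug-response matrix measured on
#' the same samples, together with observation masks.  Matrices are stored
#' samples x features.  `NA` (and `NaN`) entries are taken as unobserved and
#' excluded from every residual computation; explicit masks may also be
#' supplied (entries masked 0 are set to `NA`).
#'
#' @param expression numeric matrix, N samples x G1 genes.
#' @param response numeric matrix, N samples x G2 drugs; must have the same
#'   number of rows as `expression`.
#' @param sample_ids,gene_ids,drug_ids optional character vectors of unique
#'   labels; defaults are taken from dimnames or generated.
#' @param expression_mask,response_mask optional binary matrices (1 =
#'   observed) of the same shapes as their matrices.
#' @return An object of class `"ipad_data"`: a list with the two matrices,
#'   their masks, and the three label vectors.
#' @examples
#' d <- ipad_data(matrix(rnorm(20), 5), matrix(rnorm(10), 5))
#' dim(d$expression)
#' @export
ipad_data <- function(expression, response, sample_ids = NULL,
                      gene_ids = NULL, drug_ids = NULL,
                      expression_mask = NULL, response_mask = NULL) {
  expression <- as.matrix(expression)
  response <- as.matrix(response)
  check_matrix(expression, "expression", allow_na = TRUE)
  check_matrix(response, "response", allow_na = TRUE)
  if (nrow(expression) != nrow(response))
    stop_invalid("expression and response must have the same number of rows")
  if (any(is.infinite(expression)) || any(is.infinite(response)))
    stop_invalid("infinite entries are not allowed")

  default_ids <- function(given, dn, prefix, n) {
    ids <- if (!is.null(given)) as.character(given)
    else if (!is.null(dn)) dn
    else paste0(prefix, seq_len(n))
    if (length(ids) != n) stop_invalid("label length does not match matrix")
    if (anyDuplicated(ids))
      stop_invalid("duplicate label: ", ids[duplicated(ids)][1L])
    ids
  }
  sample_ids <- default_ids(sample_ids, rownames(expression), "S",
                            nrow(expression))
  gene_ids <- default_ids(gene_ids, colnames(expression), "G",
                          ncol(expression))
  drug_ids <- default_ids(drug_ids, colnames(response), "D", ncol(response))

  build_mask <- function(M, mask, name) {
    if (is.null(mask)) mask <- matrix(1, nrow(M), ncol(M))
    mask <- as.matrix(mask)
    check_binary(mask, paste0(name, "_mask"))
    if (!all(dim(mask) == dim(M)))
      stop_invalid(name, "_mask shape does not match ", name)
    mask[is.na(M)] <- 0
    mask
  }
  expression_mask <- build_mask(expression, expression_mask, "expression")
  response_mask <- build_mask(response, response_mask, "response")
  expression[expression_mask == 0] <- NA_real_
  response[response_mask == 0] <- NA_real_
  dimnames(expression) <- list(sample_ids, gene_ids)
  dimnames(response) <- list(sample_ids, drug_ids)
  dimnames(expression_mask) <- dimnames(expression)
  dimnames(response_mask) <- dimnames(response)

  structure(list(expression = expression, response = response,
                 expression_mask = expression_mask,
                 response_mask = response_mask,
                 sample_ids = sample_ids, gene_ids = gene_ids,
                 drug_ids = drug_ids),
            class = "ipad_data")
}

#' @export
print.ipad_data <- function(x, ...) {
  cat(sprintf("ipad_data: %d samples, %d genes, %d drugs\n",
              length(x$sample_ids), length(x$gene_ids), length(x$drug_ids)))
  miss <- function(m) mean(m == 0)
  cat(sprintf("  missing: %.1f%% expression, %.1f%% response\n",
              100 * miss(x$expression_mask), 100 * miss(x$response_mask)))
  invisible(x)
}

#' Pathway membership priors
#'
#' The binary prior knowledge of the model: which genes belong to which
#' pathway (constraining the support of the gene loadings) and, optionally,
#' which drug-pathway pairs carry a ridge rather than a row-sparsity
#' penalty.  The drug-pathway prior defaults to the all-zero matrix, the
#' setting used throughout the package's intended experiments.
#'
#' @param gene_pathway binary K x G1 matrix; every row (pathway) must
#'   contain at least one 1.
#' @param drug_pathway optional binary K x G2 matrix; `NULL` or missing
#'   means all-zero (constructed lazily when the data are seen).
#' @param pathway_ids optional character vector of K unique pathway labels.
#' @return An object of class `"ipad_prior"`.
#' @export
ipad_prior <- function(gene_pathway, drug_pathway = NULL,
                       pathway_ids = NULL) {
  gene_pathway <- as.matrix(gene_pathway)
  check_binary(gene_pathway, "gene_pathway")
  if (any(rowSums(gene_pathway) == 0))
    stop_invalid("every pathway must contain at least one member gene")
  K <- nrow(gene_pathway)
  if (!is.null(drug_pathway)) {
    drug_pathway <- as.matrix(drug_pathway)
    check_binary(drug_pathway, "drug_pathway")
    if (nrow(drug_pathway) != K)
      stop_invalid("gene_pathway and drug_pathway must have the same rows")
  }
  pathway_ids <- if (!is.null(pathway_ids)) as.character(pathway_ids)
  else if (!is.null(rownames(gene_pathway))) rownames(gene_pathway)
  else paste0("P", seq_len(K))
  if (length(pathway_ids) != K || anyDuplicated(pathway_ids))
    stop_invalid("pathway_ids must be K unique labels")
  rownames(gene_pathway) <- pathway_ids
  if (!is.null(drug_pathway)) rownames(drug_pathway) <- pathway_ids
  structure(list(gene_pathway = gene_pathway, drug_pathway = drug_pathway,
                 pathway_ids = pathway_ids),
            class = "ipad_prior")
}

#' @export
print.ipad_prior <- function(x, ...) {
  cat(sprintf("ipad_prior: %d pathways x %d genes", nrow(x$gene_pathway),
              ncol(x$gene_pathway)))
  if (!is.null(x$drug_pathway))
    cat(sprintf(", drug prior with %d nonzero entries",
                sum(x$drug_pathway)))
  cat("\n")
  invisible(x)
}

# Materialize the drug-pathway prior as a K x G2 matrix (all-zero default).
drug_prior_matrix <- function(prior, G2) {
  if (is.null(prior$drug_pathway)) return(matrix(0, nrow(prior$gene_pathway), G2))
  if (ncol(prior$drug_pathway) != G2)
    stop_invalid("drug_pathway prior has the wrong number of drugs")
  prior$drug_pathway
}

#' Solver settings for the alternating optimizer
#'
#' @param max_outer maximum outer (alternating) iterations.
#' @param max_inner_x maximum accelerated projected-gradient steps per
#'   pathway-activity update.
#' @param max_inner_irls maximum reweighting iterations per drug-loading
#'   update.
#' @param rel_tol relative objective-change threshold stopping the outer
#'   loop (and the inner loops).
#' @param irls_tol relative-change threshold for the reweighted ridge
#'   iterations; tighter than `rel_tol` so row limits are well resolved.
#' @param step either `"auto"` (inverse Lipschitz step, recomputed from the
#'   current loadings) or a fixed positive step size.
#' @param reweight_eps floor on row norms in the reweighting matrix D,
#'   guarding the weights against division by zero.
#' @param row_zero_tol relative threshold below which a drug-loading row is
#'   reported as exactly zero (rows with norm `< row_zero_tol * max row
#'   norm` are zeroed on output).  Must exceed `reweight_eps`.
#' @return A list of class `"ipad_control"`.
#' @export
ipad_control <- function(max_outer = 500L, max_inner_x = 50L,
                         max_inner_irls = 2000L, rel_tol = 1e-6,
                         irls_tol = 1e-9, step = "auto",
                         reweight_eps = 1e-10, row_zero_tol = 1e-6) {
  if (!(identical(step, "auto") || (is.numeric(step) && step > 0)))
    stop_invalid("step must be \"auto\" or a positive number")
  if (rel_tol <= 0 || irls_tol <= 0 || reweight_eps <= 0 || row_zero_tol <= 0)
    stop_invalid("tolerances must be positive")
  if (reweight_eps >= row_zero_tol)
    stop_invalid("reweight_eps must be smaller than row_zero_tol")
  if (max_outer < 1 || max_inner_x < 1 || max_inner_irls < 1)
    stop_invalid("iteration limits must be positive integers")
  structure(list(max_outer = as.integer(max_outer),
                 max_inner_x = as.integer(max_inner_x),
                 max_inner_irls = as.integer(max_inner_irls),
                 rel_tol = rel_tol, irls_tol = irls_tol, step = step,
                 reweight_eps = reweight_eps, row_zero_tol = row_zero_tol),
            class = "ipad_control")
}
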