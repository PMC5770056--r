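#' Read a numeric matrix from a labelled TSV file
#'
#' Expects a header row of feature IDs and a first column of sample IDs.
#' Empty fields, `NA` and `NaN` (case-insensitive) are read as unobserved
#' (mask 0).  The matrix is returned in samples x features orientation
#' regardless of the on-disk layout.
#'
#' @param path file path.
#' @param orientation `"samples_by_features"` (default) if rows on disk are
#'   samples, `"features_by_samples"` if the file is transposed.
#' @return A list with `values` (numeric matrix, `NA` at unobserved
#'   entries), `sample_ids`, `feature_ids`, and `mask` (binary, 1 =
#'   observed).
#' @export
read_matrix_tsv <- function(path,
                            orientation = c("samples_by_features",
                                            "features_by_samples")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_invalid("file has no data rows: ", path)
  # strsplit drops trailing empty fields; pad to the tab count so a line
  # ending in a missing value keeps its full width
  fields <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f)
  width <- lengths(gregexpr("\t", lines, fixed = TRUE))
  width[!grepl("\t", lines, fixed = TRUE)] <- 0L
  fields <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < width[i] + 1L) c(f, rep("", width[i] + 1L - length(f)))
    else f
  })
  header <- fields[[1L]]
  ncol_expected <- length(header)
  col_ids <- header[-1L]
  if (anyDuplicated(col_ids))
    stop_invalid("duplicate column ID in header: ",
                 col_ids[duplicated(col_ids)][1L])
  n <- length(lines) - 1L
  row_ids <- character(n)
  values <- matrix(NA_real_, n, length(col_ids))
  for (i in seq_len(n)) {
    f <- fields[[i + 1L]]
    if (length(f) != ncol_expected)
      stop_invalid("line ", i + 1L, ": expected ", ncol_expected,
                   " fields, found ", length(f))
    row_ids[i] <- f[1L]
    payload <- f[-1L]
    missing <- payload == "" | tolower(payload) %in% c("na", "nan")
    num <- suppressWarnings(as.numeric(payload))
    bad <- is.na(num) & !missing
    if (any(bad))
      stop_invalid("line ", i + 1L, ": non-numeric value \"",
                   payload[which(bad)[1L]], "\"")
    num[missing] <- NA_real_
    values[i, ] <- num
  }
  if (anyDuplicated(row_ids))
    stop_invalid("duplicate row ID: ", row_ids[duplicated(row_ids)][1L])
  dimnames(values) <- list(row_ids, col_ids)
  if (orientation == "features_by_samples") values <- t(values)
  mask <- (!is.na(values)) + 0
  list(values = values, sample_ids = rownames(values),
       feature_ids = colnames(values), mask = mask)
}

#' Write a labelled numeric matrix as TSV
#'
#' Inverse of [read_matrix_tsv()]: header row of column IDs (first header
#' cell `id_name`), one row per sample, unobserved (`NA`) entries written
#' as `NA`.  Numbers are printed with 17 significant digits so a
#' write-then-read round trip reproduces the doubles bit-exactly.
#'
#' @param M numeric matrix with dimnames (or labels generated on write).
#' @param path output file path.
#' @param id_name label of the first header cell.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path, id_name = "id") {
  M <- as.matrix(M)
  rn <- rownames(M); if (is.null(rn)) rn <- paste0("S", seq_len(nrow(M)))
  cn <- colnames(M); if (is.null(cn)) cn <- paste0("V", seq_len(ncol(M)))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  body <- vapply(seq_len(nrow(M)), function(i)
    paste(c(rn[i], fmt(M[i, ])), collapse = "\t"), character(1L))
  writeLines(c(paste(c(id_name, cn), collapse = "\t"), body), path)
  invisible(path)
}

#' Read pathway gene sets from a GMT file
#'
#' Standard GMT layout: one gene set per line, tab-separated as set name,
#' description, then member genes.  Builds the binary pathway-gene
#' membership matrix over the supplied gene universe; genes absent from
#' `gene_ids` are ignored (their count is reported in attribute
#' `"n_ignored"`), and sets with no gene in the universe are dropped with a
#' warning.
#'
#' @param path GMT file path.
#' @param gene_ids character vector: the gene universe (column order of the
#'   membership matrix).
#' @return An [ipad_prior] whose `gene_pathway` matrix has one row per
#'   retained set, with attribute `"n_ignored"` (genes not in the
#'   universe, counted with multiplicity across sets).
#' @export
read_gmt <- function(path, gene_ids) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_invalid("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_all <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(names_all))
    stop_invalid("duplicate gene-set name: ",
                 names_all[duplicated(names_all)][1L])
  rows <- list()
  ignored <- 0L
  dropped <- character(0L)
  for (f in fields) {
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    hit <- genes %in% gene_ids
    ignored <- ignored + sum(!hit)
    if (!any(hit)) {
      dropped <- c(dropped, f[1L])
      next
    }
    row <- as.numeric(gene_ids %in% genes[hit])
    rows[[f[1L]]] <- row
  }
  if (length(dropped))
    warning("dropped ", length(dropped),
            " gene set(s) with no gene in the universe: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (!length(rows))
    stop_invalid("no gene set overlaps the supplied gene universe")
  L1 <- do.call(rbind, rows)
  colnames(L1) <- gene_ids
  prior <- ipad_prior(L1, pathway_ids = names(rows))
  attr(prior, "n_ignored") <- ignored
  prior
}

#' Assemble the drug-pathway association table
#'
#' One row per reported drug-pathway pair combining the fitted
#' coefficient, the activation penalty from a regularization path (if
#' supplied), and the permutation p-value (if supplied).  Pairs are
#' reported when their coefficient is nonzero or they activated on the
#' path; rows are ordered by ascending p-value, ties broken by descending
#' absolute coefficient (pairs without p-values sort last).
#'
#' @param fit an `"ipad_fit"` object.
#' @param perm optional `"ipad_perm"` object for the same data and penalty.
#' @param path optional `"ipad_path"` object supplying activation
#'   penalties.
#' @param alpha significance level for the `significant` flag.
#' @return A data frame with columns `drug`, `pathway`, `coefficient`,
#'   `activation_lambda`, `p_value`, `significant`.
#' @export
association_table <- function(fit, perm = NULL, path = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "ipad_fit"))
  B2 <- fit$model$drug_loadings
  keep <- B2 != 0
  if (!is.null(path)) keep <- keep | !is.na(path$activation_lambda)
  sel <- which(keep, arr.ind = TRUE)
  tab <- data.frame(
    drug = fit$drug_ids[sel[, 2L]],
    pathway = fit$pathway_ids[sel[, 1L]],
    coefficient = B2[sel],
    activation_lambda = if (is.null(path)) NA_real_
                        else path$activation_lambda[sel],
    p_value = if (is.null(perm)) NA_real_ else perm$p_values[sel],
    stringsAsFactors = FALSE)
  tab$significant <- !is.na(tab$p_value) & tab$p_value <= alpha
  ord <- order(xtfrm(tab$p_value), -abs(tab$coefficient),
               tab$drug, tab$pathway, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write an association table as TSV
#'
#' Fixed header (`drug`, `pathway`, `coefficient`, `activation_lambda`,
#' `p_value`, `significant`), floats at 6 significant digits, rows in the
#' table's deterministic order.
#'
#' @param table a data frame from [association_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path) {
  cols <- c("drug", "pathway", "coefficient", "activation_lambda",
            "p_value", "significant")
  if (!all(cols %in% names(table)))
    stop_invalid("table is missing columns: ",
                 paste(setdiff(cols, names(table)), collapse = ", "))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))
  body <- if (nrow(table)) vapply(seq_len(nrow(table)), function(i)
    paste(table$drug[i], table$pathway[i], fmt(table$coefficient[i]),
          fmt(table$activation_lambda[i]), fmt(table$p_value[i]),
          ifelse(table$significant[i], "TRUE", "FALSE"), sep = "\t"),
    character(1L)) else character(0L)
  writeLines(c(paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read an association table written by [write_association_table()]
#'
#' @param path file path.
#' @return A data frame with the six fixed columns.
#' @export
read_association_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "NA")
  tab$significant <- as.logical(tab$significant)
  tab
}
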