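#' Expression matrix container
#'
#' Holds a samples x genes block of normalized expression values together
#' with its identifiers.  This is the common currency of the package: the
#' TF block `X` (n samples x p TFs) and the target block `Y` (n x q) used
#' by [ascca_iterate()] are both `expression_matrix` objects.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param sample_ids character vector of length `nrow(values)`.
#' @param gene_ids character vector of length `ncol(values)`.
#' @param standardized logical; `TRUE` when every column has mean 0 and
#'   sample variance 1 (denominator n - 1).
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (dimnamed matrix), `sample_ids`, `gene_ids`, `standardized`.
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values),
                              standardized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) must equal nrow(values)")
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) must equal ncol(values)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values contain missing or non-finite entries; ",
         "impute or filter upstream")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(values = values, sample_ids = sample_ids, gene_ids = gene_ids,
         standardized = isTRUE(standardized)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d samples x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) "standardized" else "raw"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Restrict an expression matrix to a set of genes
#'
#' @param em an [expression_matrix()].
#' @param ids gene identifiers to keep, in the requested order.
#' @return An `expression_matrix` with the selected columns.
#' @export
subset_genes <- function(em, ids) {
  stopifnot(inherits(em, "expression_matrix"))
  ids <- as.character(ids)
  missing <- setdiff(ids, em$gene_ids)
  if (length(missing))
    stop("gene ids not present in expression matrix: ",
         paste(missing, collapse = ", "))
  expression_matrix(em$values[, ids, drop = FALSE],
                    sample_ids = em$sample_ids, gene_ids = ids,
                    standardized = em$standardized)
}

#' Standardize expression columns
#'
#' Centers every gene column to mean zero and scales it to unit sample
#' variance (denominator n - 1), the convention under which the
#' cross-product matrix `K` of [cross_correlation()] is exactly a Pearson
#' correlation matrix.  Idempotent on already-standardized input.
#'
#' @param em an [expression_matrix()] with at least 3 samples.
#' @return A standardized `expression_matrix`.
#' @export
standardize <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  v <- em$values
  if (nrow(v) < 3) stop("standardization requires at least 3 samples")
  sds <- apply(v, 2L, sd)
  if (any(sds == 0)) {
    bad <- em$gene_ids[sds == 0]
    stop("zero-variance (constant) columns cannot be standardized: ",
         paste(bad, collapse = ", "),
         "; remove these genes upstream")
  }
  out <- scale(v, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  expression_matrix(out, sample_ids = em$sample_ids, gene_ids = em$gene_ids,
                    standardized = TRUE)
}

#' Cross-correlation matrix between a TF block and a target block
#'
#' For standardized blocks `X` (n x p) and `Y` (n x q) sharing the same
#' samples, returns the p x q matrix `K = t(X) %*% Y / (n - 1)`, whose
#' entries are the Pearson correlations between TF and target profiles.
#' `K` is the sole input of the sparse canonical iteration.
#'
#' @param X,Y standardized [expression_matrix()] objects with identical
#'   `sample_ids` in identical order.
#' @return A numeric p x q matrix with TF ids as rownames and target ids
#'   as colnames.
#' @export
cross_correlation <- function(X, Y) {
  stopifnot(inherits(X, "expression_matrix"), inherits(Y, "expression_matrix"))
  if (!X$standardized || !Y$standardized)
    stop("cross_correlation requires standardized inputs; call standardize()")
  if (!identical(X$sample_ids, Y$sample_ids))
    stop("sample_ids of X and Y differ (or are ordered differently); ",
         "align samples explicitly before calling cross_correlation")
  n <- nrow(X$values)
  K <- crossprod(X$values, Y$values) / (n - 1)
  dimnames(K) <- list(X$gene_ids, Y$gene_ids)
  K
}
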