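#' Spearman rank correlation
#'
#' Pearson correlation of average-fractional ranks (ties share the mean
#' rank).  A constant vector has no rank ordering; its correlation is
#' undefined and is reported as 0 (no association) with a warning rather
#' than `NA`, so link counting stays total.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A number in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector in spearman_rho; returning 0")
    return(0)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  stats::cor(rx, ry)
}

#' Intersection-of-Coexpression (ICE) ranking
#'
#' Guilt-by-association baseline: a candidate TF is linked to a known
#' positive TF when the Spearman correlation of their expression profiles
#' strictly exceeds `rho0` (default 0.6).  Candidates sitting at the
#' intersection of many positives — the largest link counts — are the
#' top-ranked candidate regulators.  Only positive correlations count by
#' default, reflecting the assumption that co-regulating TFs are
#' co-expressed; set `absolute = TRUE` to link on `|rho|`.
#'
#' @param X_candidates [expression_matrix()] of candidate TFs.
#' @param Y_positives [expression_matrix()] of known positive TFs; the
#'   two gene sets must be disjoint.
#' @param rho0 link threshold in `[-1, 1]`.
#' @param absolute link on `|rho| > rho0` instead of `rho > rho0`.
#' @return A data.frame with columns `rank`, `tf_id`, `link_count`,
#'   `linked_positive_ids` (comma-separated), sorted by decreasing link
#'   count with lexicographic tie-break.
#' @export
ice_rank <- function(X_candidates, Y_positives, rho0 = 0.6,
                     absolute = FALSE) {
  stopifnot(inherits(X_candidates, "expression_matrix"),
            inherits(Y_positives, "expression_matrix"))
  overlap <- intersect(X_candidates$gene_ids, Y_positives$gene_ids)
  if (length(overlap))
    stop("candidate and positive TF sets must be disjoint; overlap: ",
         paste(overlap, collapse = ", "))
  if (!identical(X_candidates$sample_ids, Y_positives$sample_ids))
    stop("sample_ids of the two blocks differ")
  RX <- apply(X_candidates$values, 2L, rank, ties.method = "average")
  RY <- apply(Y_positives$values, 2L, rank, ties.method = "average")
  rho <- suppressWarnings(stats::cor(RX, RY))   # n_cand x m_pos
  if (anyNA(rho)) {
    warning("constant expression profile(s); treating their correlations as 0")
    rho[is.na(rho)] <- 0
  }
  linked <- if (absolute) abs(rho) > rho0 else rho > rho0
  counts <- rowSums(linked)
  ids <- X_candidates$gene_ids
  ord <- order(-counts, ids, method = "radix")
  linked_ids <- vapply(seq_along(ids), function(i) {
    paste(Y_positives$gene_ids[linked[i, ]], collapse = ",")
  }, character(1))
  data.frame(rank = seq_along(ord),
             tf_id = ids[ord],
             link_count = as.integer(counts[ord]),
             linked_positive_ids = linked_ids[ord],
             row.names = NULL)
}
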