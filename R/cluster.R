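#' Cluster-size schedule for the bait loop
#'
#' The bait loop runs one k-means partition of the positive target genes
#' per average cluster size `s` in `[s_min, s_max]`.  The number of
#' clusters at size `s` is `n_s = max(1, round(T / s))` (round half to
#' even), so small `s` yields many small baits and large `s` few large
#' ones.  The default range 4..20 schedules 17 runs.
#'
#' @param T number of positive target genes (>= 2).
#' @param s_min,s_max inclusive bounds on the average cluster size.
#' @return A data.frame of class `cluster_schedule` with columns `s` and
#'   `n_clusters`, one row per scheduled k-means run.
#' @export
cluster_schedule <- function(T, s_min = 4L, s_max = 20L) {
  if (T < 2) stop("need at least 2 target genes to schedule clustering")
  stopifnot(s_min >= 1, s_min <= s_max)
  s <- seq.int(s_min, s_max)
  out <- data.frame(s = s, n_clusters = pmax(1L, as.integer(round(T / s))))
  class(out) <- c("cluster_schedule", "data.frame")
  out
}

#' Partition target genes by k-means on their expression profiles
#'
#' Genes are the points and samples the dimensions.  Profiles are
#' standardized gene-wise; with `distance = "correlation"` each profile
#' is additionally centered and scaled along the sample axis, under which
#' Euclidean k-means is monotone-equivalent to 1 - Pearson dissimilarity.
#' The best of `restarts` seeded initializations (by total within-cluster
#' sum of squares) is kept, and empty clusters are dropped.
#'
#' @param Y an [expression_matrix()] restricted to the target genes.
#' @param n_clusters requested number of clusters (<= number of targets).
#' @param seed integer seed; the same seed reproduces the same partition.
#' @param restarts number of random initializations (default 10).
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @return A list of character vectors, one per non-empty cluster, each a
#'   subset of `Y$gene_ids`; the vectors partition the target set.
#' @export
kmeans_partition <- function(Y, n_clusters, seed = 1L, restarts = 10L,
                             distance = c("euclidean", "correlation")) {
  stopifnot(inherits(Y, "expression_matrix"))
  distance <- match.arg(distance)
  T <- ncol(Y$values)
  if (n_clusters > T)
    stop("n_clusters (", n_clusters, ") exceeds the number of targets (", T, ")")
  if (n_clusters == 1) return(list(Y$gene_ids))
  Ys <- if (Y$standardized) Y else standardize(Y)
  pts <- t(Ys$values)                       # genes x samples
  if (distance == "correlation") {
    pts <- t(scale(t(pts)))                 # row-standardize profiles
    pts[!is.finite(pts)] <- 0
  }
  km <- with_preserved_seed(seed,
    kmeans(pts, centers = n_clusters, nstart = restarts, iter.max = 100L))
  split(Y$gene_ids, km$cluster, drop = TRUE)
}

#' Run the full cluster-bait loop
#'
#' For every scheduled average cluster size, partitions the positive
#' targets by k-means and fits one ASCCA bait per cluster: CV-selected
#' penalties, a final fit on the full data, extraction of the TFs with
#' nonzero u-loadings, and the enrichment-factor retention test.  All
#' hooked sets are returned in schedule order with full provenance.
#'
#' @param X_tfs standardized [expression_matrix()] of all candidate TFs.
#' @param Y_targets standardized [expression_matrix()] of the positive
#'   target genes (disjoint from the TFs).
#' @param positive_tf_ids known positive TF identifiers (subset of the
#'   TF universe).
#' @param config a [bait_config()] list.
#' @return A list of `hooked_tf_set` objects (see [enrichment_filter()]),
#'   one per processed cluster, each carrying a `provenance` entry with
#'   the schedule size `s`, cluster index, and selected penalties.
#' @export
run_bait_loop <- function(X_tfs, Y_targets, positive_tf_ids,
                          config = bait_config()) {
  stopifnot(inherits(X_tfs, "expression_matrix"),
            inherits(Y_targets, "expression_matrix"))
  if (length(intersect(X_tfs$gene_ids, Y_targets$gene_ids)))
    stop("target genes overlap the TF universe; the blocks must be disjoint")
  bad_pos <- setdiff(positive_tf_ids, X_tfs$gene_ids)
  if (length(bad_pos))
    stop("positive TF ids absent from the TF block: ",
         paste(bad_pos, collapse = ", "))
  X <- if (X_tfs$standardized) X_tfs else standardize(X_tfs)
  Y <- if (Y_targets$standardized) Y_targets else standardize(Y_targets)
  N <- ncol(X$values)

  sched <- cluster_schedule(ncol(Y$values), config$s_min, config$s_max)
  hooked <- list()
  for (r in seq_len(nrow(sched))) {
    s <- sched$s[r]
    clusters <- kmeans_partition(Y, sched$n_clusters[r],
                                 seed = derive_seed(config$seed, 1L, s),
                                 restarts = config$restarts,
                                 distance = config$distance)
    for (ci in seq_along(clusters)) {
      Yc <- subset_genes(Y, clusters[[ci]])
      sel <- cv_select(X, Yc, grid = config$grid, k = config$cv_k,
                       seed = derive_seed(config$seed, 2L, s, ci),
                       tol = config$tol, max_iter = config$max_iter)
      K <- cross_correlation(X, Yc)
      fit <- ascca_iterate(K, sel$best, tol = config$tol,
                           max_iter = config$max_iter)
      tf_ids <- names(fit$u)[fit$support_u]
      hs <- enrichment_filter(tf_ids, positive_tf_ids, N = N, EF = config$EF)
      hs$provenance <- list(s = s, cluster = ci, target_ids = clusters[[ci]],
                            params = sel$best, delta_cor = max(
                              sel$results$delta_cor),
                            converged = fit$converged)
      hooked[[length(hooked) + 1L]] <- hs
    }
  }
  hooked
}

#' Configuration of the bait loop
#'
#' @param s_min,s_max schedule bounds on the average cluster size.
#' @param grid penalty grid searched per cluster (default
#'   [coarse_penalty_grid()]; pass [penalty_grid()] for the full 35301
#'   triples).
#' @param cv_k number of CV folds.
#' @param EF enrichment factor for set retention (default 3; sensible
#'   range 1 to 5).
#' @param tol,max_iter ASCCA convergence controls.
#' @param seed master seed; all fold shuffles and k-means restarts derive
#'   from it.
#' @param restarts k-means restarts per partition.
#' @param distance k-means metric, `"euclidean"` or `"correlation"`.
#' @return A list of class `bait_config`.
#' @export
bait_config <- function(s_min = 4L, s_max = 20L, grid = coarse_penalty_grid(),
                        cv_k = 5L, EF = 3, tol = 1e-6, max_iter = 500L,
                        seed = 1L, restarts = 10L,
                        distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  stopifnot(s_min >= 1, s_min <= s_max, cv_k >= 2, EF > 0, tol > 0,
            max_iter >= 1, restarts >= 1, nrow(grid) >= 1)
  structure(list(s_min = as.integer(s_min), s_max = as.integer(s_max),
                 grid = grid, cv_k = as.integer(cv_k), EF = EF, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 restarts = as.integer(restarts), distance = distance),
            class = "bait_config")
}
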