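#' Pipeline configuration
#'
#' Bundles input paths and every tunable of the bait pipeline, validated
#' before any computation starts.
#'
#' @param expression,all_tfs,positive_tfs,positive_targets input file
#'   paths (expression TSV and three gene lists); may be `NULL` when
#'   [run_tf_finder()] is called on in-memory objects.
#' @param output_dir directory for the output tables.
#' @param s_min,s_max,grid,cv_k,EF,tol,max_iter,seed,restarts,distance
#'   see [bait_config()].
#' @param top_k number of top-ranked TFs reported (default 70).
#' @param run_ice also run the ICE baseline and the overlap comparison.
#' @param rho0 ICE link threshold.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression = NULL, all_tfs = NULL,
                            positive_tfs = NULL, positive_targets = NULL,
                            output_dir = ".",
                            s_min = 4L, s_max = 20L,
                            grid = coarse_penalty_grid(), cv_k = 5L, EF = 3,
                            tol = 1e-6, max_iter = 500L, seed = 1L,
                            restarts = 10L,
                            distance = c("euclidean", "correlation"),
                            top_k = 70L, run_ice = TRUE, rho0 = 0.6) {
  distance <- match.arg(distance)
  stopifnot(top_k >= 1, rho0 >= -1, rho0 <= 1)
  bc <- bait_config(s_min = s_min, s_max = s_max, grid = grid, cv_k = cv_k,
                    EF = EF, tol = tol, max_iter = max_iter, seed = seed,
                    restarts = restarts, distance = distance)
  structure(c(list(expression = expression, all_tfs = all_tfs,
                   positive_tfs = positive_tfs,
                   positive_targets = positive_targets,
                   output_dir = output_dir, top_k = as.integer(top_k),
                   run_ice = isTRUE(run_ice), rho0 = rho0),
              unclass(bc)),
            class = "pipeline_config")
}

validate_pipeline_inputs <- function(em, all_tf_ids, positive_tf_ids,
                                     positive_target_ids) {
  problems <- character(0)
  missing_tfs <- setdiff(all_tf_ids, em$gene_ids)
  if (length(missing_tfs))
    problems <- c(problems, paste0("TF ids absent from expression matrix: ",
                                   paste(missing_tfs, collapse = ", ")))
  missing_tgts <- setdiff(positive_target_ids, em$gene_ids)
  if (length(missing_tgts))
    problems <- c(problems,
                  paste0("target ids absent from expression matrix: ",
                         paste(missing_tgts, collapse = ", ")))
  stray_pos <- setdiff(positive_tf_ids, all_tf_ids)
  if (length(stray_pos))
    problems <- c(problems, paste0("positive TFs not in the TF universe: ",
                                   paste(stray_pos, collapse = ", ")))
  overlap <- intersect(positive_target_ids, all_tf_ids)
  if (length(overlap))
    problems <- c(problems, paste0("targets overlapping the TF universe: ",
                                   paste(overlap, collapse = ", ")))
  if (length(positive_target_ids) < 2)
    problems <- c(problems, "need at least 2 positive target genes")
  if (length(problems))
    stop("invalid pipeline inputs:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(TRUE)
}

#' Run the TF-baiting pipeline on in-memory inputs
#'
#' Executes the full workflow: standardization, the cluster-size
#' schedule, per-cluster CV-selected ASCCA baits, enrichment-based set
#' retention, frequency ranking, and (optionally) the ICE baseline over
#' the same TF universe.
#'
#' @param em an [expression_matrix()] holding all TFs and targets.
#' @param all_tf_ids identifiers of the candidate TF universe.
#' @param positive_tf_ids known positive TFs (subset of `all_tf_ids`).
#' @param positive_target_ids known positive target genes (disjoint from
#'   the TFs).
#' @param config a [pipeline_config()].
#' @return A list of class `tf_finder_result`: `ranked` (full frequency
#'   ranking), `top` (its head of size `top_k`), `hooked_sets`,
#'   `schedule`, and when `run_ice` is set, `ice` (ICE ranking of the
#'   non-positive TFs) and `comparison` (ids common to both top lists).
#' @export
run_tf_finder <- function(em, all_tf_ids, positive_tf_ids,
                          positive_target_ids, config = pipeline_config()) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(config, "pipeline_config"))
  validate_pipeline_inputs(em, all_tf_ids, positive_tf_ids,
                           positive_target_ids)
  X <- standardize(subset_genes(em, all_tf_ids))
  Y <- standardize(subset_genes(em, positive_target_ids))
  bc <- bait_config(s_min = config$s_min, s_max = config$s_max,
                    grid = config$grid, cv_k = config$cv_k, EF = config$EF,
                    tol = config$tol, max_iter = config$max_iter,
                    seed = config$seed, restarts = config$restarts,
                    distance = config$distance)
  hooked <- run_bait_loop(X, Y, positive_tf_ids, bc)
  ranked <- frequency_rank(hooked, positive_tf_ids)
  top <- top_k(ranked, config$top_k)
  out <- list(ranked = ranked, top = top, hooked_sets = hooked,
              schedule = cluster_schedule(length(positive_target_ids),
                                          config$s_min, config$s_max),
              config = config)
  if (config$run_ice) {
    candidates <- setdiff(all_tf_ids, positive_tf_ids)
    ice <- ice_rank(subset_genes(em, candidates),
                    subset_genes(em, positive_tf_ids),
                    rho0 = config$rho0)
    ice_top <- top_k(ice, config$top_k)
    out$ice <- ice
    out$comparison <- data.frame(
      tf_id = sort(intersect(top$tf_id, ice_top$tf_id)))
  }
  class(out) <- "tf_finder_result"
  out
}

#' @export
print.tf_finder_result <- function(x, ...) {
  n_ret <- sum(vapply(x$hooked_sets, `[[`, logical(1), "retained"))
  cat(sprintf(
    "<tf_finder_result> %d baits (%d retained), %d ranked TFs; top %d:\n",
    length(x$hooked_sets), n_ret, nrow(x$ranked), min(10L, nrow(x$top))))
  print(utils::head(x$top, 10L))
  invisible(x)
}

#' Run the pipeline from input files and write output tables
#'
#' File-level front end of [run_tf_finder()]: reads the expression TSV
#' and the three gene lists named in `config`, runs the pipeline, and
#' writes `ranked_tfs.tsv` (rank, tf_id, frequency, is_known_positive),
#' `retained_sets.tsv` (per-bait provenance: s, cluster, selected
#' penalties, set size and positive overlap), a `run_log.txt`, and, when
#' ICE is enabled, `ice_ranking.tsv` and `comparison.tsv` (ids common to
#' both top lists).  All result tables are deterministic functions of
#' the inputs and the seed; the log additionally records wall-clock
#' timings.
#'
#' @param config a [pipeline_config()] with all four input paths set.
#' @return Invisibly, the `tf_finder_result` with an added
#'   `output_files` element.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("expression", "all_tfs", "positive_tfs", "positive_targets")) {
    if (is.null(config[[f]]))
      stop("pipeline_config is missing the '", f, "' input path")
  }
  t0 <- Sys.time()
  em <- read_expression_tsv(config$expression)
  all_tf_ids <- read_gene_list(config$all_tfs)
  positive_tf_ids <- read_gene_list(config$positive_tfs)
  positive_target_ids <- read_gene_list(config$positive_targets)
  t_read <- Sys.time()

  res <- run_tf_finder(em, all_tf_ids, positive_tf_ids,
                       positive_target_ids, config)
  t_fit <- Sys.time()

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ranked = file.path(config$output_dir, "ranked_tfs.tsv"),
             retained = file.path(config$output_dir, "retained_sets.tsv"),
             log = file.path(config$output_dir, "run_log.txt"))
  write_tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(res$ranked, paths[["ranked"]])
  prov <- do.call(rbind, lapply(res$hooked_sets, function(h) {
    data.frame(s = h$provenance$s, cluster = h$provenance$cluster,
               lambda_u = h$provenance$params$lambda_u,
               lambda_v = h$provenance$params$lambda_v,
               gamma = h$provenance$params$gamma,
               n_ascca = h$n_ascca, n_pos_overlap = h$n_pos_overlap,
               retained = h$retained)
  }))
  write_tsv(prov, paths[["retained"]])
  if (config$run_ice) {
    paths[["ice"]] <- file.path(config$output_dir, "ice_ranking.tsv")
    paths[["comparison"]] <- file.path(config$output_dir, "comparison.tsv")
    write_tsv(res$ice, paths[["ice"]])
    write_tsv(res$comparison, paths[["comparison"]])
  }
  t_end <- Sys.time()
  log_lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("inputs: %s | %s | %s | %s", config$expression, config$all_tfs,
            config$positive_tfs, config$positive_targets),
    sprintf("schedule: s in [%d, %d]; grid: %d triples; cv_k=%d; EF=%g; top_k=%d",
            config$s_min, config$s_max, nrow(config$grid), config$cv_k,
            config$EF, config$top_k),
    sprintf("baits: %d fitted, %d retained", length(res$hooked_sets),
            sum(vapply(res$hooked_sets, `[[`, logical(1), "retained"))),
    sprintf("timing: read %.2fs, fit %.2fs, write %.2fs",
            as.numeric(t_read - t0, units = "secs"),
            as.numeric(t_fit - t_read, units = "secs"),
            as.numeric(t_end - t_fit, units = "secs")))
  writeLines(log_lines, paths[["log"]])
  message(paste(log_lines, collapse = "\n"))
  res$output_files <- paths
  invisible(res)
}
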