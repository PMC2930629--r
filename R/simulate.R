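#' Simulate an expression dataset with planted regulatory modules
#'
#' Generates a seeded synthetic dataset for end-to-end validation of the
#' bait pipeline.  Each module consists of a handful of "true" TFs whose
#' profiles are iid standard normal across samples, and a block of target
#' genes, each target being a random-weight linear combination of its
#' module's TF profiles plus Gaussian noise.  Decoy TFs and decoy targets
#' are independent noise, planting no association.  Weights are drawn
#' from `Uniform(0.5, 1.5) * effect_scale`; with `mixed_sign = TRUE` each
#' weight's sign is additionally randomized, producing modules whose TFs
#' are not mutually co-expressed (the regime where pairwise-coexpression
#' baselines break down while canonical-correlation baiting does not).
#'
#' The known-positive lists emulate the pipeline's prior knowledge: a
#' configurable fraction of each module's TFs (default half, rounded up)
#' is declared "positive", and every module target is a positive target.
#'
#' @param n_samples number of samples (columns of the profiles).
#' @param n_modules number of planted regulatory modules.
#' @param tfs_per_module true TFs per module (>= 2).
#' @param targets_per_module target genes per module.
#' @param n_decoy_tfs,n_decoy_targets independent-noise genes (>= 0).
#' @param noise_sd standard deviation of the target noise (>= 0).
#' @param effect_scale multiplier on the regulatory weights.
#' @param positive_fraction fraction of each module's TFs flagged as
#'   known positives (rounded up).
#' @param mixed_sign randomize the sign of each regulatory weight.
#' @param seed integer seed; the same seed regenerates the dataset
#'   byte-identically.
#' @return A list of class `synthetic_dataset` with elements
#'   `expression` (an [expression_matrix()] over all TFs and targets),
#'   `all_tf_ids`, `positive_tf_ids`, `positive_target_ids`, `truth`
#'   (per-module list of `tf_ids` and `target_ids`), `seed`, `noise_sd`.
#' @export
simulate_regulatory_dataset <- function(n_samples = 60L, n_modules = 2L,
                                        tfs_per_module = 3L,
                                        targets_per_module = 10L,
                                        n_decoy_tfs = 200L,
                                        n_decoy_targets = 0L,
                                        noise_sd = 0.2,
                                        effect_scale = 1,
                                        positive_fraction = 0.5,
                                        mixed_sign = FALSE,
                                        seed = 1L) {
  stopifnot(n_samples >= 1, n_modules >= 1, tfs_per_module >= 2,
            targets_per_module >= 1, n_decoy_tfs >= 0, n_decoy_targets >= 0,
            noise_sd >= 0, effect_scale > 0,
            positive_fraction > 0, positive_fraction <= 1)
  with_preserved_seed(seed, {
    cols <- list()
    truth <- list()
    positive_tf_ids <- character(0)
    for (m in seq_len(n_modules)) {
      tf_ids <- sprintf("TF_m%d_%d", m, seq_len(tfs_per_module))
      tgt_ids <- sprintf("TGT_m%d_%d", m, seq_len(targets_per_module))
      TFm <- matrix(rnorm(n_samples * tfs_per_module),
                    nrow = n_samples, dimnames = list(NULL, tf_ids))
      W <- matrix(runif(tfs_per_module * targets_per_module, 0.5, 1.5) *
                    effect_scale,
                  nrow = tfs_per_module)
      if (mixed_sign) {
        W <- W * matrix(sample(c(-1, 1),
                               tfs_per_module * targets_per_module,
                               replace = TRUE),
                        nrow = tfs_per_module)
      }
      TGTm <- TFm %*% W
      if (noise_sd > 0)
        TGTm <- TGTm + matrix(rnorm(length(TGTm), sd = noise_sd),
                              nrow = n_samples)
      colnames(TGTm) <- tgt_ids
      cols[[length(cols) + 1L]] <- TFm
      cols[[length(cols) + 1L]] <- TGTm
      truth[[sprintf("module_%d", m)]] <- list(tf_ids = tf_ids,
                                               target_ids = tgt_ids)
      n_pos <- ceiling(positive_fraction * tfs_per_module)
      positive_tf_ids <- c(positive_tf_ids, tf_ids[seq_len(n_pos)])
    }
    if (n_decoy_tfs > 0) {
      D <- matrix(rnorm(n_samples * n_decoy_tfs), nrow = n_samples,
                  dimnames = list(NULL, sprintf("DECOY_TF_%d",
                                                seq_len(n_decoy_tfs))))
      cols[[length(cols) + 1L]] <- D
    }
    if (n_decoy_targets > 0) {
      D <- matrix(rnorm(n_samples * n_decoy_targets), nrow = n_samples,
                  dimnames = list(NULL, sprintf("DECOY_TGT_%d",
                                                seq_len(n_decoy_targets))))
      cols[[length(cols) + 1L]] <- D
    }
    values <- do.call(cbind, cols)
    rownames(values) <- sprintf("S%03d", seq_len(n_samples))
    all_tf_ids <- c(unlist(lapply(truth, `[[`, "tf_ids"), use.names = FALSE),
                    if (n_decoy_tfs > 0)
                      sprintf("DECOY_TF_%d", seq_len(n_decoy_tfs)))
    positive_target_ids <- unlist(lapply(truth, `[[`, "target_ids"),
                                  use.names = FALSE)
    structure(
      list(expression = expression_matrix(values),
           all_tf_ids = all_tf_ids,
           positive_tf_ids = positive_tf_ids,
           positive_target_ids = positive_target_ids,
           truth = truth, seed = as.integer(seed), noise_sd = noise_sd),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d samples, %d TFs (%d positive), %d positive targets, %d modules, noise_sd=%g, seed=%d\n",
    nrow(x$expression$values), length(x$all_tf_ids),
    length(x$positive_tf_ids), length(x$positive_target_ids),
    length(x$truth), x$noise_sd, x$seed))
  invisible(x)
}

#' Write a synthetic dataset as pipeline input files
#'
#' Emits the four files [run_pipeline()] reads — the expression TSV and
#' the three one-id-per-line gene lists — plus a `truth.json` holding the
#' planted module map for tests.
#'
#' @param dataset a [simulate_regulatory_dataset()] result.
#' @param directory output directory (created if absent).
#' @return Named character vector of the written file paths.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  paths <- c(expression = file.path(directory, "expression.tsv"),
             all_tfs = file.path(directory, "all_tfs.txt"),
             positive_tfs = file.path(directory, "positive_tfs.txt"),
             positive_targets = file.path(directory, "positive_targets.txt"),
             truth = file.path(directory, "truth.json"))
  write_expression_tsv(dataset$expression, paths[["expression"]])
  writeLines(dataset$all_tf_ids, paths[["all_tfs"]])
  writeLines(dataset$positive_tf_ids, paths[["positive_tfs"]])
  writeLines(dataset$positive_target_ids, paths[["positive_targets"]])
  jsonlite::write_json(dataset$truth, paths[["truth"]], auto_unbox = FALSE)
  paths
}
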