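#' Enrichment-factor retention test for a hooked TF set
#'
#' Under a null of uniform sampling from the TF universe, a hooked set of
#' `n_ascca` TFs is expected to contain `(N_pos / N) * n_ascca` known
#' positives.  The set is retained only when the observed overlap
#' strictly exceeds `EF` times that expectation; the enrichment factor
#' `EF` (default 3) makes the criterion stringent enough that only sets
#' genuinely enriched in prior knowledge survive.
#'
#' @param tf_ids identifiers of the TFs hooked by one ASCCA fit (the
#'   nonzero u-support).
#' @param positive_tf_ids known positive TF identifiers.
#' @param N size of the TF universe (> 0).
#' @param EF enrichment factor (> 0).
#' @return A list of class `hooked_tf_set` with elements `tf_ids`,
#'   `n_ascca`, `n_pos_overlap`, `threshold`, `retained`, and a
#'   `provenance` slot filled in by [run_bait_loop()].
#' @export
enrichment_filter <- function(tf_ids, positive_tf_ids, N, EF = 3) {
  if (N <= 0) stop("TF universe size N must be positive")
  stopifnot(EF > 0)
  tf_ids <- unique(as.character(tf_ids))
  positive_tf_ids <- unique(as.character(positive_tf_ids))
  if (length(positive_tf_ids) > N)
    stop("more positive TFs than the universe size N")
  if (length(positive_tf_ids) == 0)
    warning("no known positive TFs: every hooked set will be discarded")
  n_ascca <- length(tf_ids)
  n_pos_overlap <- length(intersect(tf_ids, positive_tf_ids))
  threshold <- EF * (length(positive_tf_ids) / N) * n_ascca
  structure(
    list(tf_ids = tf_ids, n_ascca = n_ascca, n_pos_overlap = n_pos_overlap,
         threshold = threshold, retained = n_pos_overlap > threshold,
         EF = EF, N = N, N_pos = length(positive_tf_ids),
         provenance = NULL),
    class = "hooked_tf_set"
  )
}

#' @export
print.hooked_tf_set <- function(x, ...) {
  cat(sprintf("<hooked_tf_set> %d TFs, %d positive (threshold %.3f) -> %s\n",
              x$n_ascca, x$n_pos_overlap, x$threshold,
              if (x$retained) "retained" else "discarded"))
  invisible(x)
}

#' Pool retained hooked sets into a frequency ranking
#'
#' Counts, over the retained sets only, in how many sets each TF occurs
#' (once per set, regardless of loading magnitude), then ranks TFs by
#' frequency.  The more often a TF is re-identified across baits, the
#' stronger the evidence for its involvement.  Ties are broken by
#' lexicographic identifier so the ranking is a deterministic,
#' permutation-stable function of the input sets.
#'
#' @param sets list of `hooked_tf_set` objects from [run_bait_loop()].
#' @param positive_tf_ids identifiers used to flag rediscovered known
#'   positives in the output.
#' @return A data.frame with columns `rank` (1-based), `tf_id`,
#'   `frequency`, `is_known_positive`, sorted by decreasing frequency.
#' @export
frequency_rank <- function(sets, positive_tf_ids = character(0)) {
  retained <- Filter(function(s) isTRUE(s$retained), sets)
  if (length(retained) == 0) {
    return(data.frame(rank = integer(0), tf_id = character(0),
                      frequency = integer(0),
                      is_known_positive = logical(0)))
  }
  ids <- unlist(lapply(retained, `[[`, "tf_ids"), use.names = FALSE)
  tab <- table(ids)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  data.frame(rank = seq_along(ord),
             tf_id = names(tab)[ord],
             frequency = as.integer(tab)[ord],
             is_known_positive = names(tab)[ord] %in% positive_tf_ids,
             row.names = NULL)
}

#' Head of a ranked TF table
#'
#' @param ranked a data.frame from [frequency_rank()] or [ice_rank()].
#' @param k number of top entries to keep (default 70).
#' @return The first `min(k, nrow)` rows, order preserved.
#' @export
top_k <- function(ranked, k = 70L) {
  stopifnot(k >= 1)
  ranked[seq_len(min(k, nrow(ranked))), , drop = FALSE]
}
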