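# Cross-host differentiation ranking of gene clusters.

#' Score gene clusters by cross-host differentiation
#'
#' Three components per cluster, computed on the masked log2FC matrix
#' (non-significant and absent cells are 0):
#' * `n_sig` -- number of hosts with a significant call,
#' * `s_abs` -- sum of absolute log2 fold-changes over hosts,
#' * `s_pairwise` -- sum over all unordered host pairs of
#'   `|log2fc_i - log2fc_j|` (the combinatorial divergence between
#'   hosts; by default pairs where one host is 0 contribute that host's
#'   0, set `pairwise_sig_only = TRUE` to restrict to pairs where both
#'   hosts are significant).
#'
#' Each component is ranked descending (average ranks on ties) and the
#' combined rank is the rank of the sum of the three component ranks,
#' with ties broken by `s_abs` descending, then cluster id. The
#' combination by rank sums is one documented interpretation; a
#' weighted-sum combiner over the raw components is available via
#' `weights`.
#'
#' @param logfc_matrix hosts x clusters masked log2FC matrix
#'   ([build_logfc_matrix()]).
#' @param significance_mask optional logical matrix of the same shape;
#'   defaults to `logfc_matrix != 0`.
#' @param pairwise_sig_only restrict `s_pairwise` to pairs of significant
#'   hosts (default FALSE).
#' @param weights optional length-3 numeric; if given, clusters are
#'   ranked by `weights %*% c(n_sig, s_abs, s_pairwise)` instead of rank
#'   sums.
#' @return data.frame: cluster_id, n_sig, s_abs, s_pairwise, the three
#'   component ranks, and combined_rank (unique integers).
#' @export
score_clusters <- function(logfc_matrix, significance_mask = NULL,
                           pairwise_sig_only = FALSE, weights = NULL) {
  stop_if_not(nrow(logfc_matrix) >= 2 && ncol(logfc_matrix) >= 1,
              "empty log2FC matrix")
  if (is.null(significance_mask)) significance_mask <- logfc_matrix != 0
  stop_if_not(all(dim(significance_mask) == dim(logfc_matrix)),
              "mask and matrix must be aligned")

  n_sig <- colSums(significance_mask)
  s_abs <- colSums(abs(logfc_matrix) * significance_mask)
  pairs <- utils::combn(nrow(logfc_matrix), 2)
  s_pairwise <- vapply(seq_len(ncol(logfc_matrix)), function(k) {
    v <- logfc_matrix[, k]
    m <- significance_mask[, k]
    if (pairwise_sig_only) {
      keep <- m[pairs[1, ]] & m[pairs[2, ]]
      sum(abs(v[pairs[1, ]][keep] - v[pairs[2, ]][keep]))
    } else {
      sum(abs(v[pairs[1, ]] - v[pairs[2, ]]))
    }
  }, numeric(1))

  r1 <- rank(-n_sig, ties.method = "average")
  r2 <- rank(-s_abs, ties.method = "average")
  r3 <- rank(-s_pairwise, ties.method = "average")
  score <- if (is.null(weights)) {
    -(r1 + r2 + r3)  # higher is better
  } else {
    stop_if_not(length(weights) == 3, "weights must have length 3")
    weights[1] * n_sig + weights[2] * s_abs + weights[3] * s_pairwise
  }
  ids <- colnames(logfc_matrix) %||% as.character(seq_along(n_sig))
  ord <- order(-score, -s_abs, ids)
  combined <- integer(length(ord))
  combined[ord] <- seq_along(ord)

  out <- data.frame(
    cluster_id = ids, n_sig = as.integer(n_sig), s_abs = s_abs,
    s_pairwise = s_pairwise, rank_n_sig = r1, rank_s_abs = r2,
    rank_s_pairwise = r3, combined_rank = combined,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Top differentiated gene clusters
#'
#' @param scores result of [score_clusters()].
#' @param n how many clusters to return (default 100); if more than
#'   available, the full ranked list is returned with a note.
#' @return the first `n` rows ordered by combined rank.
#' @export
top_differentiated <- function(scores, n = 100L) {
  ord <- scores[order(scores$combined_rank), , drop = FALSE]
  if (n > nrow(ord)) {
    message(sprintf("only %d clusters available (requested %d)",
                    nrow(ord), n))
    n <- nrow(ord)
  }
  out <- ord[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
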