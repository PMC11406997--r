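# Pangenome partitioning: frequency groups, composition summaries,
# COG-category enrichment and genome clustering.

#' Construct a gene-cluster matrix
#'
#' The structural backbone of the pangenome: a clusters x genomes matrix
#' of gene-call counts (number of gene calls each genome contributes to
#' each orthologous gene cluster). Presence is defined as >= 1 gene call;
#' paralog multiplicity affects only gene-call tallies, never binning.
#'
#' @param counts integer matrix, clusters in rows (rownames = cluster ids),
#'   genomes in columns (colnames = genome ids). Non-negative; every
#'   cluster must be present in at least one genome.
#' @return the validated matrix with class `gene_cluster_matrix`.
#' @export
gene_cluster_matrix <- function(counts) {
  stop_if_not(is.matrix(counts) && is.numeric(counts),
              "counts must be a numeric matrix")
  stop_if_not(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts needs cluster rownames and genome colnames")
  stop_if_not(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  stop_if_not(all(rowSums(counts) > 0),
              "every cluster must have at least one gene call")
  storage.mode(counts) <- "integer"
  class(counts) <- c("gene_cluster_matrix", class(counts))
  counts
}

#' Assign gene clusters to pangenome frequency groups
#'
#' A cluster's bin is the number of genomes contributing at least one gene
#' call. Clusters in all genomes are "core"; everything else is
#' "accessory", with bin-1 clusters further flagged as unique.
#'
#' @param matrix a [gene_cluster_matrix()] (or plain clusters x genomes
#'   count matrix with dimnames).
#' @return data.frame with columns cluster_id, bin, group
#'   (core/accessory), is_unique.
#' @export
#' @examples
#' m <- gene_cluster_matrix(matrix(c(1L, 1L, 1L, 0L, 1L, 0L), 3, 2,
#'   dimnames = list(c("a", "b", "c"), c("G1", "G2"))))
#' assign_frequency_groups(m)
assign_frequency_groups <- function(matrix) {
  stop_if_not(nrow(matrix) > 0 && ncol(matrix) > 0,
              "empty gene-cluster matrix")
  bin <- as.integer(rowSums(matrix >= 1))
  stop_if_not(all(bin >= 1), "cluster with no occupied genome")
  data.frame(
    cluster_id = rownames(matrix),
    bin = bin,
    group = ifelse(bin == ncol(matrix), "core", "accessory"),
    is_unique = bin == 1L & ncol(matrix) > 1L,
    stringsAsFactors = FALSE
  )
}

#' Summarize pangenome composition by frequency group
#'
#' @param groups result of [assign_frequency_groups()].
#' @return data.frame with rows core, accessory, unique: cluster counts and
#'   percentages of total clusters (one decimal). Unique is a subset of
#'   accessory, so core% + accessory% = 100 within rounding.
#' @export
summarize_groups <- function(groups) {
  total <- nrow(groups)
  n_core <- sum(groups$group == "core")
  n_acc <- sum(groups$group == "accessory")
  n_uni <- sum(groups$is_unique)
  data.frame(
    group = c("core", "accessory", "unique"),
    n_clusters = c(n_core, n_acc, n_uni),
    percent = round(100 * c(n_core, n_acc, n_uni) / total, 1),
    stringsAsFactors = FALSE
  )
}

# one-sided Fisher exact p-values for the 2x2 table [a b; d e]
# (a = in-set & in-category). Returns c(enrich, deplete).
fisher_one_sided <- function(a, b, d, e) {
  tab <- matrix(c(a, d, b, e), 2)
  c(
    enrich = stats::fisher.test(tab, alternative = "greater")$p.value,
    deplete = stats::fisher.test(tab, alternative = "less")$p.value
  )
}

#' COG-category enrichment per frequency group and genome
#'
#' For each genome and frequency group (core / accessory / unique), tests
#' every COG category for over- and under-representation among that
#' genome's gene calls in the group versus the rest of its gene calls
#' (2x2 one-sided Fisher exact tests). P-values are Bonferroni-corrected
#' across categories within each genome x group family. A category is
#' "consistently enriched" in a group when it is significantly enriched in
#' at least `min_hosts` genomes.
#'
#' @param annotations data.frame with columns gene_call_id, cluster_id,
#'   genome_id, cog_category (NA allowed; NA gene calls stay in the
#'   background but are not tested as a category).
#' @param groups result of [assign_frequency_groups()].
#' @param unit count "gene_calls" (default) or "clusters" per genome as the
#'   Fisher unit of analysis.
#' @param alpha significance level after Bonferroni correction
#'   (default 0.05).
#' @param min_hosts consistency threshold (default 3).
#' @return data.frame: genome, group, cog_category, counts of the 2x2
#'   table, odds_ratio, p_enrich, p_deplete, their Bonferroni-adjusted
#'   versions, significant_enriched, plus per category x group
#'   `n_hosts_enriched` and `consistent` flags.
#' @export
cog_group_enrichment <- function(annotations, groups,
                                 unit = c("gene_calls", "clusters"),
                                 alpha = 0.05, min_hosts = 3L) {
  unit <- match.arg(unit)
  grp_map <- stats::setNames(
    ifelse(groups$is_unique, "unique", groups$group), groups$cluster_id)
  ann <- annotations
  ann$fgroup <- grp_map[ann$cluster_id]
  stop_if_not(!anyNA(ann$fgroup), "annotation refers to unknown cluster")
  if (unit == "clusters") {
    ann <- unique(ann[, c("cluster_id", "genome_id", "cog_category",
                          "fgroup")])
  }

  res <- list()
  for (g in unique(ann$genome_id)) {
    sub <- ann[ann$genome_id == g, ]
    total <- nrow(sub)
    cats_here <- sort(unique(sub$cog_category[!is.na(sub$cog_category)]))
    skipped <- setdiff(cog_categories(), cats_here)
    if (length(skipped) > 0) {
      message(sprintf("genome %s: %d COG categories absent, skipped", g,
                      length(skipped)))
    }
    n_tests <- length(cats_here)
    for (fg in intersect(c("core", "accessory", "unique"),
                         unique(sub$fgroup))) {
      in_grp <- sub$fgroup == fg
      for (cc in cats_here) {
        in_cat <- !is.na(sub$cog_category) & sub$cog_category == cc
        a <- sum(in_grp & in_cat)
        b <- sum(in_grp) - a
        d <- sum(in_cat) - a
        e <- total - a - b - d
        p <- fisher_one_sided(a, b, d, e)
        or <- (a * e) / max(b * d, .Machine$double.xmin)
        res[[length(res) + 1L]] <- data.frame(
          genome = g, group = fg, cog_category = cc,
          n_in_group_in_cat = a, n_in_group = sum(in_grp),
          n_in_cat = sum(in_cat), n_total = total,
          odds_ratio = or,
          p_enrich = p[["enrich"]], p_deplete = p[["deplete"]],
          p_enrich_adj = min(1, p[["enrich"]] * n_tests),
          p_deplete_adj = min(1, p[["deplete"]] * n_tests),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, res)
  out$significant_enriched <- out$p_enrich_adj < alpha
  out$significant_depleted <- out$p_deplete_adj < alpha
  key <- paste(out$group, out$cog_category)
  n_hosts <- tapply(out$significant_enriched, key, sum)
  out$n_hosts_enriched <- as.integer(n_hosts[key])
  out$consistent <- out$n_hosts_enriched >= min_hosts
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of rows (complete linkage, Euclidean distance)
#'
#' Agglomerative clustering as used both for the genome presence/absence
#' matrix and for host log2 fold-change profiles. Thin wrapper around
#' `stats::hclust` (which merges the lowest-index pair first on ties,
#' keeping the dendrogram deterministic).
#'
#' @param matrix numeric matrix, rows = items to cluster.
#' @param metric distance metric passed to `stats::dist` (default
#'   "euclidean").
#' @param linkage agglomeration method (default "complete").
#' @return an `hclust` object.
#' @export
hierarchical_cluster <- function(matrix, metric = "euclidean",
                                 linkage = "complete") {
  stop_if_not(nrow(matrix) >= 2, "need at least 2 rows to cluster")
  stats::hclust(stats::dist(matrix, method = metric), method = linkage)
}
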