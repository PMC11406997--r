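# Cluster-level expression analysis: count pooling, TPM, median-of-ratios
# size factors, a simplified negative-binomial Wald DE stage, cross-host
# log2FC matrices and frequency-group / COG summaries.

#' Pool gene-call counts to gene-cluster level
#'
#' Sums the counts of all gene calls belonging to the same orthologous
#' gene cluster, per sample. Pooling makes expression comparable across
#' species: the gene cluster, not the gene call, is the shared unit.
#' Column (per-sample) totals over mapped gene calls are conserved
#' exactly.
#'
#' @param counts integer matrix, gene calls x samples, with rownames.
#' @param cluster_map named character vector or data.frame
#'   (gene_call_id, cluster_id) mapping each gene call to its cluster.
#' @param unmapped what to do with gene calls absent from the map:
#'   "error" (default) or "drop" (with a warning).
#' @return integer matrix, clusters x samples.
#' @export
pool_counts <- function(counts, cluster_map, unmapped = c("error", "drop")) {
  unmapped <- match.arg(unmapped)
  if (is.data.frame(cluster_map)) {
    cluster_map <- stats::setNames(cluster_map$cluster_id,
                                   cluster_map$gene_call_id)
  }
  cl <- cluster_map[rownames(counts)]
  if (anyNA(cl)) {
    n_miss <- sum(is.na(cl))
    if (unmapped == "error") {
      stop(sprintf("%d gene calls missing from the cluster map", n_miss),
           call. = FALSE)
    }
    warning(sprintf("dropping %d unmapped gene calls", n_miss))
    counts <- counts[!is.na(cl), , drop = FALSE]
    cl <- cl[!is.na(cl)]
  }
  out <- rowsum(counts, group = cl)
  storage.mode(out) <- "integer"
  out[order(rownames(out)), , drop = FALSE]
}

#' Transcripts per million
#'
#' `TPM_g = (count_g / length_kb_g) / sum_h(count_h / length_kb_h) * 1e6`
#' per sample; every column sums to one million.
#'
#' @param counts matrix, features x samples.
#' @param lengths feature lengths in bp (named or positionally aligned).
#' @return numeric matrix of TPM values; all-zero samples give NA columns
#'   with a warning.
#' @export
compute_tpm <- function(counts, lengths) {
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  stop_if_not(length(lengths) == nrow(counts),
              "lengths must align with count rows")
  stop_if_not(all(lengths > 0), "zero-length gene")
  rate <- counts / (lengths / 1000)
  denom <- colSums(rate)
  if (any(denom == 0)) {
    warning("all-zero sample(s): TPM undefined, returning NA")
    denom[denom == 0] <- NA_real_
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median, over features with
#' nonzero counts in all samples, of the ratio of the sample's count to
#' the feature's geometric mean, then rescaled to geometric mean 1. If no
#' feature is nonzero everywhere, falls back to library-size ratios with
#' a warning.
#'
#' @param counts matrix, features x samples.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    warning("no feature nonzero in all samples; library-size fallback")
    sf <- colSums(counts)
    stop_if_not(all(sf > 0), "sample with zero total counts")
  } else {
    lc <- log(counts[ok, , drop = FALSE])
    geo <- rowMeans(lc)
    sf <- exp(apply(lc - geo, 2, stats::median))
  }
  sf / exp(mean(log(sf)))
}

#' Simplified negative-binomial Wald differential-expression test
#'
#' Per-cluster two-group comparison (Ara vs aTc) on pooled counts:
#' counts are normalized by median-of-ratios size factors; per-cluster
#' dispersion is estimated by method of moments from the pooled
#' within-condition variance and shrunk (linearly, with weight
#' `shrink`) toward a parametric mean-dispersion trend
#' `alpha(mu) = a0 + a1/mu` fitted across clusters; the Wald statistic is
#' the log2 fold-change over its delta-method standard error, with a
#' two-sided normal p-value and Benjamini-Hochberg adjustment across all
#' tested clusters. Clusters with all-zero counts are excluded from
#' testing and from the BH family. This stage is deliberately simple and
#' is validated by calibration simulations, not by equivalence with any
#' external DE engine.
#'
#' @param counts matrix, clusters x samples (pooled counts).
#' @param condition factor/character of length ncol(counts) with exactly
#'   two levels (reference = second level; log2FC is level1 vs level2,
#'   i.e. Ara vs aTc when levels are c("Ara","aTc")).
#' @param sf size factors (default: computed via [size_factors()]).
#' @param shrink dispersion shrinkage weight toward the trend in [0,1]
#'   (default 0.8; with 3 replicates per group the per-cluster moment
#'   estimate is noisy, so the trend dominates).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param pseudo normalized pseudocount added to group means so that
#'   clusters expressed in only one condition get finite log2FCs
#'   (default 0.5).
#' @return data.frame of class `de_result`: cluster_id, base_mean,
#'   log2fc, se, stat, p_value, p_adj, significant. Untested (all-zero)
#'   clusters are absent.
#' @export
nb_wald_test <- function(counts, condition, sf = NULL, shrink = 0.8,
                         alpha = 0.05, pseudo = 0.5) {
  condition <- as.factor(condition)
  stop_if_not(nlevels(condition) == 2,
              "condition must have exactly two levels")
  stop_if_not(all(table(condition) >= 2),
              "need >= 2 replicates per condition")
  stop_if_not(length(condition) == ncol(counts),
              "condition length must match samples")
  if (is.null(sf)) sf <- size_factors(counts)

  tested <- rowSums(counts) > 0
  m <- counts[tested, , drop = FALSE]
  norm <- sweep(m, 2, sf, "/")
  g1 <- condition == levels(condition)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  mu1 <- rowMeans(norm[, g1, drop = FALSE])
  mu2 <- rowMeans(norm[, g2, drop = FALSE])
  mu0 <- rowMeans(norm)

  v1 <- row_vars(norm[, g1, drop = FALSE])
  v2 <- row_vars(norm[, g2, drop = FALSE])
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  alpha_mom <- pmax((s2 - mu0) / mu0^2, 1e-8)

  # parametric trend alpha(mu) = a0 + a1/mu, fitted on moment estimates
  use <- mu0 > 1 & alpha_mom > 1e-8
  if (sum(use) >= 10) {
    tf <- stats::lm(alpha_mom[use] ~ I(1 / mu0[use]))
    a0 <- max(stats::coef(tf)[1], 1e-6)
    a1 <- max(stats::coef(tf)[2], 0)
  } else {
    a0 <- max(stats::median(alpha_mom), 1e-6)
    a1 <- 0
  }
  alpha_trend <- a0 + a1 / mu0
  disp <- shrink * alpha_trend + (1 - shrink) * alpha_mom

  lfc <- log2((mu1 + pseudo) / (mu2 + pseudo))
  # Var(log group mean) by the delta method, NB var = mu/s_j + alpha mu^2
  inv_s1 <- sum(1 / sf[g1]); inv_s2 <- sum(1 / sf[g2])
  vlog1 <- inv_s1 / (n1^2 * (mu1 + pseudo)) + disp / n1
  vlog2 <- inv_s2 / (n2^2 * (mu2 + pseudo)) + disp / n2
  se <- sqrt(vlog1 + vlog2) / log(2)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))
  padj <- stats::p.adjust(p, method = "BH")

  out <- data.frame(
    cluster_id = rownames(m), base_mean = mu0, log2fc = lfc, se = se,
    stat = stat, p_value = p, p_adj = padj,
    significant = padj < alpha, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("de_result", class(out))
  out
}

#' Build the hosts x clusters log2 fold-change matrix
#'
#' Cells carry a host's log2FC for a cluster only where that host's DE
#' call is significant; non-significant and absent (host lacks the
#' cluster) cells are exactly 0. Scope "core" keeps core clusters only;
#' scope "accessory" keeps accessory clusters with unique clusters
#' removed (a unique cluster exists in one host only, so its distance
#' contribution is artificial); "all" keeps everything. Clusters zero in
#' every host are dropped.
#'
#' @param de_results named list of [nb_wald_test()] results, one per host.
#' @param groups result of [assign_frequency_groups()].
#' @param scope "all", "core" or "accessory".
#' @return numeric matrix hosts x clusters with attribute "scope".
#' @export
build_logfc_matrix <- function(de_results, groups,
                               scope = c("all", "core", "accessory")) {
  scope <- match.arg(scope)
  keep <- switch(scope,
    all = groups$cluster_id,
    core = groups$cluster_id[groups$group == "core"],
    accessory = groups$cluster_id[groups$group == "accessory" &
                                    !groups$is_unique]
  )
  hosts <- names(de_results)
  stop_if_not(!is.null(hosts), "de_results must be a named list")
  m <- matrix(0, length(hosts), length(keep),
              dimnames = list(hosts, keep))
  for (hh in hosts) {
    de <- de_results[[hh]]
    sig <- de[de$significant & de$cluster_id %in% keep, ]
    if (nrow(sig) > 0) m[hh, sig$cluster_id] <- sig$log2fc
  }
  m <- m[, colSums(m != 0) > 0, drop = FALSE]
  stop_if_not(ncol(m) > 0, sprintf("no clusters survive scope '%s'", scope))
  attr(m, "scope") <- scope
  m
}

#' Frequency-group enrichment among a host's DEGs
#'
#' For each host, 2x2 one-sided Fisher exact tests (enrichment and
#' depletion) of core / accessory / unique membership among significant
#' clusters versus the background. The default background is the host's
#' expressed (tested) clusters; "genome" uses all clusters the host
#' carries.
#'
#' @param de_results named list of [nb_wald_test()] results per host.
#' @param groups result of [assign_frequency_groups()].
#' @param matrix the [gene_cluster_matrix()] (needed for the "genome"
#'   background).
#' @param background "expressed" (default) or "genome".
#' @return data.frame: host, group, n_deg_in_group, n_deg, n_bg_in_group,
#'   n_bg, p_enrich, p_deplete.
#' @export
deg_frequency_enrichment <- function(de_results, groups, matrix = NULL,
                                     background = c("expressed", "genome")) {
  background <- match.arg(background)
  fg <- stats::setNames(ifelse(groups$is_unique, "unique", groups$group),
                        groups$cluster_id)
  out <- list()
  for (hh in names(de_results)) {
    de <- de_results[[hh]]
    if (background == "expressed") {
      bg <- de$cluster_id
    } else {
      stop_if_not(!is.null(matrix), "genome background needs the matrix")
      bg <- rownames(matrix)[matrix[, hh] > 0]
    }
    degs <- de$cluster_id[de$significant]
    if (length(degs) == 0) {
      message(sprintf("host %s: empty DEG set, tests skipped", hh))
      next
    }
    for (g in c("core", "accessory", "unique")) {
      a <- sum(fg[degs] == g)
      b <- length(degs) - a
      d <- sum(fg[bg] == g) - a
      e <- length(bg) - length(degs) - d
      p <- fisher_one_sided(a, b, d, e)
      out[[length(out) + 1L]] <- data.frame(
        host = hh, group = g, n_deg_in_group = a, n_deg = length(degs),
        n_bg_in_group = a + d, n_bg = length(bg),
        p_enrich = p[["enrich"]], p_deplete = p[["deplete"]],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Distribution of DEGs over COG categories
#'
#' Counts up- (log2FC > 0) and down-regulated (log2FC < 0) significant
#' clusters per host x COG category x frequency group. Unassigned
#' clusters are reported under category "NA".
#'
#' @param de_results named list of [nb_wald_test()] results per host.
#' @param cluster_cog named per-cluster COG category vector (NA allowed).
#' @param groups result of [assign_frequency_groups()].
#' @return data.frame: host, group, cog_category, n_up, n_down.
#' @export
deg_cog_distribution <- function(de_results, cluster_cog, groups) {
  fg <- stats::setNames(ifelse(groups$is_unique, "unique", groups$group),
                        groups$cluster_id)
  cats <- c(cog_categories(), "NA")
  out <- list()
  for (hh in names(de_results)) {
    de <- de_results[[hh]]
    sig <- de[de$significant, ]
    cc <- cluster_cog[sig$cluster_id]
    cc[is.na(cc)] <- "NA"
    gg <- fg[sig$cluster_id]
    for (g in c("core", "accessory", "unique")) {
      for (cat in cats) {
        sel <- gg == g & cc == cat
        out[[length(out) + 1L]] <- data.frame(
          host = hh, group = g, cog_category = cat,
          n_up = sum(sel & sig$log2fc > 0),
          n_down = sum(sel & sig$log2fc < 0),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}
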