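# Concordance between expression response and device performance:
# 2-component PCA projection, Procrustes superimposition (Gower m2) and
# the PROTEST permutation test.

#' Project items onto the first two principal components
#'
#' Column-centers the matrix (no unit-variance scaling by default),
#' drops all-zero columns, and returns the projections onto the top two
#' right singular directions. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is
#' positive. If the matrix has rank < 2 the second component is a zero
#' vector (with a warning).
#'
#' @param matrix numeric matrix, items (hosts) x features; >= 3 rows.
#' @param n_components number of components (default 2).
#' @param scale. also scale columns to unit variance (correlation-mode
#'   PCA; default FALSE). Useful when features carry heterogeneous units,
#'   e.g. mixed performance metrics.
#' @return object of class `configuration2d`: list with `coords` (items x
#'   n_components score matrix) and `variance_explained`.
#' @export
pca_project <- function(matrix, n_components = 2L, scale. = FALSE) {
  stop_if_not(nrow(matrix) >= 3, "need >= 3 items for ordination")
  m <- matrix[, colSums(matrix != 0) > 0, drop = FALSE]
  stop_if_not(ncol(m) >= 2, "need >= 2 non-zero feature columns")
  if (scale.) {
    sds <- apply(m, 2, stats::sd)
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  k <- min(n_components, ncol(pc$x))
  coords <- matrix(0, nrow(m), n_components,
                   dimnames = list(rownames(m),
                                   paste0("PC", seq_len(n_components))))
  coords[, seq_len(k)] <- pc$x[, seq_len(k)]
  if (rank < n_components) {
    warning(sprintf("matrix has rank %d < %d; trailing components are zero",
                    rank, n_components))
    if (rank < n_components) coords[, seq(rank + 1, n_components)] <- 0
  }
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) coords[, j] <- -coords[, j]
  }
  ve <- ev / sum(ev)
  structure(list(coords = coords,
                 variance_explained = ve[seq_len(min(n_components,
                                                     length(ve)))]),
            class = "configuration2d")
}

# coerce configuration2d or matrix to a plain coordinate matrix
as_coords <- function(x) {
  if (inherits(x, "configuration2d")) x$coords else as.matrix(x)
}

# center (and symmetric-scale) a configuration
prepare_config <- function(m, scale = TRUE) {
  m <- scale(m, center = TRUE, scale = FALSE)
  if (scale) {
    ss <- sqrt(sum(m^2))
    stop_if_not(ss > 0, "degenerate (all-identical) configuration")
    m <- m / ss
  }
  m
}

# sum of singular values of crossprod(X, Y); closed form for 2x2
trace_norm <- function(M) {
  if (all(dim(M) == c(2L, 2L))) {
    sqrt(sum(M^2) + 2 * abs(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]))
  } else {
    sum(svd(M)$d)
  }
}

#' Procrustes superimposition and the Gower m2 statistic
#'
#' Superimposes configuration Y onto configuration X by translation,
#' rotation (reflections allowed) and uniform scaling so as to minimize
#' the sum of squared vector residuals between matched items. In the
#' symmetric, scaled form both configurations are centered and scaled to
#' unit sum of squares first, and the minimized residual sum of squares
#' is the Gower statistic `m2 = 1 - (sum of singular values of X'Y)^2`,
#' which lies in [0, 1]; 0 means the configurations are similar up to a
#' similarity transform.
#'
#' @param X,Y configurations ([pca_project()] results or plain item x
#'   dimension matrices) with identical item sets in the same order.
#' @param scale rescale Y optimally (default TRUE).
#' @param symmetric use the symmetric form (both configurations scaled to
#'   unit sum of squares; default TRUE).
#' @return object of class `procrustes_result`: list with `m2`, `t_stat`
#'   (`sqrt(1 - m2)`), `residuals` (per-item residual lengths), `Yrot`
#'   (the superimposed Y), `X` (the prepared X), `rotation`, `scale_factor`.
#' @export
procrustes_m2 <- function(X, Y, scale = TRUE, symmetric = TRUE) {
  Xm <- as_coords(X); Ym <- as_coords(Y)
  stop_if_not(nrow(Xm) == nrow(Ym) && ncol(Xm) == ncol(Ym),
              "configurations must have identical dimensions")
  if (!is.null(rownames(Xm)) && !is.null(rownames(Ym))) {
    stop_if_not(identical(rownames(Xm), rownames(Ym)),
                "configurations must share the same items in order")
  }
  stop_if_not(nrow(Xm) >= 3, "need >= 3 items")
  Xc <- prepare_config(Xm, scale = symmetric)
  Yc <- prepare_config(Ym, scale = symmetric)
  M <- crossprod(Xc, Yc)
  sv <- svd(M)
  rot <- sv$v %*% t(sv$u)
  traceY <- sum(Yc^2)
  c_scale <- if (scale) sum(sv$d) / traceY else 1
  Yrot <- c_scale * Yc %*% rot
  if (symmetric && scale) {
    m2 <- 1 - sum(sv$d)^2
  } else {
    m2 <- sum(Xc^2) + c_scale^2 * traceY - 2 * c_scale * sum(sv$d)
  }
  m2 <- max(m2, 0)
  res <- sqrt(rowSums((Xc - Yrot)^2))
  structure(list(m2 = m2, t_stat = sqrt(max(1 - m2, 0)), residuals = res,
                 Yrot = Yrot, X = Xc, rotation = rot,
                 scale_factor = c_scale, symmetric = symmetric),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes superimposition: m2 = %.4g", x$m2))
  if (!is.null(x$p_value)) {
    cat(sprintf(", t = %.4g, p = %.4g (%d permutations)",
                x$t_stat, x$p_value, x$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' PROTEST: permutation test of Procrustes concordance
#'
#' Tests the observed correlation statistic `t = sqrt(1 - m2)` against a
#' null distribution obtained by randomly reordering the items of one
#' configuration (Y) while keeping the other fixed; each configuration's
#' internal covariance is untouched. The p-value uses the add-one
#' convention `p = (1 + #(t_perm >= t_obs)) / (n_perm + 1)`. With 7 or
#' fewer items all non-identity permutations are enumerated exactly (719
#' for 6 items, the maximum number of distinct reorderings); otherwise
#' `n_perm` random permutations are sampled.
#'
#' @param X,Y as in [procrustes_m2()].
#' @param n_perm number of permutations when sampling (default 719).
#' @param seed optional integer seed for the sampled case (recorded in
#'   the result).
#' @param scale,symmetric passed to [procrustes_m2()].
#' @return a `procrustes_result` with added `p_value`, `n_perm`, `seed`,
#'   and `t_perm` (the permutation distribution).
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(12), 6, 2)
#' protest(X, X)$p_value  # 1/720: no reordering can beat t = 1
protest <- function(X, Y, n_perm = 719L, seed = NULL, scale = TRUE,
                    symmetric = TRUE) {
  stop_if_not(n_perm >= 1, "n_perm must be >= 1")
  obs <- procrustes_m2(X, Y, scale = scale, symmetric = symmetric)
  Xc <- prepare_config(as_coords(X), scale = symmetric)
  Yc <- prepare_config(as_coords(Y), scale = symmetric)
  n <- nrow(Xc)

  if (n <= 7) {
    perms <- all_permutations(n)
    keep <- rowSums(perms != matrix(seq_len(n), nrow(perms), n,
                                    byrow = TRUE)) > 0
    perms <- perms[keep, , drop = FALSE]
  } else {
    if (!is.null(seed)) {
      perms <- with_substream(seed, "protest", {
        t(replicate(n_perm, sample.int(n)))
      })
    } else {
      perms <- t(replicate(n_perm, sample.int(n)))
    }
  }
  t_perm <- vapply(seq_len(nrow(perms)), function(i) {
    trace_norm(crossprod(Xc, Yc[perms[i, ], , drop = FALSE]))
  }, numeric(1))

  obs$p_value <- (1 + sum(t_perm >= obs$t_stat)) / (nrow(perms) + 1)
  obs$n_perm <- nrow(perms)
  obs$seed <- seed
  obs$t_perm <- t_perm
  obs
}

#' Per-COG-category concordance with device performance
#'
#' Splits a hosts x clusters log2FC matrix by COG category, projects each
#' category's submatrix onto two principal components, and runs
#' [protest()] against the device-performance configuration. Categories
#' whose submatrix has fewer than two informative (non-zero) clusters are
#' reported as untestable rather than raising. Raw p-values are reported
#' with a significance flag at `alpha` (no multiplicity correction by
#' default).
#'
#' @param logfc_matrix hosts x clusters matrix (see
#'   [build_logfc_matrix()]).
#' @param cluster_cog named per-cluster COG category vector (NA =
#'   unassigned, tested as category "NA").
#' @param performance_config a [pca_project()] of the performance matrix
#'   (or a plain hosts x 2 matrix).
#' @param n_perm,seed passed to [protest()].
#' @param alpha significance level on raw p-values (default 0.05).
#' @return data.frame: cog_category, n_clusters, testable, m2, t_stat,
#'   p_value, significant.
#' @export
per_category_concordance <- function(logfc_matrix, cluster_cog,
                                     performance_config, n_perm = 719L,
                                     seed = NULL, alpha = 0.05) {
  cc <- cluster_cog[colnames(logfc_matrix)]
  cc[is.na(cc)] <- "NA"
  out <- list()
  for (cat in sort(unique(cc))) {
    sub <- logfc_matrix[, cc == cat, drop = FALSE]
    informative <- colSums(sub != 0) > 0
    row <- data.frame(cog_category = cat, n_clusters = ncol(sub),
                      testable = FALSE, m2 = NA_real_, t_stat = NA_real_,
                      p_value = NA_real_, significant = NA,
                      stringsAsFactors = FALSE)
    if (sum(informative) >= 2) {
      pr <- tryCatch(suppressWarnings({
        cfg <- pca_project(sub[, informative, drop = FALSE])
        protest(performance_config, cfg, n_perm = n_perm, seed = seed)
      }), error = function(e) NULL)
      if (!is.null(pr)) {
        row$testable <- TRUE
        row$m2 <- pr$m2
        row$t_stat <- pr$t_stat
        row$p_value <- pr$p_value
        row$significant <- pr$p_value < alpha
      }
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
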