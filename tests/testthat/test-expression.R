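# Count pooling, TPM, size factors, the NB Wald DE stage and the
# cross-host summaries built on it.

test_that("pooling sums member gene calls and conserves totals", {
  counts <- matrix(c(10L, 15L, 7L,
                     20L, 5L, 3L), 3, 2,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  map <- c(g1 = "A", g2 = "A", g3 = "B")
  pooled <- pool_counts(counts, map)
  expect_equal(pooled["A", "s1"], 25L)
  expect_equal(pooled["B", "s1"], 7L)
  expect_equal(colSums(pooled), colSums(counts))
  # single-gene cluster passes through unchanged
  expect_equal(unname(pooled["B", ]), unname(counts["g3", ]))
})

test_that("pooling conserves column sums on random tables", {
  set.seed(71)
  counts <- matrix(rpois(300, 20), 50, 6,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("s%d", 1:6)))
  map <- setNames(sample(sprintf("GC%02d", 1:18), 50, TRUE),
                  rownames(counts))
  expect_identical(colSums(pool_counts(counts, map)), colSums(counts))
})

test_that("unmapped gene calls error or drop as configured", {
  counts <- matrix(1L, 2, 2, dimnames = list(c("g1", "gX"), c("s1", "s2")))
  map <- c(g1 = "A")
  expect_error(pool_counts(counts, map), "missing from the cluster map")
  expect_warning(pooled <- pool_counts(counts, map, unmapped = "drop"),
                 "dropping")
  expect_equal(rownames(pooled), "A")
})

test_that("TPM columns sum to one million with the 2:1 length example", {
  counts <- matrix(c(100L, 100L), 2, 1,
                   dimnames = list(c("a", "b"), "s1"))
  tpm <- compute_tpm(counts, c(a = 1000, b = 2000))
  expect_equal(tpm["a", 1], 2e6 / 3, tolerance = 1e-9)
  expect_equal(tpm["b", 1], 1e6 / 3, tolerance = 1e-9)
  expect_equal(colSums(tpm), c(s1 = 1e6))
  # single gene takes the whole million
  tpm1 <- compute_tpm(matrix(5L, 1, 1, dimnames = list("a", "s")), 500)
  expect_equal(as.numeric(tpm1), 1e6)
  expect_error(compute_tpm(counts, c(a = 0, b = 100)), "zero-length")
  expect_warning(compute_tpm(matrix(0L, 2, 1,
                                    dimnames = list(c("a", "b"), "s")),
                             c(a = 100, b = 100)), "all-zero")
})

test_that("size factors are 1 for identical samples and track scaling", {
  m <- matrix(rep(c(10L, 50L, 200L), 3), 3, 3)
  expect_equal(size_factors(m), rep(1, 3))
  m2 <- cbind(m[, 1:2], 2L * m[, 3])
  sf <- size_factors(m2)
  expect_equal(sf[3] / sf[1], 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  # single-feature table: factors proportional to the counts
  m3 <- matrix(c(10L, 20L, 40L), 1, 3)
  sf3 <- size_factors(m3)
  expect_equal(sf3[2] / sf3[1], 2, tolerance = 1e-12)
})

test_that("all-zero clusters are excluded from testing and BH family", {
  set.seed(73)
  m <- rbind(matrix(rnbinom(60, mu = 50, size = 10), 10, 6),
             matrix(0L, 2, 6))
  rownames(m) <- sprintf("c%02d", 1:12)
  colnames(m) <- paste0(rep(c("Ara", "aTc"), each = 3), "_", 1:3)
  de <- nb_wald_test(m, rep(c("Ara", "aTc"), each = 3))
  expect_equal(nrow(de), 10)
  expect_false(any(c("c11", "c12") %in% de$cluster_id))
  expect_true(all(de$p_adj >= de$p_value))
  expect_identical(de$significant, de$p_adj < 0.05)
})

test_that("BH adjustment preserves the p-value ordering", {
  set.seed(79)
  m <- matrix(rnbinom(1200, mu = 80, size = 10), 200, 6,
              dimnames = list(sprintf("c%03d", 1:200),
                              paste0(rep(c("Ara", "aTc"), each = 3), "_",
                                     1:3)))
  de <- nb_wald_test(m, rep(c("Ara", "aTc"), each = 3))
  ord <- order(de$p_value)
  expect_true(all(diff(rank(de$p_adj, ties.method = "min")[ord]) >= 0))
})

test_that("the Wald stage is calibrated and powered across 3 seeds", {
  cond <- rep(c("Ara", "aTc"), each = 3)
  for (sd0 in c(101, 211, 307)) {
    set.seed(sd0)
    n <- 2000
    null_m <- matrix(rnbinom(n * 6, mu = 100, size = 10), n,
                     dimnames = list(sprintf("c%04d", 1:n),
                                     paste0(cond, "_", 1:3)))
    de0 <- nb_wald_test(null_m, cond)
    expect_gte(mean(de0$p_value < 0.05), 0.03)
    expect_lte(mean(de0$p_value < 0.05), 0.07)

    lfc <- rep(0, n); lfc[1:200] <- sample(c(-2, 2), 200, TRUE)
    m <- cbind(
      matrix(rnbinom(n * 3, mu = rep(100 * 2^(lfc / 2), 3), size = 10), n),
      matrix(rnbinom(n * 3, mu = rep(100 * 2^(-lfc / 2), 3), size = 10), n))
    dimnames(m) <- dimnames(null_m)
    de1 <- nb_wald_test(m, cond)
    expect_gte(mean(de1$significant[1:200]), 0.8)
  }
})

test_that("clusters expressed in one condition get finite log2FCs", {
  m <- cbind(matrix(50L, 3, 3), matrix(0L, 3, 3))
  dimnames(m) <- list(c("a", "b", "c"),
                      paste0(rep(c("Ara", "aTc"), each = 3), "_", 1:3))
  de <- nb_wald_test(m, rep(c("Ara", "aTc"), each = 3),
                     sf = rep(1, 6))
  expect_true(all(is.finite(de$log2fc)))
  expect_true(all(de$log2fc > 0))
})

test_that("log2FC matrix masks non-significant and absent cells", {
  groups <- data.frame(
    cluster_id = c("A", "B", "C", "D"),
    bin = c(3L, 2L, 1L, 3L),
    group = c("core", "accessory", "accessory", "core"),
    is_unique = c(FALSE, FALSE, TRUE, FALSE)
  )
  mk <- function(ids, lfc, sig) data.frame(
    cluster_id = ids, base_mean = 10, log2fc = lfc, se = 1,
    stat = lfc, p_value = 0.01, p_adj = ifelse(sig, 0.01, 0.5),
    significant = sig)
  de <- list(
    h1 = mk(c("A", "B", "C", "D"), c(2, -1, 3, 0.5),
            c(TRUE, TRUE, TRUE, FALSE)),
    h2 = mk(c("A", "B", "C", "D"), c(1, 2, -2, 1),
            c(TRUE, FALSE, FALSE, FALSE)),
    h3 = mk(c("A", "B", "C", "D"), c(0, 0, 0, 0),
            c(FALSE, FALSE, FALSE, FALSE))
  )
  m_all <- build_logfc_matrix(de, groups, "all")
  expect_equal(m_all["h1", "A"], 2)
  expect_equal(m_all["h2", "B"], 0)     # non-significant -> 0
  expect_true(all(m_all["h3", ] == 0))  # host with no significant calls
  expect_false("D" %in% colnames(m_all))  # all-zero column dropped
  m_core <- build_logfc_matrix(de, groups, "core")
  expect_equal(colnames(m_core), "A")
  m_acc <- build_logfc_matrix(de, groups, "accessory")
  expect_false("C" %in% colnames(m_acc))  # unique removed from accessory
  expect_error(build_logfc_matrix(de[3], groups, "core"), "survive")
})

test_that("DEG frequency enrichment matches the enumeration oracle", {
  # hand 2x2: 40 core DEGs of 100 DEGs vs 100 core of 300 non-DEG background
  fisher_one_sided <- getFromNamespace("fisher_one_sided", "chassisconcord")
  p <- fisher_one_sided(40, 60, 100, 300)
  oracle <- enumerate_fisher(40, 60, 100, 300)
  expect_equal(unname(p), unname(oracle), tolerance = 1e-12)
})

test_that("planted core-skewed DEGs show core enrichment per host", {
  cfg <- sim_config(n_clusters = 500, core_fraction = 0.5,
                    unique_fraction = 0.25, de_fraction_core = 0.5,
                    de_fraction_accessory = 0.05, seed = 83)
  study <- simulate_study(cfg)
  groups <- assign_frequency_groups(study$pangenome$matrix)
  ann <- study$pangenome$annotations
  cmap <- setNames(ann$cluster_id, ann$gene_call_id)
  de <- lapply(study$counts, function(tab) {
    nb_wald_test(pool_counts(tab$counts, cmap), tab$design$condition)
  })
  enr <- deg_frequency_enrichment(de, groups)
  core <- enr[enr$group == "core", ]
  expect_true(all(core$p_enrich < 0.05))
  acc <- enr[enr$group == "accessory", ]
  expect_true(all(acc$p_deplete < 0.05))
})

test_that("DEG COG distribution counts match the truth on clean flags", {
  groups <- data.frame(cluster_id = c("A", "B", "C"), bin = c(2L, 2L, 1L),
                       group = c("core", "core", "accessory"),
                       is_unique = c(FALSE, FALSE, TRUE))
  de <- list(h1 = data.frame(
    cluster_id = c("A", "B", "C"), base_mean = 1,
    log2fc = c(1.5, -2, 0.7), se = 1, stat = 1,
    p_value = 0.01, p_adj = c(0.01, 0.01, 0.2),
    significant = c(TRUE, TRUE, FALSE)))
  cc <- c(A = "T", B = "T", C = "J")
  tab <- deg_cog_distribution(de, cc, groups)
  t_up <- tab[tab$cog_category == "T" & tab$group == "core", ]
  expect_equal(t_up$n_up, 1L)
  expect_equal(t_up$n_down, 1L)
  expect_equal(sum(tab$n_up) + sum(tab$n_down), 2L)
})
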