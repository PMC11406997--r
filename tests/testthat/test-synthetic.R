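# Synthetic study generator: structure, conservation and determinism.

test_that("pangenome realizes requested fractions exactly after rounding", {
  cfg <- sim_config(n_clusters = 6469, core_fraction = 0.425,
                    unique_fraction = 0.311, seed = 3)
  pg <- simulate_pangenome(cfg)
  groups <- assign_frequency_groups(pg$matrix)
  expect_equal(sum(groups$group == "core"), round(0.425 * 6469))
  expect_equal(sum(groups$is_unique), round(0.311 * 6469))
  expect_equal(nrow(pg$matrix), 6469L)
  # every occupied slot contributes at least one gene call
  expect_true(all(pg$matrix[pg$matrix > 0] >= 1))
  # gene calls map to exactly one cluster each
  expect_false(any(duplicated(pg$annotations$gene_call_id)))
})

test_that("degenerate fractions behave: all-core and infeasible configs", {
  cfg <- sim_config(n_clusters = 50, core_fraction = 1, unique_fraction = 0,
                    seed = 1)
  pg <- simulate_pangenome(cfg)
  expect_true(all(pg$matrix >= 1))
  expect_error(sim_config(core_fraction = 0.7, unique_fraction = 0.5),
               "infeasible")
})

test_that("pangenome generation is deterministic given the seed", {
  cfg <- small_config(seed = 42)
  a <- simulate_pangenome(cfg)
  b <- simulate_pangenome(cfg)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$annotations, b$annotations)
})

test_that("COG labels come from the 23-category alphabet with planted skew", {
  cfg <- sim_config(n_clusters = 3000, core_fraction = 0.45,
                    unique_fraction = 0.3, seed = 5)
  pg <- simulate_pangenome(cfg)
  labs <- pg$cluster_cog[!is.na(pg$cluster_cog)]
  expect_true(all(labs %in% cog_categories()))
  groups <- assign_frequency_groups(pg$matrix)
  core_ids <- groups$cluster_id[groups$group == "core"]
  uni_ids <- groups$cluster_id[groups$is_unique]
  # unassigned fraction is much higher among unique clusters
  expect_gt(mean(is.na(pg$cluster_cog[uni_ids])),
            mean(is.na(pg$cluster_cog[core_ids])) + 0.2)
  # housekeeping categories over-represented in core vs unique
  hk <- mean(pg$cluster_cog[core_ids] %in% c("C", "D", "E", "O"),
             na.rm = TRUE)
  hk_uni <- mean(pg$cluster_cog[uni_ids] %in% c("C", "D", "E", "O"),
                 na.rm = TRUE)
  expect_gt(hk, hk_uni)
})

test_that("gene-call counts pool back to the drawn cluster totals", {
  cfg <- small_config(seed = 7, genes_per_cluster_mean = 2.5)
  study <- simulate_study(cfg)
  ann <- study$pangenome$annotations
  cmap <- setNames(ann$cluster_id, ann$gene_call_id)
  for (g in names(study$counts)) {
    tab <- study$counts[[g]]
    pooled <- pool_counts(tab$counts, cmap)
    totals <- tab$cluster_totals[rownames(pooled), colnames(pooled)]
    expect_identical(unname(pooled), unname(totals))
  }
})

test_that("simulated counts match the negative-binomial moment formula", {
  # a narrow mean band pins every cluster baseline to ~100 counts, so the
  # pooled-by-sample draws behave as NB(mu = 100, alpha = 0.1) draws
  cfg <- sim_config(n_clusters = 900, core_fraction = 1, unique_fraction = 0,
                    nb_mean_log_range = c(2, 2), nb_dispersion = 0.1,
                    planted_log2fc_magnitude = 0, seed = 9)
  study <- simulate_study(cfg)
  draws <- as.vector(study$counts$G1$cluster_totals)
  expect_gt(length(draws), 5000)
  expect_lt(abs(var(draws) / (100 + 0.1 * 100^2) - 1), 0.1)
  expect_lt(abs(mean(draws) / 100 - 1), 0.05)
})

test_that("zero planted magnitude produces a truth table with no DE", {
  cfg <- small_config(seed = 11, planted_log2fc_magnitude = 0)
  study <- simulate_study(cfg)
  expect_false(any(study$truth$is_de))
  expect_true(all(study$truth$true_log2fc == 0))
})

test_that("noiseless curves equal the generating models exactly", {
  cfg <- small_config(seed = 13, curve_noise_cv = 0)
  cp <- plant_concordance(cfg)
  curves <- simulate_curves(cfg, cp$hill_params, cp$gompertz_params)
  # induction Fss at zero inducer equals the baseline C
  cv1 <- curves$induction[["G1.Ara"]]
  p1 <- cp$hill_params[cp$hill_params$host == "G1" &
                         cp$hill_params$inducer == "Ara", ]
  expect_equal(unique(cv1$fss[cv1$concentrations == 0]), p1$C)
  # all induction values match the Hill model
  expect_equal(cv1$fss,
               hill_response(cv1$concentrations, p1$beta, p1$K, p1$n, p1$C))
  # growth curve equals the exponentiated Gompertz model
  g1 <- curves$growth[curves$growth$host == "G1" &
                        curves$growth$condition == "NI", ]
  gp <- cp$gompertz_params[cp$gompertz_params$host == "G1" &
                             cp$gompertz_params$condition == "NI", ]
  expect_equal(g1$value,
               0.05 * exp(gompertz_response(g1$time_h, gp$A, gp$mu,
                                            gp$lambda)),
               tolerance = 1e-12)
})

test_that("Gompertz reaches its plateau far beyond the lag", {
  A <- 1.2; mu <- 0.4; lambda <- 3
  t_late <- lambda + 10 * A / mu
  expect_lt(abs(gompertz_response(t_late, A, mu, lambda) - A), 1e-6 * A)
})

test_that("full latent coupling with no noise gives perfect concordance", {
  cfg <- small_config(seed = 17, concordance_strength = 1)
  cp <- plant_concordance(cfg)
  pr <- procrustes_m2(cp$latent_factors, cp$expr_latents)
  expect_lt(pr$m2, 1e-20)
  # determinism of the coupling block
  cp2 <- plant_concordance(cfg)
  expect_identical(cp$latent_factors, cp2$latent_factors)
  expect_identical(cp$true_performance, cp2$true_performance)
})

test_that("curve simulation rejects negative parameters", {
  cfg <- small_config(seed = 19)
  cp <- plant_concordance(cfg)
  bad <- cp$hill_params
  bad$K[1] <- -1
  expect_error(simulate_curves(cfg, bad, cp$gompertz_params), "negative")
})
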