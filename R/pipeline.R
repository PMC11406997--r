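# End-to-end orchestration: synthetic or file-based inputs through
# pangenome partitioning, kinetics, differential expression, concordance
# and ranking, with TSV outputs and a JSON run manifest.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if missing).
#' @param simulate generate the study synthetically (default TRUE).
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param inputs named list of file paths used when `simulate = FALSE`:
#'   `cluster_matrix` (TSV), `annotations` (TSV: gene_call_id,
#'   cluster_id, genome_id, cog_category), `counts` (named list per
#'   genome: counts/design/lengths TSV paths), `induction` (CSV: host,
#'   inducer, inducer_conc, replicate, fss), `growth` (CSV: host,
#'   condition, time_h, value), `fluorescence` (CSV: host, condition,
#'   channel, time_h, value).
#' @param seed master seed (default: the sim config's seed).
#' @param alpha significance level for DE and concordance (default 0.05).
#' @param n_perm PROTEST permutations (default 719).
#' @param window Fss window in hours (default `c(6, 12)`).
#' @param h,r2_min rolling-regression window size and R2 filter.
#' @param scopes log2FC matrix scopes to analyze
#'   (default `c("core", "accessory")`).
#' @param ranking_n size of the top differentiated list (default 100).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE, sim = sim_config(),
                            inputs = NULL, seed = NULL, alpha = 0.05,
                            n_perm = 719L, window = c(6, 12), h = 5L,
                            r2_min = 0.95,
                            scopes = c("core", "accessory"),
                            ranking_n = 100L) {
  stop_if_not(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  stop_if_not(n_perm >= 1, "n_perm must be >= 1")
  cfg <- list(out_dir = out_dir, simulate = simulate, sim = sim,
              inputs = inputs, seed = seed %||% sim$seed, alpha = alpha,
              n_perm = as.integer(n_perm), window = window,
              h = as.integer(h), r2_min = r2_min, scopes = scopes,
              ranking_n = as.integer(ranking_n))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' `sim:` block maps onto [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  args <- y[setdiff(names(y), "sim")]
  args$sim <- sim
  do.call(pipeline_config, args)
}

check_input_file <- function(path, what) {
  stop_if_not(!is.null(path) && file.exists(path),
              sprintf("missing input file for %s: %s", what,
                      path %||% "<unset>"))
  path
}

load_study_inputs <- function(cfg) {
  ins <- cfg$inputs
  stop_if_not(!is.null(ins), "simulate = FALSE requires inputs")
  mat <- read_cluster_matrix(check_input_file(ins$cluster_matrix,
                                              "cluster_matrix"))
  ann <- utils::read.delim(check_input_file(ins$annotations,
                                            "annotations"),
                           stringsAsFactors = FALSE)
  cc <- tapply(ann$cog_category, ann$cluster_id, function(v) v[1])
  cluster_cog <- rep(NA_character_, nrow(mat))
  names(cluster_cog) <- rownames(mat)
  cluster_cog[names(cc)] <- as.character(cc)
  counts <- lapply(ins$counts, function(p) {
    read_count_table(check_input_file(p$counts, "counts"),
                     check_input_file(p$design, "design"),
                     check_input_file(p$lengths, "lengths"))
  })
  ind_df <- read_plate_csv(check_input_file(ins$induction, "induction"))
  induction <- list()
  for (key in unique(paste(ind_df$host, ind_df$inducer, sep = "."))) {
    sub <- ind_df[paste(ind_df$host, ind_df$inducer, sep = ".") == key, ]
    induction[[key]] <- induction_curve(sub$inducer[1], sub$inducer_conc,
                                        sub$fss, sub$replicate,
                                        sub$host[1])
  }
  growth <- read_plate_csv(check_input_file(ins$growth, "growth"))
  fluor <- read_plate_csv(check_input_file(ins$fluorescence,
                                           "fluorescence"))
  list(pangenome = list(matrix = mat, annotations = ann,
                        cluster_cog = cluster_cog),
       counts = counts,
       curves = list(induction = induction, growth = growth,
                     fluorescence = fluor),
       truth = NULL, config = cfg$sim)
}

#' Run the full chassis-effect analysis on a simulated study
#'
#' The computational core shared by [run_all()] and validation code:
#' pools each host's gene-call counts to cluster level, runs the NB Wald
#' DE stage per host, builds the masked log2FC matrix for the requested
#' scope, estimates the device-performance matrix from the induction and
#' growth curves, projects both blocks onto two principal components and
#' tests their concordance with PROTEST.
#'
#' @param study a `simulated_study` (or the list returned by the
#'   file-based loader).
#' @param scope log2FC scope: "core", "accessory" or "all".
#' @param alpha DE significance level (default 0.05).
#' @param n_perm PROTEST permutations (default 719).
#' @param seed seed recorded for sampled permutations.
#' @return list: de_results, groups, logfc, performance, protest
#'   (a `procrustes_result` with p-value), configs.
#' @export
analyze_study <- function(study, scope = "core", alpha = 0.05,
                          n_perm = 719L, seed = NULL) {
  groups <- assign_frequency_groups(study$pangenome$matrix)
  ann <- study$pangenome$annotations
  cmap <- stats::setNames(ann$cluster_id, ann$gene_call_id)
  de_results <- lapply(study$counts, function(tab) {
    pooled <- pool_counts(tab$counts, cmap)
    nb_wald_test(pooled, tab$design$condition, alpha = alpha)
  })
  logfc <- build_logfc_matrix(de_results, groups, scope = scope)
  perf <- performance_matrix(study$curves$induction, study$curves$growth,
                             panel = "ordination")
  perf_cfg <- pca_project(perf)
  expr_cfg <- pca_project(logfc)
  pr <- protest(perf_cfg, expr_cfg, n_perm = n_perm, seed = seed)
  list(de_results = de_results, groups = groups, logfc = logfc,
       performance = perf, performance_config = perf_cfg,
       expression_config = expr_cfg, protest = pr)
}

#' Run the complete pipeline and write all outputs
#'
#' Executes simulate (optional) -> pangenome -> kinetics -> expression ->
#' concordance -> ranking. Each stage's outputs are written before the
#' next stage starts; the JSON run manifest is written last and records
#' the configuration snapshot, per-stage seeds, row counts and warnings,
#' so a re-run from the manifest reproduces every deterministic output.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (invisibly), as a list.
#' @export
run_all <- function(config) {
  stop_if_not(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(
    config = config_snapshot(config),
    seed = config$seed,
    substreams = c("pangenome", "coupling", "de", "counts", "curves"),
    stages = list(), warnings = character()
  )
  note <- function(stage, rows) {
    manifest$stages[[stage]] <<- list(rows = rows)
  }

  # stage: study
  study <- if (config$simulate) {
    sim <- config$sim
    sim$seed <- as.integer(config$seed)
    simulate_study(sim)
  } else {
    load_study_inputs(config)
  }
  if (config$simulate) {
    write_cluster_matrix(study$pangenome$matrix, out("cluster_matrix.tsv"))
    write_tsv(study$pangenome$annotations, out("annotations.tsv"))
    write_tsv(study$truth, out("truth.tsv"))
    for (g in names(study$counts)) {
      tab <- study$counts[[g]]
      write_tsv(data.frame(gene_call_id = rownames(tab$counts),
                           as.data.frame(tab$counts), check.names = FALSE),
                out(sprintf("counts_%s.tsv", g)))
      write_tsv(tab$design, out(sprintf("design_%s.tsv", g)))
      write_tsv(data.frame(gene_call_id = names(tab$gene_lengths),
                           length_bp = unname(tab$gene_lengths)),
                out(sprintf("lengths_%s.tsv", g)))
    }
  }
  note("study", nrow(study$pangenome$matrix))

  # stage: pangenome
  groups <- assign_frequency_groups(study$pangenome$matrix)
  comp <- summarize_groups(groups)
  write_tsv(comp, out("pangenome_summary.tsv"))
  enr <- suppressMessages(
    cog_group_enrichment(study$pangenome$annotations, groups)
  )
  write_tsv(enr, out("cog_enrichment.tsv"))
  note("pangenome", nrow(groups))

  # stage: kinetics
  hill <- do.call(rbind, lapply(study$curves$induction, function(cv) {
    f <- fit_hill(cv)
    data.frame(host = f$host, inducer = f$inducer, beta = f$beta,
               K = f$K, n = f$n, C = f$C, DR = f$DR,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
  write_tsv(hill, out("hill_fits.tsv"))
  gomp <- do.call(rbind, lapply(split(
    study$curves$growth,
    paste(study$curves$growth$host, study$curves$growth$condition)),
    function(sub) {
      sub <- sub[order(sub$time_h), ]
      f <- fit_gompertz_lag(sub$time_h, log(sub$value))
      mu_roll <- rolling_max_rate(sub$time_h, sub$value, config$h,
                                  config$r2_min)$mu
      data.frame(host = sub$host[1], condition = sub$condition[1],
                 A = f$A, mu = f$mu, lambda = f$lambda,
                 mu_rolling = mu_roll, converged = f$converged,
                 stringsAsFactors = FALSE)
    }))
  write_tsv(gomp, out("gompertz_fits.tsv"))
  tog <- toggle_metrics(study$curves$fluorescence, config$window,
                        config$h, config$r2_min)
  write_tsv(tog, out("toggle_metrics.tsv"))
  perf <- performance_matrix(study$curves$induction, study$curves$growth)
  write_logfc_matrix(perf, out("performance_matrix.tsv"))
  note("kinetics", nrow(hill) + nrow(gomp))

  # stage: expression
  ann <- study$pangenome$annotations
  cmap <- stats::setNames(ann$cluster_id, ann$gene_call_id)
  de_results <- lapply(study$counts, function(tab) {
    pooled <- pool_counts(tab$counts, cmap)
    nb_wald_test(pooled, tab$design$condition, alpha = config$alpha)
  })
  for (g in names(de_results)) {
    write_tsv(de_results[[g]], out(sprintf("de_%s.tsv", g)))
  }
  logfc_by_scope <- list()
  for (sc in config$scopes) {
    logfc_by_scope[[sc]] <- build_logfc_matrix(de_results, groups,
                                               scope = sc)
    write_logfc_matrix(logfc_by_scope[[sc]],
                       out(sprintf("logfc_%s.tsv", sc)))
  }
  note("expression", sum(vapply(de_results, nrow, 0L)))

  # stage: concordance
  perf_ord <- performance_matrix(study$curves$induction,
                                 study$curves$growth,
                                 panel = "ordination")
  perf_cfg <- pca_project(perf_ord)
  conc <- do.call(rbind, lapply(config$scopes, function(sc) {
    expr_cfg <- pca_project(logfc_by_scope[[sc]])
    pr <- protest(perf_cfg, expr_cfg, n_perm = config$n_perm,
                  seed = config$seed)
    data.frame(scope = sc, m2 = pr$m2, t_stat = pr$t_stat,
               p_value = pr$p_value, n_perm = pr$n_perm,
               seed = config$seed, stringsAsFactors = FALSE)
  }))
  write_tsv(conc, out("concordance.tsv"))
  first_scope <- config$scopes[1]
  percat <- per_category_concordance(
    logfc_by_scope[[first_scope]], study$pangenome$cluster_cog, perf_cfg,
    n_perm = config$n_perm, seed = config$seed, alpha = config$alpha)
  write_tsv(percat, out(sprintf("concordance_per_cog_%s.tsv",
                                first_scope)))
  note("concordance", nrow(conc) + nrow(percat))

  # stage: ranking
  scores <- score_clusters(build_logfc_matrix(de_results, groups, "all"))
  top <- top_differentiated(scores, config$ranking_n)
  cc <- study$pangenome$cluster_cog[top$cluster_id]
  top$cog_category <- ifelse(is.na(cc), "NA", cc)
  write_tsv(top, out("top_differentiated.tsv"))
  note("ranking", nrow(top))

  manifest$package_version <- as.character(utils::packageVersion(
    "chassisconcord"))
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, out("manifest.json"))
  invisible(manifest)
}

# plain-list snapshot of a pipeline_config for the manifest
config_snapshot <- function(cfg) {
  snap <- unclass(cfg)
  snap$sim <- unclass(snap$sim)
  snap$inputs <- NULL
  snap
}
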