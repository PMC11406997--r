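# Synthetic chassis-effect study generator.
#
# All stages draw from named substreams of the master seed ("pangenome",
# "coupling", "de", "counts", "curves") so each block is independently
# reproducible.

#' Simulate a pangenome gene-cluster matrix with COG annotations
#'
#' Generates a clusters x genomes gene-call count matrix whose composition
#' matches the requested core / accessory / unique fractions exactly after
#' rounding. Mid-frequency accessory clusters get an occupancy size drawn
#' uniformly from `2..n_genomes-1` and a uniformly chosen genome subset.
#' Each cluster carries a COG category label (or NA); category weights are
#' skewed by frequency group so that core clusters over-represent
#' housekeeping categories (C, D, E, F, H, J, M, O), accessory clusters
#' over-represent transport/metabolism and transcription (G, K, P, Q, T)
#' and unique clusters over-represent mobilome and defense (V, X), giving
#' enrichment tests recoverable signal.
#'
#' @param config a [sim_config()].
#' @return a list with elements `matrix` (a [gene_cluster_matrix()]),
#'   `annotations` (data.frame: gene_call_id, cluster_id, genome_id,
#'   cog_category) and `cluster_cog` (named per-cluster category vector,
#'   `NA` for unassigned).
#' @export
simulate_pangenome <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, "pangenome", {
    n <- config$n_genomes
    nc <- config$n_clusters
    n_core <- round(config$core_fraction * nc)
    n_unique <- round(config$unique_fraction * nc)
    n_mid <- nc - n_core - n_unique
    stop_if_not(n_mid >= 0, "rounded core + unique exceed n_clusters")
    stop_if_not(n_mid == 0 || n >= 3,
                "mid-frequency accessory clusters need n_genomes >= 3")

    genome_ids <- sprintf("G%d", seq_len(n))
    cluster_ids <- sprintf("GC_%05d", seq_len(nc))
    group <- rep(c("core", "accessory", "unique"),
                 times = c(n_core, n_mid, n_unique))

    occ <- matrix(FALSE, nc, n, dimnames = list(cluster_ids, genome_ids))
    if (n_core > 0) occ[seq_len(n_core), ] <- TRUE
    if (n_mid > 0) {
      sizes <- sample(2:(n - 1), n_mid, replace = TRUE)
      for (i in seq_len(n_mid)) {
        occ[n_core + i, sample.int(n, sizes[i])] <- TRUE
      }
    }
    if (n_unique > 0) {
      rows <- nc - n_unique + seq_len(n_unique)
      occ[cbind(rows, sample.int(n, n_unique, replace = TRUE))] <- TRUE
    }

    counts <- matrix(0L, nc, n, dimnames = dimnames(occ))
    n_slots <- sum(occ)
    counts[occ] <- 1L + stats::rpois(n_slots,
                                     config$genes_per_cluster_mean - 1)

    cluster_cog <- assign_cluster_cogs(group, config)
    names(cluster_cog) <- cluster_ids

    ann <- do.call(rbind, lapply(seq_len(n), function(j) {
      idx <- which(counts[, j] > 0L)
      reps <- counts[idx, j]
      data.frame(
        gene_call_id = sprintf("%s_gc%05d", genome_ids[j],
                               seq_len(sum(reps))),
        cluster_id = rep(cluster_ids[idx], reps),
        genome_id = genome_ids[j],
        cog_category = rep(cluster_cog[idx], reps),
        stringsAsFactors = FALSE
      )
    }))
    rownames(ann) <- NULL

    list(matrix = gene_cluster_matrix(counts), annotations = ann,
         cluster_cog = cluster_cog)
  })
}

# Per-cluster COG labels with group-dependent category skew.
assign_cluster_cogs <- function(group, config) {
  cats <- cog_categories()
  skew_sets <- list(
    core = c("C", "D", "E", "F", "H", "J", "M", "O"),
    accessory = c("G", "K", "P", "Q", "T"),
    unique = c("V", "X")
  )
  na_frac <- stats::setNames(config$cog_na_fraction,
                             c("core", "accessory", "unique"))
  out <- rep(NA_character_, length(group))
  for (g in unique(group)) {
    idx <- which(group == g)
    w <- rep(1, length(cats))
    w[cats %in% skew_sets[[g]]] <- config$cog_skew
    assigned <- stats::runif(length(idx)) >= na_frac[[g]]
    out[idx[assigned]] <- sample(cats, sum(assigned), replace = TRUE,
                                 prob = w / sum(w))
  }
  out
}

#' Plant a latent coupling between device performance and core expression
#'
#' Draws two standard-normal latent factors per host. Device-performance
#' parameters (Hill and Gompertz, on the log scale) load on these factors;
#' the host-specific component of planted core-cluster log2 fold-changes
#' loads on a second set of latents that shares a `concordance_strength`
#' fraction of signal with the first. At strength 1 (and no noise) the two
#' blocks have identical latent geometry, so Procrustes superimposition of
#' their principal-component projections is perfect; at strength 0 they are
#' independent.
#'
#' @param config a [sim_config()].
#' @return list with `latent_factors` (hosts x 2, drives performance),
#'   `expr_latents` (hosts x 2, drives expression), `hill_params`,
#'   `gompertz_params` (data.frames of generating curve parameters per
#'   host) and `true_performance` (hosts x metrics log-scale matrix).
#' @export
plant_concordance <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, "coupling", {
    n <- config$n_genomes
    hosts <- sprintf("G%d", seq_len(n))
    L <- matrix(stats::rnorm(2 * n), n, 2,
                dimnames = list(hosts, c("LF1", "LF2")))
    # concordance_strength is the fraction of each expression latent's
    # variance that is shared with the performance latents
    cs <- config$concordance_strength
    Z <- matrix(stats::rnorm(2 * n), n, 2)
    M <- sqrt(cs) * L + sqrt(1 - cs) * Z
    dimnames(M) <- dimnames(L)

    # log-scale base values of the generating curve parameters
    base <- c(
      K_Ara = log(0.08), beta_Ara = log(3000), n_Ara = log(1.8),
      C_Ara = log(120),
      K_aTc = log(8), beta_aTc = log(1500), n_aTc = log(2.2),
      C_aTc = log(250),
      mu = log(0.55), A = log(3.2), lambda = log(2.5)
    )
    # Per-parameter latent spread on the log scale, sized to the kind of
    # host-to-host variation an inverter shows across related species:
    # activation coefficients K vary by more than an order of magnitude,
    # maximal outputs several-fold, growth parameters far less.
    loading_scale <- c(
      K_Ara = 0.5, beta_Ara = 0.4, n_Ara = 0.15, C_Ara = 0.3,
      K_aTc = 0.5, beta_aTc = 0.4, n_aTc = 0.15, C_aTc = 0.3,
      mu = 0.15, A = 0.1, lambda = 0.15
    )
    noise_sd <- 0.05     # residual host-level noise
    # balanced loadings: rows whitened against the per-metric spreads so
    # that the effective loading matrix W %*% diag(D) has orthogonal rows
    # of equal norm -- both latent dimensions are then represented
    # isotropically across the metric panel and the planted geometry is
    # recoverable by PCA up to rotation
    D <- loading_scale[names(base)]
    G <- matrix(stats::rnorm(2 * length(base)), 2, length(base))
    S <- G %*% diag(D^2) %*% t(G)
    es <- eigen(S, symmetric = TRUE)
    S_invsqrt <- es$vectors %*% diag(1 / sqrt(es$values)) %*%
      t(es$vectors)
    W <- sqrt(sum(D^2)) * S_invsqrt %*% G
    W <- sweep(W, 2, D, "*")
    colnames(W) <- names(base)
    perf_log <- sweep(L %*% W, 2, base, "+") +
      matrix(stats::rnorm(n * length(base), sd = noise_sd), n)
    dimnames(perf_log) <- list(hosts, names(base))

    hill_params <- do.call(rbind, lapply(c("Ara", "aTc"), function(ind) {
      data.frame(
        host = hosts, inducer = ind,
        beta = exp(perf_log[, paste0("beta_", ind)]),
        K = exp(perf_log[, paste0("K_", ind)]),
        n = exp(perf_log[, paste0("n_", ind)]),
        C = exp(perf_log[, paste0("C_", ind)]),
        stringsAsFactors = FALSE
      )
    }))
    rownames(hill_params) <- NULL

    # induction burden: Ara operation slows growth more than aTc here
    burden <- c(NI = 1, Ara = 0.8, aTc = 0.92)
    gompertz_params <- do.call(rbind, lapply(names(burden), function(cond) {
      data.frame(
        host = hosts, condition = cond,
        A = exp(perf_log[, "A"]) * ifelse(cond == "NI", 1, 0.95),
        mu = exp(perf_log[, "mu"]) * burden[[cond]],
        lambda = exp(perf_log[, "lambda"]),
        stringsAsFactors = FALSE
      )
    }))
    rownames(gompertz_params) <- NULL

    list(latent_factors = L, expr_latents = M, hill_params = hill_params,
         gompertz_params = gompertz_params, true_performance = perf_log)
  })
}

#' Plant per-host true log2 fold-changes and DE flags
#'
#' Selects `de_fraction_core` of core clusters and `de_fraction_accessory`
#' of accessory clusters as differentially expressed. Planted core clusters
#' get a shared signed magnitude plus a host-specific component driven by
#' the expression latents of [plant_concordance()]; accessory planted
#' clusters get the shared magnitude only.
#'
#' @param pangenome result of [simulate_pangenome()].
#' @param coupling result of [plant_concordance()].
#' @param config a [sim_config()].
#' @return data.frame with columns cluster_id, genome, true_log2fc, is_de
#'   (one row per occupied cluster x genome slot).
#' @export
plant_de_truth <- function(pangenome, coupling, config) {
  with_substream(config$seed, "de", {
    mat <- pangenome$matrix
    groups <- assign_frequency_groups(mat)
    cl <- rownames(mat)
    core_idx <- which(groups$group == "core")
    acc_idx <- which(groups$group == "accessory")
    n_core_de <- round(length(core_idx) * config$de_fraction_core)
    n_acc_de <- round(length(acc_idx) * config$de_fraction_accessory)
    de_core <- sort(sample(core_idx, n_core_de))
    de_acc <- sort(sample(acc_idx, n_acc_de))

    mag <- config$planted_log2fc_magnitude
    lfc <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
    if (mag > 0) {
      if (n_core_de > 0) {
        sgn <- sample(c(-1, 1), n_core_de, replace = TRUE)
        Wk <- matrix(stats::rnorm(2 * n_core_de), 2, n_core_de)
        dev <- coupling$expr_latents %*% Wk * config$latent_logfc_scale
        # dev is hosts x clusters; the log2FC store is clusters x hosts
        lfc[de_core, ] <- sgn * mag + t(dev)
      }
      if (n_acc_de > 0) {
        sgn <- sample(c(-1, 1), n_acc_de, replace = TRUE)
        lfc[de_acc, ] <- matrix(sgn * mag, n_acc_de, ncol(mat))
      }
    }
    is_de_cluster <- logical(nrow(mat))
    if (mag > 0) is_de_cluster[c(de_core, de_acc)] <- TRUE

    occ <- mat > 0
    idx <- which(occ, arr.ind = TRUE)
    out <- data.frame(
      cluster_id = cl[idx[, 1]],
      genome = colnames(mat)[idx[, 2]],
      true_log2fc = ifelse(is_de_cluster[idx[, 1]], lfc[idx], 0),
      is_de = is_de_cluster[idx[, 1]],
      stringsAsFactors = FALSE
    )
    out[order(out$genome, out$cluster_id), , drop = FALSE]
  })
}

#' Simulate per-genome RNA-seq gene-call count tables
#'
#' Cluster-level totals are drawn negative-binomial with a per-cluster
#' baseline mean (log10-uniform over `nb_mean_log_range`, shared across
#' genomes) and dispersion `nb_dispersion`. The planted log2 fold-change is
#' split symmetrically between conditions (Ara mean `mu * 2^(lfc/2)`, aTc
#' mean `mu * 2^(-lfc/2)`), and totals of multi-gene clusters are
#' distributed multinomially across member gene calls so that pooling by
#' cluster recovers the drawn totals exactly.
#'
#' @param pangenome result of [simulate_pangenome()].
#' @param truth result of [plant_de_truth()] (or NULL for no planted DE).
#' @param config a [sim_config()].
#' @return named list (one element per genome) with `counts` (gene calls x
#'   samples integer matrix), `design` (sample, condition, replicate),
#'   `gene_lengths` (bp, named), and `cluster_totals` (the drawn
#'   cluster-level totals, for conservation checks).
#' @export
simulate_counts <- function(pangenome, truth = NULL, config) {
  validate_sim_config(config)
  with_substream(config$seed, "counts", {
    mat <- pangenome$matrix
    ann <- pangenome$annotations
    nrep <- config$n_replicates
    conds <- rep(c("Ara", "aTc"), each = nrep)
    samples <- paste0(conds, "_", rep(seq_len(nrep), 2))
    base_mu <- 10^stats::runif(nrow(mat), config$nb_mean_log_range[1],
                               config$nb_mean_log_range[2])
    names(base_mu) <- rownames(mat)
    size <- 1 / config$nb_dispersion

    lfc_lookup <- NULL
    if (!is.null(truth)) {
      lfc_lookup <- truth$true_log2fc
      names(lfc_lookup) <- paste(truth$genome, truth$cluster_id)
    }

    out <- list()
    for (g in colnames(mat)) {
      members <- ann[ann$genome_id == g, , drop = FALSE]
      cl_present <- rownames(mat)[mat[, g] > 0]
      lfc <- rep(0, length(cl_present))
      if (!is.null(lfc_lookup)) {
        hit <- lfc_lookup[paste(g, cl_present)]
        lfc <- ifelse(is.na(hit), 0, hit)
      }
      mu_ara <- base_mu[cl_present] * 2^(lfc / 2)
      mu_atc <- base_mu[cl_present] * 2^(-lfc / 2)
      mu <- cbind(matrix(mu_ara, ncol = nrep, nrow = length(cl_present)),
                  matrix(mu_atc, ncol = nrep, nrow = length(cl_present)))
      totals <- matrix(
        stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
        nrow = length(cl_present),
        dimnames = list(cl_present, samples)
      )
      storage.mode(totals) <- "integer"

      gene_counts <- matrix(0L, nrow(members), length(samples),
                            dimnames = list(members$gene_call_id, samples))
      split_idx <- split(seq_len(nrow(members)), members$cluster_id)
      for (cl in cl_present) {
        rows <- split_idx[[cl]]
        k <- length(rows)
        if (k == 1L) {
          gene_counts[rows, ] <- totals[cl, ]
        } else {
          gene_counts[rows, ] <- vapply(
            totals[cl, ],
            function(tt) stats::rmultinom(1, tt, rep(1 / k, k))[, 1],
            integer(k)
          )
        }
      }
      lengths <- pmax(100, round(stats::rlnorm(nrow(members), log(900),
                                               0.35)))
      names(lengths) <- members$gene_call_id
      out[[g]] <- list(
        counts = gene_counts,
        design = data.frame(sample = samples, condition = conds,
                            replicate = rep(seq_len(nrep), 2),
                            stringsAsFactors = FALSE),
        gene_lengths = lengths,
        cluster_totals = totals
      )
    }
    out
  })
}

# mean-1 lognormal multiplicative noise
lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Evaluate the Hill induction response
#'
#' `Fss(x) = beta * x^n / (K^n + x^n) + C`, the steady-state fluorescence
#' at inducer concentration `x`. At `x = 0` the value is the empirical
#' baseline `C`.
#'
#' @param x inducer concentration(s), >= 0.
#' @param beta maximal output above baseline (RFU).
#' @param K activation coefficient (inducer units).
#' @param n Hill coefficient.
#' @param C baseline output at zero inducer (RFU).
#' @return model value(s).
#' @export
hill_response <- function(x, beta, K, n, C) {
  stop_if_not(all(c(beta, K, n) >= 0), "Hill parameters must be >= 0")
  ifelse(x == 0, C, beta * x^n / (K^n + x^n) + C)
}

#' Evaluate the modified Gompertz growth model with lag
#'
#' Zwietering parameterization:
#' `y(t) = y0 + A * exp(-exp((mu * e / A) * (lambda - t) + 1))`,
#' where `mu` is the maximum specific rate (the slope at the inflection),
#' `A` the plateau above `y0` and `lambda` the lag time.
#'
#' @param t time (h).
#' @param A plateau height above baseline.
#' @param mu maximum specific rate (1/h).
#' @param lambda lag time (h).
#' @param y0 baseline value (default 0).
#' @return model value(s).
#' @export
gompertz_response <- function(t, A, mu, lambda, y0 = 0) {
  stop_if_not(all(c(A, mu) > 0) && lambda >= 0,
              "Gompertz parameters must be positive (lambda >= 0)")
  y0 + A * exp(-exp((mu * exp(1) / A) * (lambda - t) + 1))
}

#' Simulate induction, toggle and growth curves
#'
#' Induction assays are simulated as per-concentration steady-state
#' fluorescence (Fss) replicates from the Hill model, including
#' zero-inducer wells so the empirical baseline C is computable. Growth
#' (OD600) and toggle fluorescence curves are simulated on a fixed time
#' grid as `v0 * exp(G(t))` where `G` is the modified Gompertz model on
#' the log scale -- so the generating `mu` is the maximum specific rate
#' recovered by [rolling_max_rate()] and by [fit_gompertz_lag()] on
#' `log(value)`, and `A` is the log-fold plateau. All values are
#' multiplied by mean-1 lognormal noise with coefficient of variation
#' `curve_noise_cv`.
#'
#' @param config a [sim_config()].
#' @param hill_params data.frame host, inducer, beta, K, n, C.
#' @param gompertz_params data.frame host, condition, A, mu, lambda.
#' @return list with `induction` (named list of [induction_curve()]
#'   objects, one per host x inducer), `growth` (long data.frame: host,
#'   condition, time_h, value) and `fluorescence` (long data.frame: host,
#'   condition, channel, time_h, value).
#' @export
simulate_curves <- function(config, hill_params, gompertz_params) {
  validate_sim_config(config)
  stop_if_not(all(hill_params$beta >= 0 & hill_params$K > 0 &
                    hill_params$n > 0 & hill_params$C >= 0),
              "negative Hill parameters")
  stop_if_not(all(gompertz_params$A > 0 & gompertz_params$mu > 0 &
                    gompertz_params$lambda >= 0),
              "negative Gompertz parameters")
  with_substream(config$seed, "curves", {
    cv <- config$curve_noise_cv
    tgrid <- seq(0, config$curve_time_max, by = config$curve_time_step)
    conc_max <- c(Ara = 1.5, aTc = 160)  # mM Ara / nM aTc

    induction <- list()
    for (i in seq_len(nrow(hill_params))) {
      p <- hill_params[i, ]
      concs <- c(0, conc_max[[p$inducer]] / 2^(6:0))
      obs_conc <- rep(concs, each = config$n_curve_replicates)
      fss <- hill_response(obs_conc, p$beta, p$K, p$n, p$C) *
        lognoise(length(obs_conc), cv)
      induction[[paste(p$host, p$inducer, sep = ".")]] <- induction_curve(
        inducer = p$inducer, concentrations = obs_conc, fss = fss,
        replicate = rep(seq_len(config$n_curve_replicates), length(concs)),
        host = p$host
      )
    }

    od0 <- 0.05  # inoculum OD600
    growth <- do.call(rbind, lapply(seq_len(nrow(gompertz_params)),
      function(i) {
        p <- gompertz_params[i, ]
        v <- od0 * exp(gompertz_response(tgrid, p$A, p$mu, p$lambda)) *
          lognoise(length(tgrid), cv)
        data.frame(host = p$host, condition = p$condition, time_h = tgrid,
                   value = v, stringsAsFactors = FALSE)
      }))

    # toggle fluorescence: plateau set by induction state, kinetics by the
    # host's growth parameters
    hp <- split(hill_params, hill_params$inducer)
    fluor <- list()
    for (i in seq_len(nrow(gompertz_params))) {
      p <- gompertz_params[i, ]
      ha <- hp$Ara[hp$Ara$host == p$host, ]
      ht <- hp$aTc[hp$aTc$host == p$host, ]
      plateau <- list(
        sfGFP = c(NI = ha$C, Ara = ha$C + ha$beta, aTc = 0.5 * ha$C),
        mKate = c(NI = ht$C, Ara = 0.5 * ht$C, aTc = ht$C + ht$beta)
      )
      for (ch in names(plateau)) {
        f_max <- plateau[[ch]][[p$condition]]
        f0 <- 0.02 * f_max  # pre-induction background fluorescence
        v <- f0 * exp(gompertz_response(tgrid, log(f_max / f0),
                                        p$mu * 1.2, p$lambda)) *
          lognoise(length(tgrid), cv)
        fluor[[length(fluor) + 1L]] <- data.frame(
          host = p$host, condition = p$condition, channel = ch,
          time_h = tgrid, value = v, stringsAsFactors = FALSE)
      }
    }
    list(induction = induction, growth = growth,
         fluorescence = do.call(rbind, fluor))
  })
}

#' Simulate a complete synthetic chassis-effect study
#'
#' Orchestrates [simulate_pangenome()], [plant_concordance()],
#' [plant_de_truth()], [simulate_counts()] and [simulate_curves()] into one
#' self-consistent study with known ground truth.
#'
#' @param config a [sim_config()].
#' @return object of class `simulated_study`: list with elements
#'   `config`, `pangenome`, `coupling`, `truth`, `counts`, `curves`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_clusters = 120, seed = 7))
#' dim(study$pangenome$matrix)
simulate_study <- function(config = sim_config()) {
  validate_sim_config(config)
  pangenome <- simulate_pangenome(config)
  coupling <- plant_concordance(config)
  truth <- plant_de_truth(pangenome, coupling, config)
  counts <- simulate_counts(pangenome, truth, config)
  curves <- simulate_curves(config, coupling$hill_params,
                            coupling$gompertz_params)
  structure(list(config = config, pangenome = pangenome,
                 coupling = coupling, truth = truth, counts = counts,
                 curves = curves),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic chassis-effect study: %d genomes, %d clusters, seed %d\n",
    x$config$n_genomes, x$config$n_clusters, x$config$seed))
  cat(sprintf("  planted DE clusters: %d\n",
              length(unique(x$truth$cluster_id[x$truth$is_de]))))
  invisible(x)
}
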