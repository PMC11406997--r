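#' Configuration for a synthetic chassis-effect study
#'
#' Bundles every tunable of the synthetic-study generator. The defaults
#' emulate the experimental design the analysis was built for: six closely
#' related bacterial hosts carrying an identical inducible genetic inverter,
#' a pangenome of 6,469 orthologous gene clusters of which 42.5% are core
#' (present in all hosts) and 31.1% unique (present in exactly one), RNA-seq
#' in biological triplicate per induction state (Ara vs aTc), and
#' plate-reader curves with multiplicative noise.
#'
#' @param n_genomes number of host genomes (default 6).
#' @param n_clusters number of orthologous gene clusters (default 6469).
#' @param core_fraction fraction of clusters present in all genomes
#'   (default 0.425).
#' @param unique_fraction fraction of clusters present in exactly one genome
#'   (default 0.311). `core_fraction + unique_fraction` must be <= 1; the
#'   remainder is accessory with occupancy drawn uniformly from
#'   `2..n_genomes-1`.
#' @param genes_per_cluster_mean mean number of gene calls a cluster
#'   contributes per occupied genome (>= 1; the excess over 1 is Poisson).
#'   Default 1.04, matching roughly one paralog per 25 cluster-genome slots.
#' @param nb_mean_log_range pair: log10 range of per-cluster baseline
#'   expression means (default `c(0.5, 3)`, i.e. ~3 to 1000 counts).
#' @param nb_dispersion negative-binomial dispersion alpha in
#'   `var = mu + alpha * mu^2` (default 0.1).
#' @param n_replicates RNA-seq replicates per condition (default 3).
#' @param de_fraction_core,de_fraction_accessory fraction of core / accessory
#'   clusters planted as differentially expressed (defaults 0.6 and
#'   0.25: in a strongly induced inverter most core clusters respond,
#'   and the accessory response is markedly sparser).
#' @param planted_log2fc_magnitude absolute log2 fold-change of planted DE
#'   clusters (default 2).
#' @param concordance_strength in [0,1]: fraction of shared latent signal
#'   between each host's performance metrics and its core-cluster log2FC
#'   profile. 0 makes the two blocks independent; 1 gives identical latent
#'   geometry. Default 0.7.
#' @param latent_logfc_scale standard-deviation scale of the latent-driven,
#'   host-specific component of planted core log2FCs (default 1).
#' @param curve_noise_cv coefficient of variation of the lognormal
#'   multiplicative noise on plate-reader curves (default 0.05).
#' @param curve_time_max,curve_time_step time grid for kinetic curves in
#'   hours (defaults 24 and 1/6, i.e. 10-minute sampling).
#' @param n_curve_replicates replicate wells per inducer concentration in
#'   induction assays (default 8).
#' @param cog_skew odds multiplier by which group-typical COG categories
#'   (housekeeping in core, metabolic transport in accessory, mobilome /
#'   defense in unique) are over-weighted when labelling clusters
#'   (default 3).
#' @param cog_na_fraction length-3 vector: probability that a core /
#'   accessory / unique cluster is COG-unassigned (default
#'   `c(0.08, 0.25, 0.5)`).
#' @param seed master integer seed; every stochastic stage derives its own
#'   substream from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_clusters = 200, seed = 1)
#' cfg$core_fraction
sim_config <- function(n_genomes = 6L,
                       n_clusters = 6469L,
                       core_fraction = 0.425,
                       unique_fraction = 0.311,
                       genes_per_cluster_mean = 1.04,
                       nb_mean_log_range = c(0.5, 3),
                       nb_dispersion = 0.1,
                       n_replicates = 3L,
                       de_fraction_core = 0.6,
                       de_fraction_accessory = 0.25,
                       planted_log2fc_magnitude = 2,
                       concordance_strength = 0.7,
                       latent_logfc_scale = 1,
                       curve_noise_cv = 0.05,
                       curve_time_max = 24,
                       curve_time_step = 1 / 6,
                       n_curve_replicates = 8L,
                       cog_skew = 3,
                       cog_na_fraction = c(0.08, 0.25, 0.5),
                       seed = 1L) {
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    n_clusters = as.integer(n_clusters),
    core_fraction = core_fraction,
    unique_fraction = unique_fraction,
    genes_per_cluster_mean = genes_per_cluster_mean,
    nb_mean_log_range = nb_mean_log_range,
    nb_dispersion = nb_dispersion,
    n_replicates = as.integer(n_replicates),
    de_fraction_core = de_fraction_core,
    de_fraction_accessory = de_fraction_accessory,
    planted_log2fc_magnitude = planted_log2fc_magnitude,
    concordance_strength = concordance_strength,
    latent_logfc_scale = latent_logfc_scale,
    curve_noise_cv = curve_noise_cv,
    curve_time_max = curve_time_max,
    curve_time_step = curve_time_step,
    n_curve_replicates = as.integer(n_curve_replicates),
    cog_skew = cog_skew,
    cog_na_fraction = cog_na_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if_not(cfg$n_genomes >= 2, "n_genomes must be >= 2")
  stop_if_not(cfg$n_clusters >= 1, "n_clusters must be >= 1")
  props <- c(cfg$core_fraction, cfg$unique_fraction, cfg$de_fraction_core,
             cfg$de_fraction_accessory, cfg$concordance_strength,
             cfg$cog_na_fraction)
  stop_if_not(all(props >= 0 & props <= 1),
              "all proportions must lie in [0, 1]")
  stop_if_not(cfg$core_fraction + cfg$unique_fraction <= 1,
              "infeasible fractions: core_fraction + unique_fraction > 1")
  stop_if_not(cfg$n_replicates >= 2, "n_replicates must be >= 2")
  stop_if_not(cfg$genes_per_cluster_mean >= 1,
              "genes_per_cluster_mean must be >= 1")
  stop_if_not(cfg$nb_dispersion > 0, "nb_dispersion must be positive")
  stop_if_not(cfg$curve_noise_cv >= 0, "curve_noise_cv must be >= 0")
  stop_if_not(length(cfg$nb_mean_log_range) == 2 &&
                diff(cfg$nb_mean_log_range) >= 0,
              "nb_mean_log_range must be an increasing pair")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic chassis-effect study configuration\n")
  cat(sprintf("  %d genomes, %d gene clusters (core %.1f%%, unique %.1f%%)\n",
              x$n_genomes, x$n_clusters, 100 * x$core_fraction,
              100 * x$unique_fraction))
  cat(sprintf("  NB counts: dispersion %.3g, %d replicates/condition\n",
              x$nb_dispersion, x$n_replicates))
  cat(sprintf("  planted |log2FC| %.2g, concordance strength %.2g, seed %d\n",
              x$planted_log2fc_magnitude, x$concordance_strength, x$seed))
  invisible(x)
}
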