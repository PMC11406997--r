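# chassisconcord

Pangenome-aware analysis of genetic device performance across bacterial
hosts.

## The problem

An identical genetic device — here an inducible *inverter* toggled
between two fluorescent states by L-arabinose (Ara) and
anhydrotetracycline (aTc) — performs very differently depending on which
host operates it. This host dependence is the **chassis-effect**, and it
is a central obstacle for broad-host-range synthetic biology: a circuit
optimized in one organism may behave arbitrarily in the next.

`chassisconcord` asks whether the chassis-effect can be traced through
genome structure and expression: do hosts whose *core genomes* (gene
clusters shared by all hosts) respond more similarly to device operation
also perform more similarly? The package provides every stage of that
analysis for a panel of related bacterial hosts, plus a synthetic-study
generator with planted ground truth so that each stage's statistical
behavior can be verified.

## What it computes

**Pangenome partitioning.** Gene clusters (orthologous groups across
genomes) are binned by the number of genomes they occur in: *core* (all
genomes), *accessory* (a strict subset), *unique* (exactly one, a subset
of accessory). Per genome and frequency group, COG functional categories
are tested for over/under-representation with one-sided Fisher exact
tests, Bonferroni-corrected across the 23 categories.

**Device performance.** Induction curves (steady-state fluorescence Fss
vs inducer concentration x) are fitted with the Hill model

    Fss(x) = beta * x^n / (K^n + x^n) + C

with the baseline `C` fixed to the empirical zero-inducer mean. Growth
and toggle fluorescence curves are summarized by the modified Gompertz
model with lag, `y(t) = y0 + A*exp(-exp((mu*e/A)*(lambda - t) + 1))`,
rolling-regression maximum specific rates, dynamic ranges `DR = beta/C`
and `DR_S = Fss_induced / Fss_NI`, and the growth difference
`delta_mu = ((mu1 - mu2)/mu1) * 100`.

**Cluster-level differential expression.** RNA-seq gene-call counts are
pooled to gene-cluster level (the cross-species comparison unit), then
tested per host with a simplified negative-binomial Wald stage:
median-of-ratios size factors, moment dispersion shrunk toward a fitted
mean-dispersion trend, normal Wald p-values, Benjamini-Hochberg
adjustment. Calibration is demonstrated by simulation (type-I error and
power), not by equivalence with any external engine.

**Concordance (the headline test).** The hosts-by-metrics performance
matrix and the hosts-by-clusters significant log2 fold-change matrix are
each projected onto their first two principal components; the two
6-point configurations are compared by Procrustes superimposition. The
**Gower statistic m²** is the sum of squared residuals after optimal
translation, rotation/reflection and scaling (symmetric form:
`m² = 1 - (sum of singular values of X'Y)²`), and **PROTEST** tests
`t = sqrt(1 - m²)` against row permutations of one configuration —
enumerated exactly (719 non-identity orderings) for six hosts.

**Differentiation ranking.** Clusters are ranked by the number of hosts
significantly expressing them, the sum of absolute log2 fold-changes,
and the combinatorial sum of pairwise absolute differences between
hosts, combined by rank sums.

## Worked example

```r
library(chassisconcord)

cfg <- sim_config(n_clusters = 400, core_fraction = 0.45,
                  unique_fraction = 0.3, concordance_strength = 0.9,
                  seed = 11)
study <- simulate_study(cfg)
summarize_groups(assign_frequency_groups(study$pangenome$matrix))
#>       group n_clusters percent
#> 1      core        180      45
#> 2 accessory        220      55
#> 3    unique        120      30

fit_hill(study$curves$induction[["G1.aTc"]])
#> Hill fit (aTc, G1): beta=2105 K=8.804 n=2.64 C=251.3 DR=8.38

res <- analyze_study(study, scope = "core", seed = 11)
res$protest
#> Procrustes superimposition: m2 = 0.1156, t = 0.9404, p = 0.001389 (719 permutations)
```

The composition table shows the requested core/accessory/unique split
realized exactly. The Hill fit recovers host G1's aTc response: maximal
output `beta` ≈ 2105 RFU above a baseline `C` ≈ 251 RFU (dynamic range
8.4-fold), half-activation at `K` ≈ 8.8 nM aTc. The Procrustes result
says the core-genome expression response and the device-performance
configuration agree far better than chance (m² = 0.12; only the
unpermuted ordering reaches this fit, p = 1/720): the study's planted
concordance (strength 0.9) is recovered.

The full pipeline — simulation or file inputs through pangenome,
kinetics, DE, concordance and ranking, with TSV outputs and a JSON run
manifest — runs via `run_all(pipeline_config(...))`, or from a shell via
`inst/cli/chassisconcord.R run-all --config cfg.yaml`.

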