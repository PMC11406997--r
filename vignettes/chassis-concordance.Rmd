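---
title: "Models and methods: quantifying the chassis-effect and its concordance with core-genome expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chassisconcord)
```

## The scientific question

When the same genetic device — an inducible inverter toggled between an
Ara-driven and an aTc-driven fluorescent state — is operated by several
related bacterial species, its measurable performance differs by host:
the chassis-effect. `chassisconcord` implements the statistical pipeline
for asking *where in the genome* that effect is traceable: it partitions
the hosts' pangenome into core, accessory and unique gene clusters,
quantifies device performance and growth from plate-reader curves,
estimates each host's transcriptional response to device operation at
the gene-cluster level, and then tests whether hosts with more similar
expression responses also have more similar performance — concordance,
assessed by Procrustes superimposition of two principal-component
projections with a permutation null.

Because each stage is a statistical estimator, the package also ships a
synthetic-study generator with planted ground truth. Every calibration
and recovery claim made below is computed by the test suite or by
`scripts/acceptance.R`; none is asserted from memory.

## Pangenome partitioning

A gene-cluster matrix records, for each orthologous gene cluster, how
many gene calls each genome contributes. A cluster's *bin* is the number
of genomes with at least one call; clusters in all genomes are core,
the rest accessory, and bin-1 clusters are additionally flagged unique.
Paralog multiplicity (counts above 1) affects gene-call tallies but
never binning.

Functional enrichment per genome and frequency group uses 2×2 one-sided
Fisher exact tests of gene calls (in-group × in-category), both
directions, Bonferroni-corrected across the COG categories present in
that genome. The unit of analysis is the gene call by default because a
genome's functional investment in a group scales with its gene content,
paralogs included; `unit = "clusters"` switches to distinct clusters.
A category is reported "consistently enriched" when significant in at
least 3 hosts. Categories absent from a genome are skipped with a log
note rather than tested against an empty margin.

Genome and expression-profile dendrograms use complete-linkage
agglomeration on Euclidean distances (`stats::hclust`, which merges the
lowest-index pair on ties, so results are deterministic).

## Kinetic models

**Induction.** The steady-state fluorescence response to inducer
concentration $x$ is the Hill function

$$F_{ss}(x) = \frac{\beta x^n}{K^n + x^n} + C,$$

with $\beta$ the maximal output above baseline (RFU), $K$ the activation
coefficient (mM Ara or nM aTc), $n$ the steepness, and $C$ the baseline.
$C$ is *not* fitted: it is the empirical mean of the zero-inducer wells,
which keeps the three fitted parameters identifiable from typical
7-point dilution series. Fitting is Levenberg–Marquardt on
per-concentration replicate means with multi-start ($K$ at the geometric
median concentration, $n \in \{0.5, 1, 2, 4\}$) under positivity bounds.
$K$ is additionally bounded one decade beyond the tested concentration
range: outside it the parameter is unidentifiable, and unbounded fits of
saturated curves run to degenerate optima. Non-convergence is flagged in
the result, never thrown. Fss itself is the mean over a late-growth
window, 6–12 h by default. The dynamic range is $DR = \beta / C$
(the largest fold-change the reporter can show), and the specific
dynamic range $DR_S$ is an induced state's Fss over the same host and
channel's non-induced Fss — values below 1 mean the induced output fell
under baseline.

**Growth and rates.** The maximum specific rate is estimated by rolling
regression: OLS of $\ln(\text{value})$ against time in windows of
`h = 5` points, keeping the maximum slope among windows with
$R^2 \ge 0.95$ (exactly constant windows count as $R^2 = 1$, yielding
rate 0 for flat curves rather than a filter failure). Whole curves are
summarized by the modified Gompertz model with lag,

$$y(t) = y_0 + A \exp\!\big(-\exp\big(\tfrac{\mu e}{A}(\lambda - t) + 1\big)\big),$$

where $\mu$ (1/h) is the slope at the inflection, $A$ the plateau above
$y_0$ and $\lambda$ (h) the lag. A package-wide convention keeps the two
estimators consistent: *the Gompertz model describes the log-scale
curve*. OD600 and fluorescence series are fitted as `log(value)`, so the
fitted $\mu$ is a maximum specific rate directly comparable with the
rolling-regression estimate (the suite checks agreement within 5%), and
$A$ is the log-fold plateau. Gompertz fitting is multi-start
Levenberg–Marquardt seeded from data extremes and the maximum raw-window
slope, with several lag starts; $y_0$ is unbounded below to accommodate
log-scale curves.

The growth difference between two conditions is reported as
$\Delta\mu = \frac{\mu_1 - \mu_2}{\mu_1} \cdot 100$ — the relative
percentage change, positive when condition 2 grows slower. This is the
only reading of "relative percentage change" that is dimensionally
consistent, and it is the definition implemented.

## Cluster-level differential expression

Counts of gene calls are pooled by gene cluster before testing —
pooling first means results are reported per cluster, the unit shared
across species, and column totals are conserved exactly (an invariant
the suite asserts as integer equality).

The DE stage is a deliberately simple negative-binomial Wald test,
validated by calibration rather than by mimicking any larger engine:

1. *Normalization*: median-of-ratios size factors (median over features
   positive in all samples of the count over the feature's geometric
   mean), rescaled to geometric mean 1, with a library-size fallback
   when no feature is everywhere-positive.
2. *Dispersion*: per-cluster method of moments from the pooled
   within-condition variance, then a linear shrink (weight 0.8 by
   default) toward a parametric trend $\alpha(\mu) = a_0 + a_1/\mu$
   fitted across clusters. With 3 replicates per condition the moment
   estimate is very noisy, so the trend dominates; the shrink weight is
   exposed for designs with more replicates. The shrink is arithmetic,
   not geometric: averaging on the log scale biases dispersion low and
   inflates the type-I error.
3. *Test*: log2 fold-change of normalized group means with a pseudocount
   of 0.5 (so clusters expressed in one condition only get finite,
   shrunken estimates — never log of zero), a delta-method standard
   error ($\mathrm{Var}\,\hat\mu_g = \sum_j (\mu/s_j + \alpha\mu^2)/n_g^2$),
   a two-sided normal p-value, and Benjamini–Hochberg adjustment across
   all clusters passing the all-zero filter, independently per host.

Under the study's design point (means near 100, dispersion 0.1, 3 vs 3),
the suite verifies a raw-p rejection rate within [0.03, 0.07] under the
null and recall ≥ 0.8 for planted |log2FC| = 2 at BH 0.05, across
multiple seeds.

The cross-host log2FC matrix is masked: a cell carries a host's estimate
only where that host's adjusted p is below 0.05; non-significant and
absent cells are exactly zero. For the accessory scope, unique clusters
are removed — a cluster present in one host has no between-host
comparison and only inflates distances.

## Concordance by Procrustes superimposition

Both blocks are projected to two principal components
(`stats::prcomp`; columns centered, not variance-scaled by default, with
a correlation-mode flag; deterministic sign convention: the
largest-magnitude loading of each component is positive; rank-deficient
inputs yield a zero second component with a warning).

Two projected configurations $X, Y$ (hosts as points) are compared in
the symmetric, scaled form: both are centered and scaled to unit sum of
squares, and the optimal rotation (reflections allowed — otherwise the
statistic would depend on arbitrary PCA sign conventions) comes from the
SVD of $X^\top Y$. The residual after optimal superimposition is the
Gower statistic

$$m^2 = 1 - \Big(\sum_i \sigma_i(X^\top Y)\Big)^2 \in [0, 1],$$

and significance of $t = \sqrt{1 - m^2}$ is assessed by PROTEST:
re-ordering the rows of one configuration (which preserves each block's
internal covariance), with the add-one p-value
$(1 + \#\{t_\pi \ge t_{obs}\})/(n_{perm} + 1)$. For 7 or fewer hosts all
non-identity orderings are enumerated — 719 for six hosts, making the
minimum attainable p exactly 1/720 — and random sampling is used above
that. Which matrix is permuted does not change the null by
exchangeability. The implementation is checked in two independent ways:
against a brute-force numeric optimizer over rotation angle, reflection
and scale (agreement within 1e-6 over hundreds of random
configurations) and against the `vegan` reference implementation of the
statistic.

The performance block entering the ordination is a non-redundant all-log
panel: the eight Hill parameters plus the non-induced growth $\mu$, $A$,
$\lambda$. Derived metrics (DR, which is $\beta/C$) and repeated
induction conditions are excluded from this panel on purpose: they
duplicate directions of host variation, which re-weights the projected
geometry — exactly the kind of distortion a rotation-and-scale-only
superimposition cannot absorb. The full metric table (with DR, toggle
metrics and per-condition growth) is still produced for reporting.

A second iteration splits the log2FC matrix by COG category and runs the
same test per category, reporting raw p-values (no multiplicity
correction by default, exposed as an option) and flagging categories
with fewer than two informative clusters as untestable.

## The synthetic-study generator

The generator emulates the statistical structure the analysis assumes,
with defaults matching a six-host inverter study: 6,469 clusters, 42.5%
core and 31.1% unique, triplicate RNA-seq per induction state,
negative-binomial counts with dispersion 0.1 and baselines spanning
3–1000 counts, 8-replicate induction series, 10-minute plate-reader
sampling over 24 h with 5% lognormal CV (multiplicative, since
plate-reader error scales with signal). Accessory occupancy is uniform
over sizes 2..n−1 with uniformly chosen genome subsets. COG labels are
skewed by group — housekeeping categories (C, D, E, F, H, J, M, O)
toward core, transport/metabolism and transcription (G, K, P, Q, T)
toward accessory, mobilome/defense (V, X) toward unique, with the
unassigned fraction rising from 8% (core) to 50% (unique) — so
enrichment tests have recoverable signal. All randomness flows from one
master seed through named substreams (pangenome, coupling, de, counts,
curves), so each block is independently reproducible.

**Planted concordance.** Two standard-normal latent factors per host
drive both blocks. Performance parameters load on the latents on the log
scale, with per-parameter spreads sized to a realistic chassis-effect
(activation coefficients vary by roughly an order of magnitude across
hosts; growth parameters by tens of percent), and the loading matrix is
whitened so that its effective rows are orthogonal with equal norm: the
latent geometry is embedded isotropically in metric space, hence
recoverable by PCA up to rotation — the transform family Procrustes can
absorb. Planted core clusters carry a shared signed log2FC of magnitude
2 plus a host-specific component loading on expression latents that
share a `concordance_strength` fraction of their *variance* with the
performance latents; accessory planted clusters carry the shared
magnitude only. At strength 1 with no noise the two latent blocks are
identical (m² = 0); at strength 0 they are independent and the PROTEST
p-value is uniform. The DE fractions default to 0.6 of core and 0.25 of
accessory clusters — in a strongly induced device most of the shared
core genome responds.

**What the generator does not emulate** — and therefore what passing
tests do not establish about real data: read-level effects (mapping
ambiguity, rRNA carryover, positional bias), library-composition
artifacts beyond global size factors, batch or plate effects,
cluster–cluster expression correlation (counts are independent given the
latents), orthology-inference errors in the cluster matrix itself,
autocorrelated plate-reader noise, and hysteresis dynamics of the
toggle. The pipeline's statistical calibration is demonstrated under the
generator's assumptions; on real data the NB Wald stage in particular
should be read as a screening stage, not a replacement for a full DE
engine.

## Validation problem sizes

The suite and acceptance script use scaled-down but structurally
faithful studies, chosen as the package's own validation design:
400-cluster studies for the 100 end-to-end concordance recovery runs,
2,000 clusters for DE calibration, 500 configuration pairs for the
PROTEST null, 200 random configurations against the brute-force
superimposition oracle, and 100 seeded fits per kinetic estimator. At
these sizes the whole suite runs in under a minute.

## Known limitations

* With six hosts the permutation floor is p = 1/720 and the PROTEST null
  is coarse; small m² differences between scopes are not interpretable
  as effect-size differences.
* The Hill fit fixes C empirically; systematic baseline drift between
  zero-inducer wells and the series would bias β and DR.
* K is reported at its bound (one decade beyond the grid) for curves
  saturated or unresponsive over the tested range; such fits carry a
  high residual and should be screened by the convergence flag and rss.
* The Wald normal approximation is anti-conservative for very low counts
  at n = 3; the all-zero filter and trend shrinkage contain but do not
  eliminate this.
* The rank-sum combination of the three differentiation components is
  one documented interpretation; a weighted-sum combiner is provided for
  sensitivity analysis.
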