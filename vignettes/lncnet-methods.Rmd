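---
title: "Methods: reversal-based lncRNA discovery, co-expression networks, and survival stratification"
author: "lncnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reversal-based lncRNA discovery, co-expression networks, and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

# Overview

`lncnet` implements a four-stage analysis for identifying long non-coding
RNAs (lncRNAs) whose expression responds to estrogen-receptor (ER)
agitation, predicting their functions, and assessing their prognostic
value. The intended substrate is a log2-scale expression matrix covering
both protein-coding and lncRNA genes (e.g. a re-annotated microarray),
a three-condition cell-line design — vehicle (ethanol), the ER agonist
17β-estradiol (E2), and E2 plus the full antagonist ICI-182,780 — and a
patient cohort with survival follow-up.

The stages are:

1. **Reversal-based differential expression.** A gene is called
   estrogen-receptor agitation-related (ERAR) when it changes
   significantly under E2 relative to vehicle *and* changes
   significantly in the opposite direction when the antagonist is added.
   Because ICI fully blocks the receptor, a genuine ER-driven response
   must reverse; requiring both contrasts suppresses genes that drift
   for unrelated reasons.
2. **Coding–non-coding (CNC) co-expression network.** Pearson
   correlation across samples links genes with shared regulation;
   lncRNAs inherit functional context from correlated coding genes.
3. **Hub-based function assignment.** Each lncRNA with enough coding
   neighbours is treated as the hub of a sub-network; gene-set terms
   over-represented among its neighbours are assigned to the hub
   (guilt by association).
4. **Prognostic stratification.** Random-forest recursive feature
   elimination (RF-RFE) picks a small panel of candidate lncRNAs;
   k-means on the panel splits patients into two groups whose survival
   is compared by Kaplan–Meier curves and the log-rank test.

A synthetic-data module generates inputs with planted ground truth for
every stage, which is how the package's statistical behaviour is
verified.

# Stage 1: differential expression with reversal

For each contrast (E2 vs ethanol; E2+ICI vs E2) the per-gene effect is
the difference of group means on the log2 scale, i.e. a log2 fold
change. Two statistics are available:

* `moderated_t` (default): the pooled two-sample t statistic with the
  gene-wise variance shrunk toward the mean variance across genes,
  $s^2_{post} = (d_0 s^2_0 + d\,s^2_g)/(d_0 + d)$ with a fixed prior
  weight $d_0 = 4$ and $s^2_0$ the average pooled variance. This is a
  deliberately light-weight version of the moderated statistics that
  are standard for microarray designs: with 4 replicates per condition
  a per-gene variance estimate has 6 degrees of freedom, and without
  shrinkage the test is so underpowered that even 8-fold planted
  effects are missed after multiple-testing correction. We verified
  this directly on the synthetic design (3 log2-unit shifts, n = 4 per
  group): the per-gene Welch test recovers only about three quarters of
  planted reversal genes, the moderated test essentially all of them.
  Full empirical-Bayes estimation of $d_0$ is intentionally out of
  scope; a fixed prior keeps the statistic transparent and the default
  conservative.
* `welch_t`: the ordinary Welch two-sample t-test with
  Satterthwaite degrees of freedom, for designs with enough replicates.

P-values are two-sided and adjusted by Benjamini–Hochberg within each
contrast separately. The ERAR filter then requires, in **both**
contrasts, `|log2FC| > log2(fc_threshold)` (default fold change 2) and
adjusted p below `alpha_de` (default 0.01), plus strict sign reversal
between the contrasts. The symmetric rule is applied: genes repressed
by E2 and de-repressed by ICI qualify as `down` ERAR genes. Direction
labels follow the E2-vs-ethanol contrast.

Degenerate genes (zero within-group variance) get p = 1 when the group
means agree and p = 0 otherwise, so constant genes can never be called.

# Stage 2: the CNC network

Genes are first ranked by unbiased sample variance (divisor $n-1$)
across all samples, coding and non-coding jointly, and the top
`keep_fraction` (default 75%) are retained; ties are broken by input
order and the retained count is `ceiling(fraction × n_genes)`. A
per-biotype variant is available for sensitivity analysis.

An edge between genes $g,h$ requires all enabled criteria:

* $|r_{gh}| \ge$ `pcc_cutoff` (default 0.93), the hard correlation
  cutoff;
* Fisher's asymptotic test of the correlation,
  $z = \operatorname{atanh}(r)\sqrt{n-3}$ against the standard normal,
  Bonferroni-corrected over all $\binom{n_{genes}}{2}$ tested pairs,
  below `alpha_corr` (default 0.01). The multiplier is the full pair
  count because every pair is tested after variance filtering. An
  exact-t alternative ($t = r\sqrt{(n-2)/(1-r^2)}$, $n-2$ df) can be
  selected;
* the per-gene percentile rule: $r_{gh}$ lies in the top or bottom
  `percentile_q` fraction (default 0.05) of each endpoint's
  off-diagonal correlations (`endpoint_rule = "both"`, the stricter
  symmetric reading) or of at least one endpoint (`"either"`).
  Quantiles use linear interpolation. We read "0.05 percentile" as the
  fraction 0.05 (5%); the alternative reading (0.05% = 5e-4) is
  available by setting `percentile_q` accordingly.

Each criterion can be disabled (`NULL`) to reproduce variants of the
procedure. Edges are classified CC, CN or NN from the endpoint
biotypes, and the node set is the genes with at least one edge.
Correlations of ±1 get p = 0 by convention. Zero-variance genes are
rejected by name rather than silently dropped.

One consequence of the percentile rule worth knowing: with $G$ genes
after filtering, a gene can have at most about $2qG$ flagged partners,
so on small matrices the rule — not the correlation cutoff — caps node
degree. The hub threshold of ten coding neighbours therefore needs
$G \gtrsim 10/q$ genes to be attainable at all.

# Stage 3: hub annotation

lncRNA nodes adjacent to at least `min_neighbours` (default 10)
protein-coding genes are hubs; lncRNA–lncRNA edges never count toward
the threshold because only coding genes carry functional annotation.
For each hub, every gene-set term is tested by the upper-tail
cumulative hypergeometric probability
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, where $N$ is the
universe size, $K$ the within-universe term size, $n$ the hub's
within-universe neighbour count and $k$ the overlap. Terms with
p below `alpha_enrich` (default 0.01, uncorrected — a BH option exists
but is off by default, matching the procedure's raw threshold) are
assigned to the hub as predicted functions; hubs with no enriched term
are dropped from the report.

The default universe is the set of coding genes in the study that
belong to at least one gene set — the natural background when
annotation covers only part of the array — and can be overridden.
Terms whose within-universe size falls outside [5, 2000] are skipped
(standard enrichment hygiene). Neighbours outside the universe are a
contract violation for `annotate_hub()`; the `hub_report()` driver
restricts neighbour sets to the universe before testing.

# Stage 4: prognostic stratification

**RF-RFE.** The classification label defaults to the binary event
indicator of the chosen endpoint (event occurrence is the natural
binarisation when no landmark time is given). Resampling is placed
*outside* the elimination, avoiding selection bias: within each of
`n_folds × n_repeats` stratified train/test splits (defaults 5 × 10), a
random forest (`ranger`, `num_trees = 200`) is fitted on the training
part, features are ranked by out-of-bag permutation importance, the
least important feature is dropped, and the loop repeats down to one
feature, recording held-out accuracy at every subset size. The
selected size maximises mean held-out accuracy with ties going to the
smaller size; the selected features are those most frequently surviving
at that size across resamples (ties by candidate order). One feature is
dropped per iteration, which is exact at the intended scale (~33
candidates).

**Stratification.** Selected features are z-scored per gene and
patients are split by k-means with k-means++-style farthest-point
seeding, `n_restarts = 50` restarts, best within-cluster sum of squares
wins, `k = 2`. Group labels are semantic: the group with the higher
event rate is labelled "poor" prognosis post hoc, since k-means labels
are arbitrary.

**Survival comparison.** Kaplan–Meier curves come from the
product-limit estimator (via the `survival` package) and the two-group
comparison from the standard log-rank test: observed-minus-expected
events accumulated over distinct event times with the hypergeometric
variance and simultaneous handling of ties, $\chi^2$ with 1 df. Tests
against hand-worked accumulations on small fixtures pin these down to
1e-10.

The whole stage is deterministic given `(data, seed, config)`: every
stochastic step runs under a seed set through an RNG-state-preserving
wrapper, so repeated calls are bit-identical and do not perturb the
caller's RNG.

# The synthetic-data generator

`generator_config()` fixes the study conditions; its defaults are the
conditions under which the package's statistical guarantees are
verified, and mirror the intended application scale while staying
desk-sized (about a minute for the full pipeline):

* **Three-condition study**: 1,000 coding + 100 lncRNA genes, 4
  replicates per condition; gene baselines uniform on 5–10 log2 units
  with residual SD 0.3 (typical post-normalisation microarray noise);
  30 planted ERAR genes shifted ±3 log2 units under E2 and returned to
  baseline under E2+ICI, half up, half down.
* **Module study**: 30 samples; each of 3 modules has a latent factor
  $f \sim N(0,1)$ per sample and members
  $\mu_g + \lambda f + \sigma_m \varepsilon$. With the default
  $\sigma_m = \sqrt{1-\lambda^2}$ the expected within-module pairwise
  correlation is exactly $\lambda^2 \approx 0.94$ at $\lambda = 0.97$ —
  deliberately *marginal* against the 0.93 edge cutoff, to exercise the
  threshold. For recovery benchmarks we instead set
  `module_noise_sd = 0.15` (within-module correlation ≈ 0.977), a
  tight-module regime in which planted hubs should be found
  essentially always; both regimes are part of the test suite, the
  marginal one checking the correlation calibration itself and the
  tight one checking end-to-end hub and term recovery. Each module's
  15 coding members fill 75% of one planted 20-gene term; 200 total
  terms.
* **Cohort**: 164 patients (discovery) with a balanced latent risk
  group; survival exponential with baseline hazard 0.01/month and
  hazard ratio 3 between groups; independent uniform censoring with the
  horizon solved in closed form so the expected censoring fraction hits
  the requested 0.3; 5 informative of 33 candidate features separated
  by 1.5 SD between risk groups; validation cohorts (140 patients) can
  reuse the discovery cohort's informative set, as a shared biology
  requires.

What the generator does **not** emulate: probe-level effects, batch
structure, correlated noise between non-module genes, non-exponential
hazards (a Weibull shape is not currently exposed), imbalanced risk
groups, or biotype-specific intensity distributions. Passing tests
therefore demonstrate the correctness and calibration of the
*procedure*, not performance guarantees on any particular real
dataset.

# Numerical and design choices

* Variances use divisor $n-1$ everywhere; the variance filter ranks
  coding and non-coding genes in one pool.
* BH adjustment is `stats::p.adjust`; the hypergeometric tail is
  `stats::phyper` (log-space internals); both are cross-checked in the
  tests against naive-sort and exact binomial-summation references.
* The Bonferroni multiplier for correlation p-values is the number of
  tested pairs after variance filtering.
* "Two-fold change" is interpreted on the linear scale
  (`|log2FC| > 1`), the standard convention.
* The correlation cutoff 0.93 is treated as a correlation (not a
  p-value) threshold.
* Quantiles are type-7 (linear interpolation), R's default, and the
  degenerate all-equal case flags every partner.
* Missing values are rejected, not imputed: the intended input is
  complete post-RMA expression.
* File round-trips write 15 significant digits, reproducing doubles to
  better than 1e-12.
* Test-suite problem sizes are scaled-down versions of the defaults
  (e.g. RF-RFE checks run 2 repeats of 5-fold resampling with 150
  trees); the selection rule and accuracy bookkeeping are identical at
  every scale.

# Known limitations

* The moderated statistic uses a fixed prior weight rather than
  estimating it from the data; with many replicates per condition
  `welch_t` may be preferable.
* Enrichment treats gene sets as flat; no ontology-graph propagation.
* The network stage stores the full correlation matrix (dense); it is
  comfortable to ~20k genes but not beyond.
* RF-RFE reports resampled accuracy for the event-indicator label; it
  is not a time-to-event model, and no individual-gene predictive-power
  summary is produced.
* The log-rank test is the unweighted two-group form; no trend or
  stratified variants.
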