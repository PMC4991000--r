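# lncnet

Discovery and characterisation of long non-coding RNAs (lncRNAs) driven
by estrogen-receptor (ER) signalling, for transcriptomics and systems
biology researchers working with coding+non-coding expression profiles
and survival cohorts.

The package implements a four-stage pipeline:

1. **Reversal-based differential expression.** In a three-condition
   design — vehicle (ethanol), the ER agonist E2 (17β-estradiol), and
   E2 plus the full antagonist ICI-182,780 — a gene is
   estrogen-receptor agitation-related (**ERAR**) when it satisfies, in
   *both* the E2-vs-ethanol and E2+ICI-vs-E2 contrasts,
   `|log2FC| > 1` and BH-adjusted `p < 0.01`, with opposite fold-change
   signs (the antagonist reverses the agonist response).
2. **Coding–non-coding (CNC) co-expression network.** After a top-75%
   variance filter, gene pairs are linked when `|r| ≥ 0.93` (Pearson),
   Fisher's asymptotic test `z = atanh(r)·√(n−3)` is significant at
   Bonferroni-corrected `p ≤ 0.01`, and the correlation lies in the top
   or bottom 5% of each endpoint's correlation profile. Edges are
   classified coding–coding (CC), coding–noncoding (CN),
   noncoding–noncoding (NN).
3. **Hub-based function prediction.** Each lncRNA with ≥ 10 coding
   neighbours is a hub; gene-set terms enriched in its neighbours by
   the upper-tail cumulative hypergeometric test
   (`P(X ≥ k)`, `X ~ Hypergeom(N, K, n)`, `p < 0.01`) become the hub's
   predicted functions (guilt by association).
4. **Prognostic stratification.** Random-forest recursive feature
   elimination (held-out accuracy over repeated stratified CV) selects
   a panel of candidate lncRNAs; k-means (`k = 2`) on the z-scored
   panel splits patients into groups compared by Kaplan–Meier curves
   and the log-rank test; the higher-event-rate group is labelled
   "poor" prognosis.

A synthetic-data module (`generator_config()`,
`generate_three_condition_study()`, `generate_module_study()`,
`generate_cohort()`) produces all inputs with planted ground truth, so
the whole pipeline is testable without any external downloads. See the
methods vignette (`vignettes/lncnet-methods.Rmd`) for the models,
assumptions, and design decisions.

## Worked example

```r
library(lncnet)

cfg <- generator_config(seed = 7, module_noise_sd = 0.15)

## Stage 1: ERAR genes from a synthetic three-condition study
sim <- generate_three_condition_study(cfg)
c1 <- contrast(sim$study, "E2", "ethanol")
c2 <- contrast(sim$study, "E2_ICI", "E2")
erar <- erar_filter(c1, c2, fc_threshold = 2, alpha = 0.01)
nrow(erar)
#> [1] 30          # all 30 planted reversal genes, no false calls
head(erar, 3)
#>   gene_id biotype direction log2fc_c1     p_adj_c1 log2fc_c2     p_adj_c2
#> 1  PC0032  coding        up  3.025681 1.918348e-06 -2.938125 2.564138e-06
#> 2  PC0086  coding        up  2.917409 2.060609e-06 -2.913506 2.187245e-06
#> 3  PC0125  coding        up  3.142549 9.889204e-07 -3.108015 2.128727e-06

## Stages 2-3: network and hub annotation
mod <- generate_module_study(cfg)
net <- build_network(variance_filter(mod$study, 0.75))
net
#> CNCNetwork: 45 coding + 3 lncRNA nodes; 360 edges (CC 315 / CN 45 / NN 0 )
hubs <- hub_report(net, mod$sets, study = mod$study)
names(hubs)
#> [1] "LNC019" "LNC049" "LNC080"   # the three planted hub lncRNAs
hubs[[1]]$enrichment[1, c("term_id", "overlap", "term_size", "p")]
#>   term_id overlap term_size            p
#> 1   T0001      15        20 2.964409e-29

## Stage 4: prognosis on a synthetic 164-patient cohort
coh <- generate_cohort(cfg)
prog <- prognostic_pipeline(coh$cohort, seed = 7, n_repeats = 2,
                            num_trees = 150)
sum(coh$truth$informative %in% prog$rfe$selected)
#> [1] 5           # all 5 planted prognostic lncRNAs in the panel
max(prog$rfe$accuracy_by_size)
#> [1] 0.717       # best mean held-out accuracy
prog$stratification$logrank_chi2; prog$stratification$logrank_p
#> [1] 22.09
#> [1] 2.61e-06    # the two k-means groups differ strongly in survival
prog$stratification$prognosis_of
#>      1      2
#> "good" "poor"
```

The ERAR table lists each called gene with its direction under E2 and
the fold changes / adjusted p-values of both contrasts. The hub report
shows that each planted hub recovered its planted 20-gene term with 15
of its neighbours overlapping it. In the prognosis stage the accuracy
curve is flat once the informative features are included — the selected
panel is therefore larger than 5, but contains all planted prognostic
genes, and stratification cleanly separates survival.

With real data, replace the generators with
`read_expression_study()`, `read_gmt()` and `read_cohort()`, or run
everything at once with `run_pipeline()` (see `?run_pipeline`), or from
a shell via `inst/scripts/lncnet.R`.

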