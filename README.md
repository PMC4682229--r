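# astronet

Grade-wise differential expression, molecular subtype classification
and signature-specific regulatory network inference for astrocytoma
transcriptomics.

## The problem

Astrocytic brain tumors span WHO grades from the mostly benign
pilocytic astrocytoma (PA I) through diffuse and anaplastic
astrocytoma (AS II, AS III) to glioblastoma (GBM IV). Comparative
expression analysis of these grades against normal-brain references
asks: which genes change in which grades and directions, how do
individual tumors relate to the known expression subtypes (neural,
proneural, classical, mesenchymal), which gene signature separates
PA I from the adult grades, and which transcription factors (TFs) in
that signature can explain the expression of the other signature
genes?

astronet is a tidyverse-native R package for this workflow. It is
aimed at computational biologists who want each stage — state calling,
subset partitioning, enrichment, centroid classification, signature
derivation, sparse network inference, hub/validation analysis — as a
tested, pipeable function over plain tibbles, together with a
synthetic-cohort generator with planted ground truth so every stage
can be validated end to end.

## The model at the core

* **Expression states.** Per grade, each gene is tested tumor-versus-
  reference with Welch's t-test on log2 values; Benjamini–Hochberg
  q-values over the grade's gene list; state OVER/UNDER when
  `q < 1e-4` with positive/negative mean log-ratio, else UNCHANGED.
* **Subtype calls.** Pearson correlation of a tumor's per-gene
  log-ratios with each subtype centroid over their common genes;
  assignment to the subtype with the greatest significant positive
  correlation (one-sided `p < 0.05`), else UNCLASSIFIED.
* **Signature.** Genes whose PA I state is not shared by the higher
  grades and whose class-mean log-ratio difference
  |mean(PA I) − mean(AS II + AS III + GBM IV)| is at least 2 log2
  units.
* **Regulatory network.** For each signature gene *i* over tumors *d*,

  ```
  e_id = Σ_{j ∈ TF \ {i}}  a_ji · e_jd
  ```

  with `e` the tumor-versus-reference log2-ratio. Candidate TFs enter
  along the lasso path; each entry is scored with the covariance test
  (statistic asymptotically Exp(1) under the null, `p = exp(-T)`), and
  links with `p < 5e-5` are kept. `a_ji > 0` labels TF *j* an
  activator of gene *i*, `a_ji < 0` a repressor.

## Worked example

Simulate a cohort with planted ground truth, call states, derive the
signature, and infer the regulatory network:

```r
library(astronet)

cfg <- sim_config(n_genes = 500, n_tfs = 10, n_targets = 60,
                  n_per_grade = 20, n_ref = 15,
                  de_counts = c(15, 30, 45, 90), seed = 11)
sim    <- simulate_cohort(cfg)
states <- call_states_all(sim$expr, sim$metadata)

sapply(tumor_grades(), function(g)
  sum(states$grade == g & states$state != "UNCHANGED"))
#>  PA1  AS2  AS3 GBM4
#>   34   46   62  109
grade_trend(c(34, 46, 62, 109))
#> # A tibble: 1 × 2
#>       r      p
#>   <dbl>  <dbl>
#> 1 0.946 0.0542
```

The number of differentially expressed genes rises with grade
(planted counts were 15/30/45/90; each grade also detects the
signature TFs and targets), and the grade trend statistic summarizes
that increase. Continuing:

```r
lr  <- to_log_ratios(sim$expr, sim$metadata)
sig <- derive_signature(states, lr, sim$metadata)
nrow(sig)
#> [1] 24

tfs <- rownames(sim$truth$coeff_matrix)
net <- infer_network(colnames(sim$truth$coeff_matrix),
                     lr, tfs, p_threshold = 5e-5)
net
#> Signature-specific regulatory network
#>   10 TFs x 60 signature genes (600 possible links)
#>   9 selected links: 1 activator, 8 repressor
#>   51 signature genes without regulators; 4 TFs without targets

network_recovery(net, sim$truth$coeff_matrix)
#> # A tibble: 1 × 6
#>   n_true n_selected    tp precision recall sign_agreement
#>    <int>      <int> <int>     <dbl>  <dbl>          <dbl>
#> 1      9          9     9         1      1              1
```

All nine planted regulatory links are recovered, none are spurious,
and every recovered sign matches the planted coefficient's sign.
`tidy(net)` returns the edge table, `glance(net)` the one-row summary,
`autoplot(net)` the out-degree chart, and `hub_ranking(net)` the TF
hub report. `run_pipeline(pipeline_config(...))` chains every stage
and writes TSV outputs plus a digest manifest;
`inst/cli/astronet.R` exposes the same stages as shell subcommands.

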