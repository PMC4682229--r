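---
title: "Methods: grade-wise expression states, subtype calls and signature-specific regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grade-wise expression states, subtype calls and signature-specific regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astronet)
```

## Scope and model overview

astronet implements a comparative transcriptomics workflow for
astrocytic brain tumors across WHO grades — pilocytic astrocytoma
(PA I), diffuse and anaplastic astrocytoma (AS II, AS III) and
glioblastoma (GBM IV) — analyzed against normal-brain references on the
log2 expression scale. The pipeline has five analytic layers:

1. **Expression states per grade.** For each grade, every gene is
   tested against the reference samples with Welch's unequal-variance
   t-test on the raw log2 values; p-values are adjusted to q-values by
   Benjamini–Hochberg step-up over the grade's full gene list, and each
   gene receives a discrete state: OVER if `q < 1e-4` with positive
   mean log-ratio, UNDER if negative, UNCHANGED otherwise. The grade
   trend (DE count versus numeric grade 1–4) is summarized by Pearson
   correlation, and exclusive Venn-style subsets quantify which genes
   change in exactly which grade combinations. Category enrichment
   uses the one-sided hypergeometric tail (Fisher) against the full
   measured universe.
2. **Subtype classification.** Each tumor's per-gene log-ratios are
   correlated with subtype centroid vectors over their common genes
   (centroid order, reported with coverage); the sample is assigned to
   the subtype with the greatest *significant positive* correlation
   (one-sided `p < 0.05` from the exact t transform of Pearson's r),
   otherwise it stays UNCLASSIFIED.
3. **Signature derivation.** A gene joins the PA I-versus-higher-grades
   signature when its PA I state is not shared by the higher grades
   (six criteria, recorded per gene) *and* the absolute difference
   between its mean log-ratio in PA I and in the pooled AS II + AS III
   + GBM IV class is at least 2 log2 units (four-fold, inclusive).
4. **Regulatory network inference.** Each signature gene's log-ratio
   profile across tumors is modeled as a linear combination of the
   signature's TF log-ratios, `e_i = sum_j a_ji e_j` with no intercept
   and self-regulation excluded. The lasso path provides the candidate
   order; the covariance significance test scores each entering TF and
   links with `p < 5e-5` are kept, with signed coefficients from an
   unpenalized refit on the selected set (activator if positive,
   repressor if negative).
5. **Network analysis.** Hub ranking by outgoing links, the TF-to-TF
   hierarchy (strictly more than 5 TF targets), cross-cohort
   predictive validation (predicted versus observed log-ratios,
   per-gene Pearson r), and the expression-versus-mutation deviation
   map.

## The lasso path and the covariance test

The path is computed by the least-angle algorithm with the lasso
modification: coefficients are piecewise linear in the penalty
$\lambda$, predictors enter when their absolute correlation with the
residual reaches the active level and are dropped when a coefficient
crosses zero. At every knot the KKT conditions hold —
$|x_j^\top r| \le \lambda$ for inactive and
$x_j^\top r = \lambda\,\mathrm{sign}(\beta_j)$ for active predictors —
and the tests assert this at tolerance 1e-8, alongside exact
equivalence with coordinate-wise soft-thresholding on orthonormal
designs and agreement with glmnet at matched penalties.

For the $k$-th entry at knot $\lambda_k$ the covariance statistic is

$$T_k = \frac{\langle y, X\hat\beta(\lambda_{k+1})\rangle -
        \langle y, X_A\tilde\beta_A(\lambda_{k+1})\rangle}{\sigma^2},$$

where $A$ is the active set just before the entry and $\tilde\beta_A$
the lasso solution restricted to $A$, evaluated at the next knot. Under
the null that all signal variables are already active, $T_k$ is
asymptotically standard exponential, so $p = \exp(-T_k)$. Each
predictor is scored at its first entry; drops are recorded but
re-entries are not re-scored. The noise variance $\sigma^2$ comes from
the residual variance of the full least-squares fit when $n > p + 1$
(the regime of all shipped defaults), otherwise from a df-corrected
refit on a cross-validated support; numerically exact fits are floored
at $\sigma^2 = 10^{-8}$ with a warning so noiseless toys remain
testable.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `q_threshold` | 1e-4 | probability | DE state call cutoff per grade |
| `lfc_threshold` | 2 | log2 units | class-difference filter for signature membership (inclusive) |
| `subtype_alpha` | 0.05 | probability | one-sided significance for centroid assignment |
| `network_p_threshold` | 5e-5 | probability | covariance-test cutoff for regulatory links |
| `deviation_threshold` | 1 | log2 units | "strong deviation" box of the mutation map |

The first four mirror the thresholds conventionally used in this
analysis style; the mutation-map threshold quantifies an otherwise
qualitative notion of "strongly deviating" and is explicitly
parameterized.

## Design decisions on genuinely open points

* **Test variant.** The per-gene test is Welch's unequal-variance t;
  group sizes in grade-wise designs are routinely unbalanced, making
  equal-variance pooling fragile. Benjamini–Hochberg is the q-value
  default, with a simple Storey-type option (`method = "storey"`).
* **Criteria quantifier.** "Not in AS II, AS III or GBM IV" is read
  disjunctively by default: a gene qualifies when its PA I state
  differs from at least one higher grade. A strict mode
  (`strict = TRUE`: differs from all three) is available; the
  disjunctive reading produces the broader candidate set that the
  class-difference filter then prunes.
* **Scale of the difference filter.** The "difference below two"
  filter is applied on the log2-ratio scale (|Δ of class-mean
  log-ratios| ≥ 2, i.e. four-fold), consistent with displaying and
  modeling expression as log-ratios throughout; the boundary is
  inclusive.
* **Ties in subtype assignment.** Exactly equal correlations are
  broken by centroid column order, a documented reproducibility rule;
  samples with no significant positive subtype are UNCLASSIFIED rather
  than forced to the argmax.
* **Possible-link denominator.** The conventional count multiplies
  |TF| by the signature size, counting TF self-pairs even though the
  model never fits them; the self-excluded count is reported alongside
  (`possible_links(..., exclude_self = TRUE)`).
* **Edge coefficients.** Reported `a_ji` come from an unpenalized
  least-squares refit on the selected TF set (the lasso estimate is
  shrunken); sign labels derive from the refit. The standardized path
  coefficients remain available from the path object for sensitivity
  checks.
* **No intercept.** The regulatory model carries no intercept beyond
  response centering and predictor standardization inside the path;
  log-ratios are approximately centered, and the refit is on the raw
  log-ratio scale.
* **Methylation sign convention.** In the mutation map, copy-number
  coupling is expected same-sign and methylation coupling
  opposite-sign (promoter hypermethylation accompanying
  underexpression). This is a labeling convention for the deviation
  categories, not a claim about any particular gene.

## The synthetic-cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, with full ground truth:

* baseline gene means drawn from N(7, 2²) log2 units — a typical
  microarray intensity range; the value cancels in every log-ratio
  stage;
* grade-specific planted DE effects on "free" genes, with per-grade
  counts that default to an increasing sequence (50/100/150/300 at the
  2,000-gene scale) to reproduce the monotone grade trend, and
  configurable to break monotonicity for negative controls;
* grade-specific expression shifts for every TF (drawn from the same
  effect-size range), reflecting that the signature's TFs are by
  construction differentially expressed, plus per-sample biological TF
  variability (`tf_biological_sd`, default 1 log2 unit) representing
  tumor heterogeneity. This patient-level TF variation is what
  propagates through the coefficient matrix and makes the planted
  network identifiable: with grade means alone the TF design would be
  effectively rank four and collinear;
* signature-target log-ratios equal to the transposed sparse
  coefficient matrix times the realized TF log-ratios plus noise — the
  generative analogue of the regulatory model, exact when
  `noise_sd = 0`;
* mutation layers per TF: coupled TFs get
  `sign × strength × mean TF log-ratio` plus noise (methylation
  sign −1, copy number +1), uncoupled TFs pure noise around zero.

All draws come from one seeded stream in a documented order (baseline,
TF grade shifts, DE assignments, coefficient matrix, noise matrix,
per-sample TF variability, labels and couplings), so identical configs
are bit-reproducible and a stored ground truth can be combined with a
new seed to produce an independent cohort from the same planted
network — the basis of the cross-cohort validation.

What the generator does **not** emulate: probe-level intensities and
array normalization artifacts, batch effects, correlated gene blocks
outside the planted network, copy-number segmentation structure, and
subtype-driven expression programs (subtype labels are recorded as
ground truth; classifier testing uses dedicated centroid-plus-noise
draws). Passing recovery tests therefore demonstrates correctness of
the inferential machinery under the stated generative model, not
performance on real cohorts.

## Numerical choices and degenerate inputs

* Zero-variance genes are flagged and kept UNCHANGED instead of
  failing the grade; their p/q values are NA.
* Zero variance in both groups with equal means gives p = 1; with
  unequal means p = 0, flagged.
* Constant predictors abort the path with the offending name; constant
  sample vectors abort centroid correlation.
* Path knots are computed with positivity tolerance 1e-12; the
  covariance test clamps negative statistics (numerical noise) to
  zero, i.e. p = 1.
* Truncated paths (`max_steps`) score only entries that have a
  following knot; if a path saturates (active set reaching
  min(n − 1, p)), the last coefficients are held below the final knot.
  Neither regime occurs at the shipped problem sizes.

## Problem sizes used by the tests and the acceptance script

The shipped simulations are deliberate desk-scale reductions of a
cohort-scale study (which would have on the order of 125 tumors,
17,000 genes, 1,089 signature genes, 151 TFs): 2,000 genes with 20 TFs
and 200 planted targets over 120 tumors (30 per grade) and 20
references for network recovery and validation; 1,000 genes at 10
versus 10 for the global-null FDR check; 10,000 replicates of n = 100,
p = 10 for the null calibration of the covariance test; 200-gene
centroids with 100 samples per subtype at noise 0.5 for the
classifier. These sizes keep every statistical property measurable
with tight Monte-Carlo error while remaining quick to rerun.

## Known limitations

* The covariance test's exponential null is asymptotic; at small n or
  strongly collinear designs its finite-sample calibration degrades
  (the null-calibration test quantifies this at the shipped sizes).
* The network is selected per response gene; no joint sparsity or
  stability selection across genes is attempted, and directionality
  comes entirely from the TF annotation, not causal inference.
* FDR adjustment treats genes as exchangeable within a grade;
  correlation between genes is not modeled.
* The signature criteria operate on discretized states, so genes
  hovering at the q-threshold can enter or leave the signature under
  small perturbations; the class-difference filter damps but does not
  remove this.
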