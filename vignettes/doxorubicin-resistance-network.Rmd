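---
title: "From differential expression to ceRNA networks: the lncnet pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From differential expression to ceRNA networks: the lncnet pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

## The problem

Chemoresistance screens of the doxorubicin-resistant MCF-7/ADR breast
cancer line against its sensitive MCF-7 parent typically profile a few
replicates per condition on a combined lncRNA/mRNA microarray, then ask
which long non-coding RNAs sit at the centre of the dysregulated
transcriptional programme. Because most lncRNAs carry no functional
annotation, the standard strategy is guilt by association: find the mRNAs
a lncRNA is tightly coexpressed with, and read the lncRNA's putative role
off the pathways those mRNAs belong to. `lncnet` implements that whole
chain as composable, tested R functions:

1. two-group differential expression (`call_de`),
2. hypergeometric over-representation against GO and KEGG collections and
   the dual-membership mRNA selection (`enrich`, `overlap_go_kegg`),
3. the Pearson lncRNA–mRNA coexpression network with degree-based hub
   selection (`build_coexpression_network`, `select_hubs`),
4. the tripartite lncRNA–mRNA–pathway network
   (`build_pathway_network`, `hub_pathway_significance`),
5. Kaplan–Meier survival stratification by expression
   (`analyze_survival`, `subgroup_analysis`),
6. clinicopathological association statistics (`chi_square_2x2`,
   `roc_auc`, `ddcq`, `paired_compare`), and
7. ceRNA (competing endogenous RNA) network assembly from scored
   interaction tables (`assemble_cerna`).

A seeded synthetic-data module (`simulate_*`) generates every input with
known ground truth, so each stage can be validated end to end.

## Differential expression

Intensities are kept on the log2 scale throughout; fold changes are
reported on the linear scale with the signed convention common in array
tables: `log2FC = mean(case) − mean(control)`, and the linear value is
`2^log2FC` when positive, `−2^(−log2FC)` when the case group is lower, so
down-regulated genes carry values like −281.3 and `|FC| ≥ 1` always.

The test is the equal-variance Student's t (`df = n1 + n2 − 2`), which is
what two-group array comparisons of this vintage report; Welch's form is
a flag. With n = 3 per group there is no information to stabilise
variances and no moderated statistic is attempted — that is a deliberate
non-goal, since the calling rule being mirrored is a plain
`|FC| ≥ 2 & p < 0.05` filter. The Benjamini–Hochberg FDR is computed and
reported for every gene but is not the operative filter (the screen
filtered on raw p); `use_fdr = TRUE` switches the filter if wanted.

Degenerate inputs follow a documented convention rather than erroring
mid-pipeline: when both groups are constant, equal means give
`t = 0, p = 1` and unequal means give `t = ±Inf, p = 0`.

## Enrichment and the dual GO/KEGG selection

Over-representation uses the upper-tail hypergeometric test
`P(X ≥ k)` with the universe defaulting to all genes on the annotation —
the microarray background convention, not the genome. The EASE-style
conservative variant (discounting one overlapping gene) is available via
`ease = TRUE` for users who want to mimic DAVID's statistic; the default
is the exact test.

The selection rule for the network's mRNA side is interpreted at the
*gene* level: an mRNA is kept if it belongs to at least one significant
GO term **and** at least one significant KEGG pathway. Term-level
interpretations were rejected because they do not yield a well-defined
gene list. The selection is idempotent and order-independent by
construction (sorted, duplicate-free).

## The coexpression network

Correlations are computed across **all samples of both groups pooled**
(6 in the emulated design). Whether the original screen pooled or
correlated within groups is unstated; pooling is assumed because only
group separation at n = 3 + 3 can produce the near-unity |r| values
(0.9999…) that the published candidate table contains. The consequence —
worth stating plainly — is that at these sample sizes the edge set is
driven by the group effect: any two strongly differential genes correlate
near ±1. The method is therefore a fold-change-concordance screen as much
as a coexpression screen, which is why the pipeline applies it only to
genes that already passed the DE filter.

Edges are retained at `|r| ≥ 0.99` (inclusive, matching the screen's
"equal to or greater than"; a strict flag exists because the methods text
also says "> 0.99"). The threshold is applied to the absolute value and
the sign kept as an edge attribute: the published network itself contains
negative (dotted-line) edges near −0.9999, so thresholding signed r would
discard half the network. No p-values are attached to correlations — at
n = 6 they carry no information beyond r itself, and the screen used a
pure cutoff.

Numerical choice: the correlation matrix is rounded to 12 decimals before
thresholding, so exact duplicates reach |r| = 1 exactly and boundary
comparisons are well defined; 1e−12 is far below any biologically
meaningful difference in r and far above double-precision fuzz.

Hubs are lncRNAs of degree ≥ 6, sorted by decreasing degree with a
lexicographic id tie-break for reproducibility. Degree centrality is the
plain incident-edge count — the simplest centrality, and the one the
screening strategy defines.

## Pathway network

The tripartite network links each hub's partner mRNAs to every pathway
containing them (raw membership), because how the published figure
assigned pathways is not stated; membership is the assumption-free
choice. Separately, `hub_pathway_significance` scores each pathway by the
hypergeometric enrichment of the hub's partner set, BH-adjusted, with
significance at FDR < 0.05 — mirroring the per-hub pathway bar charts
such screens report. The universe for that test is again the array-wide
annotation, since no other universe is recoverable.

## Survival stratification

The cohort-cleaning filters drop records with expression exactly 0 and
records with follow-up below 30 days, reporting counts per rule (a
record failing both is dropped once, counted twice). The high/low split
is at the median of the *cleaned* cohort, with the median record in the
low group; the original analysis tool's split rule is unpublished, and
the median is the convention that needs no tuning. Other quantiles are a
parameter.

The log-rank test is the Mantel–Haenszel form with the hypergeometric
variance (ties with d > 1 handled standardly), computed via the
`survival` package. The hazard ratio is the O/E (Pike) estimator
`(O_high/E_high)/(O_low/E_low)` — chosen over Cox regression because the
pipeline mirrors an analysis in which no partial-likelihood machinery
appears, and Cox modelling is a non-goal. Users should know the Pike
estimator's known behaviour: it is accurate near HR = 1 and attenuates
toward the null for large effects under complete follow-up (at a true
HR of 3 with no censoring it recovers ≈ 2.5); with realistic censoring
the attenuation shrinks. The package's validation asserts recovery
within 15% at HR = 2 and within 20% at HR = 3, which the estimator
meets.

Subgroup analyses (`ER = 1`, `HER2 = 1`, chemoresistant, …) re-run the
full chain on the restricted cohort and refuse subgroups below 10
records rather than returning unstable estimates.

## Clinical statistics

The 2×2 association test is Pearson's chi-square **without** continuity
correction — verified to reproduce the published association statistics
for age (0.606), ER (4.848), PR (1.818), HER2 (5.488), TNM stage (3.810)
and Ki-67 (3.778) from their printed counts; Yates correction is a flag.
One published row (lymph-node metastasis, printed 3.333) is not
reproduced by either form from its printed counts (Pearson gives 4.848,
Yates 3.039); a typo in the source counts or statistic is likely, and
the package makes no attempt to match it. Expected counts in a 20-patient
series are necessarily small; the implementation suppresses the
small-count warning because reproducing the printed statistic, not
approximation quality, is the point of this operation.

AUC is the Mann–Whitney probability with half-weight ties. 2^−ΔΔCq
follows the standard two-condition, housekeeping-referenced form.

## ceRNA assembly

The external database queries behind lncRNA→miRNA and miRNA→mRNA
predictions are out of scope; the module consumes user-supplied (or
simulated) score tables and applies exactly the printed thresholds:
correlation > 0.9 and binding > 0.04 (both strict), context++ ≤ −0.2
(inclusive) — boundary semantics follow the inequality signs as printed.
Triplets are additionally restricted to mRNAs among the hub's
coexpression partners (a flag), since a sponge model is only meaningful
for targets the hub is coexpressed with, and every published target in
the worked example lies in the hub's partner list. Output is sorted by
(miRNA, mRNA), making assembly invariant to input row order.

## What the synthetic data emulates — and what it does not

`simulate_expression` draws per-gene Gaussian baselines
(`baseline_mean = 8`, `baseline_sd = 1.5` on log2 scale, typical of
normalized array intensities), adds `log2|FC|` group effects for planted
genes, and residual noise (`noise_sd = 0.25` by default, a mid-range
array replicate noise). Hub modules are affine copies of the realized
hub profile plus Gaussian noise calibrated from the realized hub SD so
the expected hub–partner correlation equals the target `rho` exactly in
the noiseless limit; the module's fold change applies to hub and
partners alike, which is what makes pooled correlations near unity, just
as in the real design. The generator does **not** model probe-level
physics (background, saturation), batch effects, or heavy-tailed noise;
passing tests therefore demonstrate algorithmic correctness and
statistical calibration, not robustness to array artefacts.

`simulate_survival` uses exponential event times with the hazard
multiplied by `true_hr` in the high-expression half (optionally only in
a covariate-positive stratum), and independent exponential censoring
whose rate is set so the expected censored fraction equals
`censor_rate` at the baseline hazard — the standard independent
censoring model. Zero-expression and short-follow-up records are
injected afterwards by overwriting sampled records, so their counts are
exact for filter tests. Real cohorts differ: censoring is largely
administrative, hazards are not exponential, and expression-outcome
dependence is not a clean two-group effect.

## Validation problem sizes

The shipped test-suite and acceptance script use: exhaustive
hypergeometric enumeration for all consistent (k, K, n, N) with N ≤ 20;
1,000 random p-vectors against an independent BH step-up oracle; 2,000
null log-rank cohorts (100 per group) for the 0.05 ± 0.015 type-I band;
20 cohorts of 500 per group for HR = 2 recovery within 15%; 100 seeded
expression simulations (60 genes, target r 0.999) for ≥ 95% exact hub
recall; and 20 simulations of 500 genes with planted |FC| = 4 for exact
DE recovery. These sizes give Monte-Carlo error comfortably inside each
asserted band while keeping the default run fast on a single CPU.

## Known limitations

- Dataset-level counts from the original screen (numbers of DE genes,
  the 495 selected mRNAs, the 855-edge network, specific pathway
  p-values, TCGA cohort sizes and p-values) depend on the original data
  and database snapshots and are not reproduction targets.
- n = 3 per group makes every per-gene statistic fragile; the pipeline
  reproduces the screen's rules faithfully rather than improving on
  them (no moderated variance, no correlation p-values, no Cox model).
- The GO DAG is treated as flat sets: no parent propagation or
  elim-style decorrelation.
- The ceRNA stage is purely score-filtering plus assembly; it performs
  no expression-based mediation statistics.
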