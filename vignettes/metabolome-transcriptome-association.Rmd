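---
title: "Methods: differential metabolites, pathway enrichment and gene-metabolite networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential metabolites, pathway enrichment and gene-metabolite networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metranet)
```

# The analysis problem

Widely targeted metabolomics quantifies hundreds of known metabolites as MRM
peak areas across a small, replicated, staged design — here the three culture
stages of cotton somatic embryogenesis (nonembryogenic calli NEC, primary
embryogenic calli PEC, globular-stage embryos GE; three biological replicates
each). The question is which metabolites change between stages, which
pathways those changes concentrate in, and how the changes relate to the
companion transcriptome. `metranet` implements that chain as a reusable,
tested pipeline:

1. **QC** — replicate-level Pearson correlation between samples and a PCA
   variance decomposition of the sample cloud.
2. **Differential accumulation** — per-comparison fold change plus a
   two-class PLS-DA VIP score; a metabolite is *differentially accumulated*
   (a DAM) when its fold change is $\ge 2$ (up) or $\le 0.5$ (down) and its
   VIP is $\ge 1$, optionally also requiring $p < 0.05$ from a per-feature
   location test.
3. **Pathway enrichment** — one-sided hypergeometric (Fisher's exact)
   over-representation of the DAM set within each annotated pathway,
   Benjamini–Hochberg corrected.
4. **Association** — replicate-level Pearson correlation of gene–metabolite
   pairs, nine-quadrant classification of (metabolite status, gene status),
   and a signed bipartite network over pairs with $|r| > 0.8$.

# Differential calling

## Scales

Fold change is computed on the raw peak-area scale as the ratio of replicate
means, because published worked examples report raw-scale ratios spanning
$10^{-6}$ to $10^{4}$. Everything inferential — PLS-DA, the location test,
sample correlation, PCA — runs on $\log_2(x+1)$ values, mean-centered and
(for PLS-DA) unit-variance scaled, since peak areas are approximately
log-normal and span orders of magnitude.

## Zero handling

Undetected metabolites carry peak area 0, which makes ratios infinite. The
default imputation replaces every zero with half the smallest positive value
in the matrix before any ratio is formed (`impute_zeros()`); a constant
pseudocount is available as an alternative. On/off metabolites — absent in
one stage, abundant in another — therefore produce very large but finite
fold changes, which is exactly the regime in which the published tables show
values like $3.92\times 10^4$. Imputation is deliberately separate from
I/O: the stored matrix keeps the true zeros.

## PLS-DA and VIP

The two-class PLS-DA is fitted by sequential NIPALS extraction. For a single
centered response the weight of each component is the exact
$w \propto X^\top y$ direction; the score $t = Xw$ deflates both blocks.
Determinism is guaranteed by a fixed sign convention (first non-zero weight
entry positive) and input-order tie-breaking. VIP uses the standard Wold
formulation over all extracted components,

$$\mathrm{VIP}_j = \sqrt{p\,\frac{\sum_a SSY_a (w_{ja}/\lVert w_a\rVert)^2}
{\sum_a SSY_a}},$$

with $p$ the number of features and $SSY_a$ the response sum of squares
explained by component $a$. Because weight vectors are unit norm,
$\sum_j \mathrm{VIP}_j^2 = p$ holds exactly on every fit, which the test
suite asserts to $10^{-6}$. Two components are extracted by default — with
two classes and three replicates per group the useful rank is small, and
VIP is dominated by the first component in practice. VIP is computed
per-comparison (two classes at a time), not across all three stages at
once; a three-stage discriminant analysis would answer a different question
than the pairwise DAM definitions used downstream.

## The p-value filter

The DAM rule is stated in two forms in the field: fold change + VIP alone,
and the same with an added $p < 0.05$. Both are reachable here: the filter
is ON by default (`use_p = TRUE` in `differential_analysis()`), using a
Welch test on $\log_2$ values, and can be disabled to recover the pure
FC+VIP rule. Degenerate inputs use deterministic conventions: if both groups
have zero variance the p-value is 1 for equal means and 0 otherwise (the
test statistic diverges in that limit, and an error would make noiseless
synthetic data untestable).

## Thresholds

All boundaries are inclusive exactly as conventionally stated: up requires
$\mathrm{FC} \ge 2$, down $\mathrm{FC} \le 0.5$, and $\mathrm{VIP} \ge 1$;
the p cut is strict ($p < 0.05$). Gene-side calls use $|\log_2\mathrm{FC}|
\ge 1$ with BH-adjusted $p < 0.05$ and no VIP, or accept a precomputed
status table from an external DEG workflow.

# Pathway enrichment

The over-representation p-value is the hypergeometric upper tail
$P(X \ge k)$ for $k$ DAMs among the $K$ pathway members, drawing $n$
annotated DAMs from $N$ annotated background features — equivalent to the
one-sided Fisher's exact test on the 2×2 table. The background is the set of
*detected* features with at least one pathway annotation, not a whole
pathway-database universe: this keeps runs self-contained and avoids
dependence on external database versions. "FDR" means Benjamini–Hochberg
throughout. The enrichment factor defaults to the relative form
$(k/n)/(K/N)$; a coverage form $k/K$ is available since plots in the
literature are ambiguous about which is used. Pathways with no differential
member are omitted from reports, and only reported pathways enter the BH
correction.

# Association layer

## Correlation mode

Which samples the published networks correlated over is not recoverable:
their pair tables report PCC values of exactly $\pm 1$, which is the
automatic outcome of correlating two *stage means* (two points). The
package therefore exposes both modes. `replicates` (default) correlates the
6 replicate-level $\log_2$ values of the two compared stages and is the
statistically meaningful choice; `stage_means` reproduces the published
$\pm 1$ convention. Pairs with a constant profile have undefined
correlation and are excluded with a logged count, never imputed.

## Nine quadrants and networks

The quadrant index is a pure function of the status pair: metabolite status
selects the row (up / unchanged / down, top to bottom) and gene status the
column (down / unchanged / up, left to right), giving quadrant 1 =
(metabolite up, gene down) through quadrant 9 = (metabolite down, gene up);
3 and 7 are the concordant cells, 1 and 9 the discordant ones. Networks
keep pairs with $|r|$ strictly above 0.8 (matching the "> 0.8" convention),
sign edges by the sign of $r$, and take nodes only from edge endpoints.
Construction is a set operation — idempotent and order-independent.

The curated pair tables shipped under `inst/extdata` are verbatim
transcriptions of published worked examples (classic somatic-embryogenesis
genes against purine-metabolism and flavonoid-biosynthesis metabolites).
One published row is internally inconsistent — the *BBM* gene carries a
positive log2 fold change yet PCC $=-1$ against upregulated metabolites,
which no two-point mean correlation can produce — and is transcribed
uncorrected; the package reproduces the published network counts either
way.

# The synthetic-data generator

`generate_metabolome()` / `generate_transcriptome()` emulate the structure
the analysis assumes, with known ground truth:

- **Baselines** are log-normal (`baseline_log_mean = log(1e6)`,
  `baseline_log_sd = 1.5`), spanning the orders of magnitude of MRM peak
  areas.
- **Stage effects** are multiplicative, $2^{\delta}$ at the test stage of
  each planted comparison; default planting is 20 up + 10 down features at
  $|\delta| = 3$ per comparison, comfortably above the FC threshold of 2 so
  that recovery measures the pipeline rather than boundary luck.
- **Replicate noise** is multiplicative log-normal with
  $\sigma = \ln(1 + \mathrm{CV})$; the default CV of 0.1 is a free choice
  (replicate variability is not recoverable from published summaries) at
  the low end of what targeted MS typically shows.
- **True zeros**: 5% of non-planted features have their reference-stage
  values set to 0, exercising imputation and generating the on/off extreme
  fold changes. Ground truth is derived from the noiseless post-imputation
  stage means, so zero-driven fold changes count as true positives — truth
  and matrix are consistent by construction.
- **Classes** follow the published census composition (amino acids 15%,
  flavones 15%, organic acids 12%, lipids 11%, nucleotides 10%, remainder
  "other"), apportioned by the deterministic largest-remainder method.
- **Pairs**: each planted gene's log-scale stage profile is a signed linear
  transform of its metabolite's, so the replicate-level PCC approaches the
  planted sign exactly as noise vanishes.

What the generator does **not** emulate: correlated noise between
metabolites, class-dependent abundance distributions, drift/batch effects,
censoring at a detection limit (zeros are all-or-nothing per stage), or any
chromatographic structure. Passing recovery tests therefore demonstrates
the statistical machinery under the stated noise model, not performance on
any particular real data set.

# Validation scale and determinism

The packaged validation runs at the study's census scale for the metabolome
(581 metabolites, 3 stages × 3 replicates) over 20 generator seeds for
recovery rates, 500 randomized instances ($N \le 60$) for the
hypergeometric-vs-enumeration sweep, and 50 null draws for the enrichment
type-I check; these sizes make the whole suite complete in well under a
minute while keeping the Monte-Carlo standard errors far from the asserted
margins. Everything is seeded: the same configuration and seed reproduce
matrices, result tables and the pipeline manifest bit for bit.

# Known limitations

- Study-scale headline numbers that depend on the unpublished raw matrices
  (global DAM counts, the census composition of real data, the leading-PCA
  contribution, co-mapped pathway totals) cannot be reproduced from the
  printed record; the package validates the *procedures* on synthetic data
  instead.
- Printed fold changes are rounded to three significant digits, so
  recomputed $\log_2$ values can differ from printed ones by up to one unit
  in the last printed decimal; the worked-example checks use exactly that
  tolerance and document it.
- The stage-means correlation mode is degenerate by construction (always
  $\pm 1$); it exists for compatibility and should not be used for
  inference.
- PLS-DA here is the two-class NIPALS special case; OPLS-DA and multi-class
  discrimination are out of scope.
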