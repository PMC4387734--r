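---
title: "Comparing p-value tables from multiple analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing p-value tables from multiple analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvcomp)
```

## The problem

Different statistical methods applied to the same omics dataset — a t-test,
a rank test and a permutation test on a microarray; several association
models on a SNP panel; edgeR-style and DESeq-style models on RNA-seq counts
— routinely disagree about which markers are significant, because each
method encodes different assumptions. A common, pragmatic response is to
compare the per-method p-value lists directly and to carry forward the
markers that every method flags: the intersection is a conservative
candidate list for downstream validation (e.g. RT-PCR). `pvcomp` implements
that comparison workflow as a library and a CLI, for any table with one row
per marker and one column per method's p-values.

Three views are provided:

1. **All-pairs view** — Pearson or Spearman correlation of every method
   pair plus a scatterplot matrix, to see at a glance which methods agree.
2. **Two-method detail view** — at thresholds $\alpha_A$, $\alpha_B$, the
   markers partition into four Venn classes (significant under both, A
   only, B only, neither); a threshold sweep recomputes the counts over a
   decreasing grid of cut-offs.
3. **Multi-method table** — for any subset of $\ge 2$ methods with
   per-method thresholds, a table sorted by average p-value whose cells are
   colored red (significant) or green (not), more intense for smaller p,
   with the commonly-significant markers extracted and, optionally, a
   Fisher combined p-value per marker.

## Input model and missing values

The single input format is a UTF-8 TSV with a header row: first column the
marker id, remaining columns one method each, cells decimal p-values
(scientific notation accepted). Tokens `NA`, the empty string and `.` are
treated as missing by default (configurable). Validation is strict:
duplicate marker ids, non-numeric cells and values outside $[0,1]$ are
errors that name the offending row and column.

Two missing-value policies exist. `drop_any_missing` removes every marker
with any missing entry up front, mirroring how published result tables are
usually cleaned; `pairwise_complete` keeps everything and lets each
pairwise operation use its own pair-complete subset (markers missing in
exactly one of two compared methods are excluded from that pair and listed
as "not comparable"). Exact zeros are accepted on input but clamped to
`1e-300` before any log transform or Fisher combination, since real tools
do emit `p = 0` and $-\log_{10} 0$ is undefined.

Row order of the input file is canonical: ranking ties break by it, and
selections preserve it.

## Ranking and selection

Markers are ranked by the arithmetic mean of their raw p-values across the
(selected) methods — raw p, not $-\log_{10} p$, so a single extremely small
p-value does not dominate the average. `select_top()` keeps the $N$
smallest-average markers (or a percentage, rounded up), ties broken by
input order; a marker whose whole row is missing sorts last. Missing
entries are excluded from the mean rather than imputed.

## Correlation scale: raw vs $-\log_{10}$

p-value scatterplots are conventionally drawn on the $-\log_{10}$ scale,
and that is the default for both plots and correlations
(`transform = "neglog10"`). Both scales are exposed because neither is
canonical, and they can genuinely disagree: resampling methods floor their
p-values at $1/(B+1)$ for $B$ permutations, so on the log scale their
values truncate (at $\approx 3$ for $B = 1000$) while an analytic test's
p-values keep shrinking. A Pearson correlation on the log scale between a
permutation test and the t-test is therefore biased downward purely by this
finite-$B$ truncation. When a resampling method is in the mix, correlate on
the raw scale or use Spearman (which is transform-invariant). The
acceptance property that the t-test tracks its own permutation version more
closely than the Wilcoxon test is checked on the raw scale for exactly this
reason.

## Significance, the Venn partition, and the sweep

Significance is inclusive, $p \le \alpha$, matching common practice. For
two methods the partition into both / A-only / B-only / neither is exact
and exhaustive over pair-complete markers — the package's property tests
verify it against an independent per-marker loop on a thousand random
matrices. The sweep applies one common threshold per grid point (default
grid `0.05, 0.01, 0.005, 0.001`, user-overridable, strictly decreasing
enforced); every significant-set count is non-increasing as the cut-off
tightens, which the tests also verify by brute-force set intersection.

## The multi-method table and its colors

Each cell of the multi-method table is red iff $p \le \alpha_{method}$,
green otherwise. Intensity encodes the degree of significance on a
logarithmic ramp, which is a documented package choice (the underlying idea
— "more significant, more intense" — does not pin down a formula):

* red cells: intensity $= \min\!\left(1,
  \log_{10}(\alpha/p) \,/\, \log_{10}(\alpha/p_{sat})\right)$, i.e. 0 at
  the threshold and saturating at $p_{sat}$ (default $10^{-10}$);
* green cells: 0 for $p \ge 0.5$, ramping up toward the threshold boundary
  on the same log scale.

Within each hue the intensity is monotone in $p$; across the hue boundary
it deliberately resets (a barely-significant cell is faint red), so hue —
not intensity — carries the significance decision.

## Fisher's combined p-value

For a marker with surviving p-values $p_1, \dots, p_k$ (missing entries
dropped, $k$ adjusted accordingly),
$X^2 = -2\sum_i \ln p_i \sim \chi^2_{2k}$ under the null when the $p_i$ are
independent, and the combined p is the upper tail. For $k = 1$ this returns
the input p-value, and combining $k$ copies of a *small* p sharpens the
evidence; note the reversal for weak evidence (three copies of $p = 0.6$
combine to $\approx 0.8$), which is the chi-square tail behaving correctly,
not a bug.

The independence assumption deserves emphasis: when one dataset is analyzed
by several methods the inputs are strongly dependent and the combined p is
only a descriptive summary. The combination is therefore opt-in
(`with_combined = TRUE`), the result objects carry the flag, and every
rendered report with a combined column prints a caution footer. For a true
meta-analysis across independent datasets the test is valid.

## Annotation links

Marker types are recognized from identifier shape: `rs` + digits
(case-insensitive) is a dbSNP rsID; `ENS...G/T/P` + digits is an Ensembl
id; other purely alphanumeric ids are treated as gene symbols — array probe
ids such as `BB471471` are indistinguishable from symbols by shape and
share that class; anything else is unknown. rsIDs link to their dbSNP
record, gene symbols to the NCBI Gene search and the DAVID lookup; Ensembl
ids get no link (web annotation expects official symbols — converting is a
deliberate non-goal). URL templates live in
`options(pvcomp.annotation_templates = ...)` so they can be updated when
the sites change. No network access happens anywhere: URLs are constructed,
never fetched.

## The synthetic-data generators

Two generators make every module testable without external data.

`simulate_pvalue_matrix()` emulates the *statistical shape* of a
multi-method result table: latent z-scores from an equicorrelated Gaussian
(one shared factor; a single $\rho$ is sufficient for every test surface
and easy to validate), a fraction $\pi_1$ of signal markers shifted by
$\mu$, one-sided upper-tail conversion to p-values, and completely-at-random
missingness. Under $\pi_1 = 0$ each column is exactly Uniform(0,1), which
the null-calibration acceptance test exploits (KS uniformity, significant
counts within 4 binomial SDs of $\alpha M$).

`simulate_two_group()` goes one level deeper and produces *real* p-values:
Gaussian expression for two groups of samples with a `de_fraction` of genes
mean-shifted by `fold_effect` standard deviations, analyzed by Welch's
t-test, the Wilcoxon rank-sum test (normal approximation with tie and
continuity correction, validated against `stats::wilcox.test`), and a
permutation test of the Welch statistic with $p = (b+1)/(B+1)$ (never zero,
slightly conservative). Defaults (2 groups, `fold_effect = 2`,
`noise_sd = 1`, $B = 1000$) reflect a moderately powered microarray-style
study.

What the generators do **not** emulate: heavy-tailed or count-distributed
expression, correlated genes, batch effects, or informative missingness. A
green test therefore establishes algorithmic correctness of the comparison
machinery on data with the right marginal structure — it does not establish
that any particular real dataset's published counts would be reproduced.

Both generators take an explicit `seed`, are bit-reproducible given it, and
restore the caller's RNG state.

## Worked example

```{r example}
m <- simulate_pvalue_matrix(500, 4, rho = 0.6, pi1 = 0.1, mu = 2.5,
                            missing_rate = 0.02, seed = 42)
correlation_matrix(m)

classify_pair(m, "method1", "method2", 0.05)

threshold_sweep(m, "method1", "method2")

head(common_significant(m, thresholds = 0.01))

fisher_combine(c(0.05, 0.05))
```

The same pipeline is scriptable: `run_cli()` dispatches the `pairwise`,
`detail`, `multi`, `annotate`, `simulate` and `merge` subcommands, writes
all TSV/HTML/image artifacts plus a `run_config.json` capturing the fully
resolved configuration, and is byte-deterministic for its TSV/HTML outputs
(`merge` outer-joins one-method files by marker id for one-file-per-method
workflows).

## Numerical choices and limitations

* Clamp floor `1e-300`: keeps $-\log_{10}$ and $\ln$ finite without
  visibly distorting any realistic p-value.
* Inclusive thresholds ($p \le \alpha$); ties in ranking break by input
  order; percent selection rounds up.
* Correlation cells with fewer than 2 pair-complete markers, or with a
  constant column, are `NA` rather than an error.
* The Venn diagram is drawn for 2 sets only; for 3 or more methods the
  multi-method table plays that role (an n-way Venn does not scale
  visually).
* No multiplicity correction is applied anywhere: the tool compares raw
  per-method p-values at user-chosen thresholds, and the combined p is
  likewise uncorrected.
* Rendering matches semantics, not pixels, of any particular GUI: images
  are standard base-graphics PNG/SVG; only TSV/HTML outputs are promised
  byte-identical across repeated runs.
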