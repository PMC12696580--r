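---
title: "Methods: pairing scores, TE windows, and the statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairing scores, TE windows, and the statistical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepair)
library(dplyr)
```

## The question and the measurement

In organisms where homologous chromosomes physically pair — constitutively in
*Drosophila* somatic cells, transiently in mammals — haplotype-resolved Hi-C
lets one measure how tightly the maternal and paternal copies of a region sit
together. The unit of analysis is a fixed-size genomic window, and the
measurement is the **pairing score**

$$P_w = \log_2 \bar{f}_w,$$

where $\bar f_w$ is the average trans-homolog contact frequency observed for
window $w$. Higher $P_w$ means tighter pairing. This package computes $P_w$
from published contact matrices, aggregates genomic features — transposable
element (TE) annotations, SNP calls, RNA and TE-derived read coverage — into
the same windows, and asks whether TE content is associated with looser
pairing.

Window width follows the resolution of the available contact data: 4 kb for
the fly cell-line track, 40 kb for the mouse embryo data, 32 kb for yeast.
Windows tile each chromosome from coordinate 0, half-open, the last window
truncated at the chromosome end.

### The averaging support

Published descriptions of the score say "average contact frequency for a
given window" without fixing what is averaged. The default here is the
smallest faithful reading: the single homologous (diagonal) cell of the
window. A diagonal band is available as an option
(`band_halfwidth = b` averages the cells at offsets $-b\ldots b$ along the
same chromosome; unobserved cells inside the band count as zero frequency,
cells beyond the chromosome end are excluded from the support). Neither
reading is asserted as "the" original; results in this package are reported
for the single-cell default unless stated otherwise.

### Missing scores

A window whose averaged contact mass is zero gets a missing score, not
$-\infty$; such windows are dropped listwise from every test, with a tally.
Users who prefer a complete track can set a positive `pseudocount`, which is
added to the mean frequency before the log. Matrices are assumed
pre-normalized: no ICE/balancing is performed, since the pipeline consumes
published matrices.

## The synthetic data generator

Real inputs for this analysis are large external Hi-C accessions, so the
package ships a generative model that emulates their structure with known
ground truth. It is first-class, tested code, not a fixture:

* **True pairing score.** Each window draws an independent
  $\mathcal N(\mu_0, \sigma_0^2)$ baseline on the log2 scale
  (defaults $\mu_0 = 0$, $\sigma_0 = 0.5$), plus the `effect` of every TE
  family overlapping the window (each family counted once per window,
  additively, before noise). The marginal normality of the baseline is an
  assumption of convenience — the marginal distribution of real pairing
  scores is not published — and parameter-recovery results should be read
  with that in mind.
* **Contacts.** The emitted frequency of window $w$ is
  $2^{P_w + \varepsilon}$, $\varepsilon \sim \mathcal N(0, \sigma_n^2)$
  (default $\sigma_n = 0.3$), placed on the homologous diagonal cell.
  Optional band emission adds neighbors at offsets $1..b$ with geometric
  decay $0.5^{o}$, to exercise band averaging.
* **TE insertions.** Placed uniformly over the genome, lengths log-uniform
  on 500–7000 bp (spanning real LINE/LTR element scales; no published
  insertion-length model exists for this analysis), overlap permitted. Each
  insertion independently receives a genotype class
  (`maternal_only` / `paternal_only` / `both`) with configurable
  probabilities (defaults 0.25/0.25/0.5); no class-specific pairing effect
  is simulated by default, since all classes are reported to behave alike.
* **SNPs.** Per-window counts are Poisson with mean 20 (the center of real
  per-4 kb-window SNP histograms), with a configurable fraction of windows
  forced to zero — a point mass standing in for the observed excess of
  SNP-free windows, which published histograms describe but do not
  parameterize.
* **Coverage.** RNA read depth per window is
  $\max(0, \mathrm{round}(100 + 30\,P_w + \eta))$ — positively coupled to
  pairing; TE-derived read depth is nonzero only in TE-containing windows
  and uses a negative slope ($50 - 30\,P_w$), so depth accumulates where
  pairing is depressed. The bases and slopes are arbitrary but of realistic
  order for per-4 kb read counts.

What the generator does **not** emulate: read-level data (no FASTQ, no
restriction fragments, no mapping artifacts), spatial autocorrelation of
Hi-C signal along the diagonal, chromatin-state structure (no
euchromatin/heterochromatin masking), distance-dependent contact decay, or
family-specific insertion preferences. Tests passing on this model therefore
show that the *pipeline arithmetic* is right and that effects of the assumed
form are recoverable — not that real data satisfy the model.

Identical seed and configuration give byte-identical output files.

## Feature aggregation rules

* A window "contains" a TE if they overlap by at least 1 bp (the
  `bedtools intersect` default); containment of the full element is not
  required, and a TE spanning several windows contributes to each.
* Read counting follows `bedtools multicov`: a read is counted once in
  every window it overlaps.
* SNPs are points; VCF positions are converted to 0-based on read.
* Parental concordance of TE calls uses 50% reciprocal overlap plus family
  identity (the matching rule is otherwise unpublished); both thresholds are
  exposed.
* Chromosome name mismatches between inputs are an error, never silently
  reconciled.

## The statistical battery

All tests treat windows as independent observations. Hi-C signal is in fact
spatially autocorrelated along the genome, so nominal p-values are
optimistic; this replicates the analysis convention of the studies this
package models, and no spatial correction is offered.

* **TE vs no-TE** (`compare_groups`): two-sample t (Welch by default;
  pooled-variance provided because `pairwise.t.test`-style analyses pool) or
  Wilcoxon rank-sum. The Wilcoxon p-value is exact when both groups have at
  most 50 values and no ties, the tie- and continuity-corrected normal
  approximation otherwise.
* **Per-family tests** (`per_family_tests`): each family detected in at
  least `min_windows = 3` scored windows is compared against the no-TE
  baseline; Bonferroni correction uses $m$ = the number of families actually
  tested, $p_{\mathrm{adj}} = \min(1, m\,p)$. A family's direction is
  "lower" iff its median score is below the baseline median.
* **Family bias test** (`family_bias_counts` + `binomial_bias_test`): the
  per-family mean (or median) score is compared with the same statistic over
  *all* scored windows — TE and no-TE alike, i.e. the entire genome with
  contact data; $k$ counts families **strictly** below the reference (exact
  ties, measure-zero on real data, are not counted). The exact binomial test
  against $p_0 = 0.5$ uses the conventional two-sided rule (sum of all
  outcome probabilities not exceeding that of the observed $k$), which
  reproduces published worked examples to print precision.
* **Trend tests** (`trend_test`): Pearson, Spearman, or the OLS slope of
  score on covariate — whether published "significant trends" were
  correlations or regression slopes is not stated, so all three are provided
  and none asserted as original.
* **Genotype-class tests** (`genotype_class_tests`): each class versus
  no-TE windows, Bonferroni over the classes tested.
* Two-sided alternatives everywhere by default; directional "less" is
  exposed since the scientific hypotheses are one-sided. Only Bonferroni is
  offered (no FDR), matching the analysis convention being replicated.

### Degenerate inputs

A genome where every window contains TE content — the expected situation for
yeast at 32 kb windows, where insertions occur roughly every 25–40 kb —
leaves no baseline group. The pipeline then skips the TE vs no-TE,
per-family and genotype-class comparisons with an explicit warning, reports
the fact, and still runs the bias and trend analyses. Groups with fewer than
2 scored windows are an error (named) in direct calls and a logged skip in
the pipeline.

## A worked example

A small synthetic genome with one depressive LINE family:

```{r example}
cfg <- run_config(simulation = simulation_config(
  seed = 11,
  assembly = assembly(c("c1", "c2"), c(1.2e6, 8e5)),
  noise_sd = 0.3,
  family_specs = bind_rows(
    te_family("Baggins-like", "LINE", 25, effect = -1),
    te_family("NullDNA", "DNA", 15, effect = 0))))
run <- run_pipeline(cfg, file.path(tempdir(), "demo_run"))
glance(run)
tidy(run$family_tests)
```

The injected family is recovered as significantly lower after Bonferroni;
the null family is not.

## Problem sizes and verification

The package's own test suite verifies, among other properties: exact
binomial p-values for all $(k, n \le 20)$ against direct pmf summation;
exact Wilcoxon p-values for group sizes up to 8 against full
rank-assignment enumeration; all overlap counting against a per-base
brute-force scan on genomes up to 100 kb; pairing-score log identities to
1e-9; type-I error calibration of the TE vs no-TE test over 200 null
replicates on 300-window genomes; and recovery of a $-1$ log2 family effect
over $\ge 50$ of ~2500 windows in 20 replicates. These sizes were chosen as
the smallest at which the law-of-large-numbers checks are stable.

## Known limitations

* Windows are treated as independent; no spatial autocorrelation model.
* No cis-score analysis, no Hi-C matrix balancing, no read-level processing
  (alignment, variant calling, TE discovery are upstream of this package).
* The synthetic model's normal baseline and uniform TE placement are
  conveniences, not biology; see above for what passing tests do and do not
  establish.
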