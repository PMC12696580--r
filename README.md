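# tepair

Do transposable elements (TEs) loosen the pairing of homologous
chromosomes? `tepair` is an R package for analysts working with
haplotype-resolved Hi-C: it turns contact matrices into per-window
**pairing scores**, overlays TE annotations, SNP calls and read coverage on
the same windows, and runs the statistical battery that the question calls
for — TE vs no-TE comparisons, per-family tests with Bonferroni correction,
an exact binomial bias test across families, and pairing-vs-depth trend
tests.

The core quantity is the pairing score of a fixed-size genome window *w*,

&nbsp;&nbsp;&nbsp;&nbsp;*P<sub>w</sub>* = log₂ *f̄<sub>w</sub>*,

the log2 average trans-homolog contact frequency for that window (higher =
tighter physical pairing; 4 kb windows for fly data, 40 kb mouse, 32 kb
yeast). The family-level bias test asks whether, of the *n* TE families
with scored windows, the number *k* whose mean pairing falls below the
genome-wide mean departs from Binomial(*n*, ½) — i.e., whether TE families
are disproportionately found in loosely paired windows.

Because the real inputs are large external Hi-C accessions, the package
includes a fully specified synthetic diploid generator
(`simulate_dataset()`) with known ground-truth pairing effects, so every
stage of the pipeline is testable end-to-end without downloading anything.

## A worked example

Simulate a 2 Mb diploid genome (500 × 4 kb windows) in which one LINE
family depresses pairing by 1 log2 unit wherever it inserts, then run the
whole pipeline:

```r
library(tepair)
library(dplyr)

cfg <- run_config(simulation = simulation_config(
  seed = 11,
  assembly = assembly(c("c1", "c2"), c(1.2e6, 8e5)),
  noise_sd = 0.3,
  family_specs = bind_rows(
    te_family("Baggins-like", "LINE", 25, effect = -1),
    te_family("NullDNA",      "DNA",  15, effect = 0))))

run <- run_pipeline(cfg, "demo_run")
glance(run)
#> # A tibble: 1 × 9
#>   n_windows n_scored n_te_windows n_no_te_windows n_families_tested
#>       <int>    <int>        <int>           <int>             <int>
#> 1       500      500           54             446                 2
#> # i 4 more variables: n_families_significant <int>, te_comparison_p <dbl>,
#> #   bias_estimate <dbl>, bias_p <dbl>

tidy(run$family_tests)
#> # A tibble: 2 × 8
#>   term         te_class n_windows statistic p.value p.adjusted estimate direction
#>   <chr>        <chr>        <int>     <dbl>   <dbl>      <dbl>    <dbl> <chr>
#> 1 Baggins-like LINE            34    -7.59  4.62e-9    9.23e-9  -0.842  lower
#> 2 NullDNA      DNA             20    -0.849 4.05e-1    8.11e-1  -0.0407 lower
```

The injected family is recovered: its 34 windows score significantly lower
than the 446 no-TE windows after Bonferroni correction (adjusted p =
9.2e-9, median 0.84 log2 units below baseline), while the zero-effect
family is correctly not significant. `run_pipeline()` also writes every
artifact to the run directory — `pairing.bedGraph`,
`window_features.tsv`, one TSV per analysis, `manifest.json` and a
markdown `report.md` — and `report("demo_run")` regenerates the summary
from those files.

Worked example of the bias test on printed inputs: 509 of 810 TE families
below the genome-wide mean gives

```r
binomial_bias_test(509, 810)
#>       k     n estimate  p_value    p0
#>     509   810    0.628 2.61e-13   0.5
```

Lower-level entry points: `make_windows()`, `read_contacts()` /
`aggregate_bins()` / `compute_pairing_scores()`, `build_window_features()`
+ `join_pairing()`, then `compare_groups()`, `per_family_tests()`,
`family_bias_counts()`, `trend_test()`, `genotype_class_tests()`. Results
are tibbles with `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
views. A thin command-line wrapper lives at `inst/cli/tepair.R`
(`simulate`, `run`, `report` subcommands with a YAML config).

See `vignettes/pairing-te-methods.Rmd` for the model, the synthetic
generator's assumptions, and every numerical rule (averaging support,
missing-score handling, overlap semantics, test variants).

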