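#' Configure an end-to-end pipeline run
#'
#' A run either simulates its inputs (`simulation` given) or reads them from
#' files (`paths` given) — exactly one of the two. File inputs are: sparse
#' contact triplets, a chrom.sizes file, and optionally TE BED, SNP VCF, and
#' RNA / TE-read BED4 coverage.
#'
#' @param simulation A [simulation_config()], or `NULL`.
#' @param paths Named list of input paths (`contacts`, `chrom_sizes`,
#'   optional `tes`, `snps`, `rna_coverage`, `te_coverage`), or `NULL`.
#' @param window_size Analysis window in bp (default 4000; for file inputs it
#'   must match or coarsen the contact resolution).
#' @param resolution Bin width of the contact file if finer than
#'   `window_size` (default: equal to `window_size`).
#' @param band_halfwidth,pseudocount Passed to [compute_pairing_scores()].
#' @param test,t_variant,alternative,min_windows Passed to the statistical
#'   battery.
#' @param trend_method Method for [trend_test()] (default `"pearson"`).
#' @return A validated run config (class `tepair_run_config`).
#' @export
run_config <- function(simulation = NULL, paths = NULL,
                       window_size = 4000, resolution = NULL,
                       band_halfwidth = 0, pseudocount = 0,
                       test = c("t", "wilcoxon"),
                       t_variant = c("welch", "pooled"),
                       alternative = c("two.sided", "less", "greater"),
                       min_windows = 3,
                       trend_method = c("pearson", "spearman", "ols_slope")) {
  if (is.null(simulation) == is.null(paths)) {
    abort("supply exactly one of `simulation` or `paths`")
  }
  if (!is.null(paths)) {
    stopifnot(all(c("contacts", "chrom_sizes") %in% names(paths)))
    missing <- !vapply(paths, file.exists, logical(1))
    if (any(missing)) {
      abort(paste0("input file(s) not found: ",
                   paste(unlist(paths[missing]), collapse = ", ")))
    }
  }
  structure(list(
    simulation = simulation, paths = paths,
    window_size = if (!is.null(simulation)) simulation$window_size else window_size,
    resolution = resolution,
    band_halfwidth = band_halfwidth, pseudocount = pseudocount,
    test = match.arg(test), t_variant = match.arg(t_variant),
    alternative = match.arg(alternative), min_windows = min_windows,
    trend_method = match.arg(trend_method)
  ), class = "tepair_run_config")
}

#' Run the full pairing/TE analysis pipeline
#'
#' simulate (or read) -> pairing scores -> window features -> statistical
#' battery, writing every artifact into `out_dir`: the pairing track
#' (bedGraph), the window feature table (TSV), one TSV per analysis, a JSON
#' manifest (config hash, package version, artifact row counts) and a
#' markdown report. When the window grid leaves no TE-free window (as happens
#' at coarse window sizes over TE-dense genomes), all comparisons against the
#' no-TE baseline are skipped with a warning and the report says so; the bias
#' and trend analyses still run.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list of class `tepair_run` with the in-memory
#'   results: `grid`, `track`, `windows`, `te_comparison`, `family_tests`,
#'   `genotype_tests`, `bias`, `trends`, `skipped`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "tepair_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status_path <- file.path(out_dir, "STATUS")
  writeLines("INCOMPLETE", status_path)

  if (!is.null(config$simulation)) {
    dataset <- simulate_dataset(config$simulation)
    write_dataset(dataset, file.path(out_dir, "inputs"))
    grid <- dataset$grid
    contacts <- dataset$contacts
    tes <- dataset$tes
    snps <- dataset$snps
    rna_cov <- dataset$rna_coverage
    te_cov <- dataset$te_coverage
  } else {
    p <- config$paths
    asm <- read_chrom_sizes(p$chrom_sizes)
    grid <- make_windows(asm, config$window_size)
    contacts <- read_contacts(p$contacts)
    if (!is.null(config$resolution) && config$resolution != config$window_size) {
      contacts <- aggregate_bins(contacts, config$resolution, config$window_size)
    }
    tes <- if (!is.null(p$tes)) read_te_bed(p$tes) else NULL
    snps <- if (!is.null(p$snps)) read_snp_vcf(p$snps) else NULL
    rna_cov <- if (!is.null(p$rna_coverage)) read_bed4(p$rna_coverage) else NULL
    te_cov <- if (!is.null(p$te_coverage)) read_bed4(p$te_coverage) else NULL
  }

  track <- compute_pairing_scores(contacts, grid,
                                  band_halfwidth = config$band_halfwidth,
                                  pseudocount = config$pseudocount)
  write_bedgraph(track, file.path(out_dir, "pairing.bedGraph"))

  features <- build_window_features(grid, tes = tes, snps = snps,
                                    rna_coverage = rna_cov, te_coverage = te_cov)
  windows <- join_pairing(features, track)
  write_feature_table(windows, file.path(out_dir, "window_features.tsv"))

  n_note <- sum(!windows$has_te & !is.na(windows$score))
  skipped <- character()
  te_comparison <- family_tests <- genotype_tests <- NULL
  if (n_note < 2) {
    warn(paste0("all (or all but one) scored windows contain TE content at ",
                config$window_size, " bp resolution; ",
                "TE vs no-TE, per-family and genotype-class comparisons skipped"))
    skipped <- c("te_comparison", "family_tests", "genotype_tests")
  } else {
    te_comparison <- compare_groups(windows, "has_te", test = config$test,
                                    alternative = config$alternative,
                                    t_variant = config$t_variant)
    readr::write_tsv(te_comparison, file.path(out_dir, "te_vs_note.tsv"))
    family_tests <- per_family_tests(windows, min_windows = config$min_windows,
                                     test = config$test,
                                     alternative = config$alternative,
                                     t_variant = config$t_variant)
    readr::write_tsv(family_tests, file.path(out_dir, "family_tests.tsv"))
    genotype_tests <- genotype_class_tests(windows, test = config$test,
                                           alternative = config$alternative,
                                           t_variant = config$t_variant)
    if (nrow(genotype_tests) > 0) {
      readr::write_tsv(genotype_tests, file.path(out_dir, "genotype_tests.tsv"))
    }
  }

  bias <- tryCatch({
    fb <- family_bias_counts(windows)
    res <- binomial_bias_test(fb$k, fb$n)
    res$reference <- fb$reference
    res
  }, error = function(e) {
    warn(paste0("bias test skipped: ", conditionMessage(e)))
    skipped <<- c(skipped, "bias")
    NULL
  })
  if (!is.null(bias)) readr::write_tsv(bias, file.path(out_dir, "bias_test.tsv"))

  trends <- purrr::map_dfr(c("rna_depth", "te_depth", "snp_count"), function(cv) {
    tryCatch(as_tibble(trend_test(windows, cv, method = config$trend_method)),
             error = function(e) tibble())
  })
  if (nrow(trends) > 0) readr::write_tsv(trends, file.path(out_dir, "trends.tsv"))

  manifest <- list(
    package = "tepair",
    version = as.character(utils::packageVersion("tepair")),
    config_hash = rlang::hash(config),
    window_size = config$window_size,
    n_windows = nrow(grid),
    n_scored_windows = sum(!is.na(track$score)),
    n_te_windows = sum(windows$has_te),
    n_no_te_windows = sum(!windows$has_te),
    n_contacts = nrow(contacts),
    skipped = as.list(skipped),
    artifacts = lapply(
      setNames(nm = list.files(out_dir, pattern = "\\.(tsv|bedGraph)$")),
      function(f) length(readLines(file.path(out_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  run <- structure(list(grid = grid, track = track, windows = windows,
                        te_comparison = te_comparison,
                        family_tests = family_tests,
                        genotype_tests = genotype_tests,
                        bias = bias, trends = trends,
                        skipped = skipped, out_dir = out_dir),
                   class = "tepair_run")
  writeLines(report_lines(run), file.path(out_dir, "report.md"))
  writeLines("COMPLETE", status_path)
  invisible(run)
}

write_feature_table <- function(windows, path) {
  flat <- windows
  for (col in c("families", "te_classes", "genotype_classes")) {
    flat[[col]] <- vapply(flat[[col]], paste, "", collapse = ",")
  }
  readr::write_tsv(flat, path)
}

#' Summarize a completed run
#'
#' Regenerates the human-readable report of a run directory from its TSV
#' artifacts (every reported number is recomputable from them).
#'
#' @param run A `tepair_run` object or the path to a completed run directory.
#' @return The report, as a character vector of markdown lines, invisibly;
#'   also printed.
#' @export
report <- function(run) {
  if (is.character(run)) {
    status_path <- file.path(run, "STATUS")
    if (!file.exists(status_path) || readLines(status_path)[[1]] != "COMPLETE") {
      abort(paste0("not a completed run directory: ", run))
    }
    lines <- readLines(file.path(run, "report.md"))
  } else {
    stopifnot(inherits(run, "tepair_run"))
    lines <- report_lines(run)
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

report_lines <- function(run) {
  w <- run$windows
  n_sig <- if (!is.null(run$family_tests)) sum(run$family_tests$p_adjusted < 0.05) else NA
  lines <- c(
    "# Pairing score / TE analysis report",
    "",
    sprintf("- windows: %d (%d with a pairing score)", nrow(w), sum(!is.na(w$score))),
    sprintf("- TE-containing windows: %d; no-TE windows: %d",
            sum(w$has_te), sum(!w$has_te)),
    ""
  )
  if ("te_comparison" %in% run$skipped) {
    lines <- c(lines,
               "## TE vs no-TE comparison",
               "",
               "Skipped: all scored windows contain TE content at this window size,",
               "so no TE-free baseline exists (expected for TE-dense genomes at",
               "coarse resolution).", "")
  } else if (!is.null(run$te_comparison)) {
    tc <- run$te_comparison
    lines <- c(lines,
               "## TE vs no-TE comparison", "",
               sprintf("- %s test, %s: statistic %.4f, p = %.4g",
                       tc$test, tc$alternative, tc$statistic, tc$p_value),
               sprintf("- median score TE windows %.4f vs no-TE %.4f",
                       tc$median1, tc$median2), "")
  }
  if (!is.null(run$family_tests)) {
    ft <- run$family_tests
    lines <- c(lines, "## Per-family tests", "",
               sprintf("- families tested (>= min windows): %d", nrow(ft)),
               sprintf("- significant after Bonferroni (p < 0.05): %d", n_sig))
    sig <- ft[ft$p_adjusted < 0.05, ]
    if (nrow(sig) > 0) {
      lines <- c(lines, "", "family | class | n windows | p adjusted | direction",
                 "--- | --- | --- | --- | ---",
                 sprintf("%s | %s | %d | %.3g | %s", sig$family, sig$te_class,
                         sig$n_windows, sig$p_adjusted, sig$direction))
    }
    lines <- c(lines, "")
  }
  if (!is.null(run$genotype_tests) && nrow(run$genotype_tests %||% tibble()) > 0) {
    gt <- run$genotype_tests
    lines <- c(lines, "## Genotype-class comparisons", "",
               sprintf("- %s: n = %d, p adjusted = %.3g, direction %s",
                       gt$genotype_class, gt$n_class, gt$p_adjusted, gt$direction),
               "")
  }
  if (!is.null(run$bias)) {
    lines <- c(lines, "## Family bias test", "",
               sprintf("- %d of %d families below the genome-wide mean (estimate %.2f), exact binomial p = %.3g",
                       run$bias$k, run$bias$n, run$bias$estimate, run$bias$p_value),
               "")
  }
  if (!is.null(run$trends) && nrow(run$trends) > 0) {
    tr <- run$trends
    lines <- c(lines, "## Trend tests", "",
               sprintf("- score vs %s (%s): estimate %.4f, p = %.3g, n = %d",
                       tr$covariate, tr$method, tr$estimate, tr$p_value, tr$n),
               "")
  }
  lines
}

#' @export
print.tepair_run <- function(x, ...) {
  cat("<tepair_run> in ", x$out_dir, "\n", sep = "")
  report(x)
  invisible(x)
}
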