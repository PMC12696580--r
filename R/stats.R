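# The statistical battery: group comparisons of pairing scores, per-family
# tests with Bonferroni correction, the families-below-reference binomial
# bias test, and pairing-vs-depth trend tests. All functions take the joined
# windows table (build_window_features() + join_pairing()) and drop windows
# with missing scores listwise, reporting how many were dropped.

drop_unscored <- function(windows, quiet = FALSE) {
  miss <- is.na(windows$score)
  if (any(miss) && !quiet) {
    inform(paste0(sum(miss), " window(s) without a pairing score dropped"))
  }
  windows[!miss, , drop = FALSE]
}

#' Compare pairing scores between two groups of windows
#'
#' Two-sample test of pairing scores between window groups — canonically TE
#' versus no-TE windows. Uses Student/Welch t or the Wilcoxon rank-sum test;
#' the Wilcoxon p-value is exact (full null distribution) when both groups
#' have at most 50 untied values, and the tie/continuity-corrected normal
#' approximation otherwise.
#'
#' @param windows Data frame with a `score` column (log2 pairing score, `NA`
#'   allowed and dropped) and the grouping column.
#' @param group Name of the grouping column (must yield exactly two groups),
#'   or a logical/character vector of length `nrow(windows)`.
#' @param test `"t"` (default) or `"wilcoxon"`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the first group relative to the second.
#' @param t_variant `"welch"` (default, unequal variances) or `"pooled"`.
#' @return A one-row tibble of class `tepair_comparison`: groups, sizes,
#'   test, statistic, `p_value`, and per-group mean/median summaries.
#' @export
compare_groups <- function(windows, group = "has_te",
                           test = c("t", "wilcoxon"),
                           alternative = c("two.sided", "less", "greater"),
                           t_variant = c("welch", "pooled")) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  t_variant <- match.arg(t_variant)
  windows <- as_tibble(windows)
  g <- if (length(group) == 1 && is.character(group)) windows[[group]] else group
  if (is.null(g) || length(g) != nrow(windows)) abort("invalid `group`")
  keep <- !is.na(windows$score) & !is.na(g)
  score <- windows$score[keep]
  logical_group <- is.logical(g)
  g <- as.character(g[keep])
  # logical groups put TRUE (the TE side) first; otherwise alphabetical
  labs <- if (logical_group) c("TRUE", "FALSE") else sort(unique(g))
  if (length(labs) != 2) abort("`group` must define exactly two groups")
  x <- score[g == labs[[1]]]
  y <- score[g == labs[[2]]]
  for (i in 1:2) {
    if (sum(g == labs[[i]]) < 2) {
      abort(paste0("group '", labs[[i]], "' has fewer than 2 scored windows"))
    }
  }
  ht <- run_two_sample_test(x, y, test, alternative, t_variant)
  structure(tibble(
    group1 = labs[[1]], group2 = labs[[2]],
    n1 = length(x), n2 = length(y),
    test = test, alternative = alternative,
    statistic = unname(ht$statistic), p_value = ht$p.value,
    mean1 = mean(x), mean2 = mean(y),
    median1 = median(x), median2 = median(y)
  ), class = c("tepair_comparison", class(tibble())))
}

run_two_sample_test <- function(x, y, test, alternative, t_variant) {
  if (test == "t") {
    t.test(x, y, alternative = alternative, var.equal = t_variant == "pooled")
  } else {
    exact <- length(x) <= 50 && length(y) <= 50
    suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                 exact = exact, correct = TRUE))
  }
}

#' Per-family tests of pairing score against no-TE windows
#'
#' For every TE family detected in at least `min_windows` scored windows,
#' compares the pairing scores of that family's windows against the no-TE
#' baseline windows, then Bonferroni-corrects over the m families actually
#' tested.
#'
#' @param windows Joined windows table with `score`, `has_te` and the
#'   `families` list-column.
#' @param min_windows Minimum number of scored windows a family must overlap
#'   to be tested (default 3).
#' @param test,alternative,t_variant As in [compare_groups()].
#' @return A tibble of class `tepair_family_tests`, one row per tested
#'   family, sorted by adjusted p: `family`, `te_class`, `n_windows`,
#'   `statistic`, `p_raw`, `p_adjusted` (`= min(1, m * p_raw)`),
#'   `median_score`, `direction` (`"lower"` iff family median < no-TE
#'   median), with `m` and the baseline summary as attributes.
#' @export
per_family_tests <- function(windows, min_windows = 3,
                             test = c("t", "wilcoxon"),
                             alternative = c("two.sided", "less", "greater"),
                             t_variant = c("welch", "pooled")) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  t_variant <- match.arg(t_variant)
  windows <- drop_unscored(as_tibble(windows))
  baseline <- windows$score[!windows$has_te]
  if (length(baseline) < 2) abort("fewer than 2 scored no-TE baseline windows")
  base_median <- median(baseline)

  fam_class <- family_class_map(windows)
  long <- tidyr::unnest(windows[c("score", "families")], "families") |>
    rename(family = "families")
  counts <- count(long, .data$family, name = "n_windows")
  tested <- counts$family[counts$n_windows >= min_windows]
  if (length(tested) == 0) {
    warn("no TE family passes the min_windows filter")
    return(empty_family_tests())
  }
  m <- length(tested)
  res <- purrr::map_dfr(tested, function(fam) {
    sc <- long$score[long$family == fam]
    ht <- run_two_sample_test(sc, baseline, test, alternative, t_variant)
    tibble(family = fam,
           te_class = fam_class[fam] %||% NA_character_,
           n_windows = length(sc),
           statistic = unname(ht$statistic),
           p_raw = ht$p.value,
           median_score = median(sc),
           direction = ifelse(median(sc) < base_median, "lower", "higher"))
  })
  res$te_class <- unname(fam_class[res$family])
  res$p_adjusted <- bonferroni(res$p_raw, m)
  res <- res[order(res$p_adjusted, res$p_raw, res$family),
             c("family", "te_class", "n_windows", "statistic", "p_raw",
               "p_adjusted", "median_score", "direction")]
  structure(res, class = c("tepair_family_tests", class(tibble())),
            m = m, n_baseline = length(baseline), baseline_median = base_median)
}

empty_family_tests <- function() {
  structure(tibble(family = character(), te_class = character(),
                   n_windows = integer(), statistic = numeric(),
                   p_raw = numeric(), p_adjusted = numeric(),
                   median_score = numeric(), direction = character()),
            class = c("tepair_family_tests", class(tibble())),
            m = 0L, n_baseline = NA_integer_, baseline_median = NA_real_)
}

family_class_map <- function(windows) {
  if (!"te_classes" %in% names(windows)) return(character())
  # te_classes is aligned element-wise with families (see assign_tes())
  pairs <- tibble(family = unlist(windows$families),
                  te_class = unlist(windows$te_classes))
  if (nrow(pairs) == 0) return(character())
  pairs <- distinct(pairs, .data$family, .keep_all = TRUE)
  setNames(pairs$te_class, pairs$family)
}

#' Count TE families whose pairing falls below the genome-wide reference
#'
#' Computes, for each TE family with at least one scored window, the mean (or
#' median) pairing score over its windows, and compares it with the same
#' statistic over all scored windows of the genome. Returns how many families
#' fall strictly below the reference — the (k, n) input of
#' [binomial_bias_test()]. Ties with the reference are not counted in k.
#'
#' @param windows Joined windows table (`score`, `families`).
#' @param reference_stat,per_family_stat `"mean"` (default) or `"median"`.
#' @return A list with `k`, `n`, `reference`, and the per-family tibble.
#' @export
family_bias_counts <- function(windows, reference_stat = c("mean", "median"),
                               per_family_stat = c("mean", "median")) {
  reference_stat <- match.arg(reference_stat)
  per_family_stat <- match.arg(per_family_stat)
  windows <- drop_unscored(as_tibble(windows), quiet = TRUE)
  if (nrow(windows) == 0) abort("no scored windows")
  ref_fun <- if (reference_stat == "mean") mean else median
  fam_fun <- if (per_family_stat == "mean") mean else median
  reference <- ref_fun(windows$score)
  long <- tidyr::unnest(windows[c("score", "families")], "families") |>
    rename(family = "families")
  if (nrow(long) == 0) abort("no TE family with a scored window")
  per_family <- long |>
    group_by(.data$family) |>
    summarise(stat = fam_fun(.data$score), n_windows = n(), .groups = "drop") |>
    mutate(below = .data$stat < reference)
  list(k = sum(per_family$below), n = nrow(per_family),
       reference = reference, per_family = per_family)
}

#' Exact binomial test for a pairing-score bias across TE families
#'
#' Tests whether the proportion of TE families with pairing below the
#' genome-wide reference departs from `p0 = 0.5` (no bias: equally many
#' families above and below). The p-value is the conventional exact two-sided
#' rule: the sum of probabilities of all outcomes whose point probability
#' does not exceed that of the observed k.
#'
#' @param k Number of families below the reference (see
#'   [family_bias_counts()]).
#' @param n Number of families tested.
#' @param p0 Null proportion (default 0.5).
#' @return A one-row tibble of class `tepair_bias`: `k`, `n`, `estimate`
#'   (k/n), `p_value`, `p0`.
#' @examples
#' binomial_bias_test(509, 810)  # estimate 0.63, p ~ 2.6e-13
#' @export
binomial_bias_test <- function(k, n, p0 = 0.5) {
  if (length(n) != 1 || n < 1) abort("`n` must be a positive integer")
  if (k < 0 || k > n) abort("`k` must lie in [0, n]")
  ht <- binom.test(k, n, p = p0, alternative = "two.sided")
  structure(tibble(k = as.integer(k), n = as.integer(n),
                   estimate = k / n, p_value = ht$p.value, p0 = p0),
            class = c("tepair_bias", class(tibble())))
}

#' Trend test between pairing score and a per-window covariate
#'
#' Association between the pairing score and a count covariate (RNA read
#' depth, TE-derived read depth, SNP count): Pearson or Spearman correlation,
#' or the slope of an ordinary least-squares regression of score on the
#' covariate.
#'
#' @param windows Joined windows table.
#' @param covariate Name of the covariate column (e.g. `"rna_depth"`).
#' @param method `"pearson"` (default), `"spearman"` or `"ols_slope"`.
#' @return A one-row tibble of class `tepair_trend`: `method`, `covariate`,
#'   `estimate` (correlation or slope), `p_value`, `n`.
#' @export
trend_test <- function(windows, covariate,
                       method = c("pearson", "spearman", "ols_slope")) {
  method <- match.arg(method)
  windows <- as_tibble(windows)
  if (!covariate %in% names(windows)) abort(paste0("no column `", covariate, "`"))
  x <- windows[[covariate]]
  keep <- !is.na(windows$score) & !is.na(x)
  x <- as.numeric(x[keep]); score <- windows$score[keep]
  if (length(x) < 3) abort("fewer than 3 paired defined values")
  if (stats::var(x) == 0) abort("zero variance: covariate is constant")
  if (method == "ols_slope") {
    fit <- summary(lm(score ~ x))
    est <- fit$coefficients["x", "Estimate"]
    p <- fit$coefficients["x", "Pr(>|t|)"]
  } else {
    ct <- suppressWarnings(cor.test(score, x, method = method))
    est <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(tibble(method = method, covariate = covariate,
                   estimate = est, p_value = p, n = length(x)),
            class = c("tepair_trend", class(tibble())))
}

#' Compare each TE genotype class against no-TE windows
#'
#' One comparison per genotype class present (`maternal_only`,
#' `paternal_only`, `both`, `unknown`): windows containing a TE of that class
#' versus no-TE windows, Bonferroni-corrected over the classes tested.
#' Classes with fewer than 2 scored windows are skipped with a warning.
#'
#' @param windows Joined windows table with the `genotype_classes`
#'   list-column.
#' @param test,alternative,t_variant As in [compare_groups()].
#' @return A tibble, one row per tested class, with the [compare_groups()]
#'   columns plus `genotype_class` and `p_adjusted`.
#' @export
genotype_class_tests <- function(windows, test = c("t", "wilcoxon"),
                                 alternative = c("two.sided", "less", "greater"),
                                 t_variant = c("welch", "pooled")) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  t_variant <- match.arg(t_variant)
  windows <- drop_unscored(as_tibble(windows))
  baseline <- windows$score[!windows$has_te]
  if (length(baseline) < 2) abort("fewer than 2 scored no-TE baseline windows")
  present <- sort(unique(unlist(windows$genotype_classes)))
  usable <- character()
  rows <- list()
  for (cl in present) {
    in_cl <- vapply(windows$genotype_classes, function(g) cl %in% g, logical(1))
    sc <- windows$score[in_cl]
    if (length(sc) < 2) {
      warn(paste0("genotype class '", cl, "' has fewer than 2 scored windows; skipped"))
      next
    }
    ht <- run_two_sample_test(sc, baseline, test, alternative, t_variant)
    rows[[cl]] <- tibble(
      genotype_class = cl, n_class = length(sc), n_baseline = length(baseline),
      test = test, statistic = unname(ht$statistic), p_raw = ht$p.value,
      median_class = median(sc), median_baseline = median(baseline),
      direction = ifelse(median(sc) < median(baseline), "lower", "higher"))
    usable <- c(usable, cl)
  }
  if (length(rows) == 0) {
    warn("no genotype class with >= 2 scored windows")
    return(tibble())
  }
  res <- bind_rows(rows)
  res$p_adjusted <- bonferroni(res$p_raw, length(usable))
  res
}

#' Bonferroni correction
#'
#' Multiplies each raw p-value by the number of tests m and caps at 1.
#' `m` may exceed `length(p)` when only a subset of tested hypotheses is
#' being adjusted.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Number of tests (default `length(p)`).
#' @return Adjusted p-values, `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (m < length(p)) abort("`m` must be at least length(p)")
  pmin(1, m * p)
}
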