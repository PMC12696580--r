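score_table <- function(score, group) {
  tibble::tibble(score = score, grp = group)
}

# windows table with explicit family membership per window
fam_table <- function(score, families) {
  tibble::tibble(score = score,
                 families = families,
                 te_classes = lapply(families, function(f) rep("LINE", length(f))),
                 has_te = lengths(families) > 0)
}

test_that("compare_groups reproduces hand-computed statistics", {
  w <- score_table(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  res <- compare_groups(w, "grp")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  w <- score_table(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  res <- compare_groups(w, "grp", test = "t", t_variant = "pooled")
  # pooled t by hand: diff -3, s_p = 1, se = sqrt(2/3)
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(res$statistic, 3), -3.674)

  res <- compare_groups(w, "grp", test = "wilcoxon")
  expect_equal(res$p_value, 0.1)  # 2 * (1 / choose(6, 3))

  w_bad <- score_table(c(1, 2, 3, 4), c("a", "a", "a", "tiny"))
  expect_error(compare_groups(w_bad, "grp"), "tiny")
})

test_that("exact Wilcoxon p-values equal full rank-assignment enumeration", {
  withr::local_seed(19)
  for (n1 in c(3, 5, 8)) {
    for (n2 in c(3, 6, 8)) {
      x <- sample(seq_len(100), n1)  # distinct values: no ties
      y <- sample(setdiff(seq_len(100), x), n2)
      w <- score_table(c(x, y), rep(c("a", "b"), c(n1, n2)))
      res <- compare_groups(w, "grp", test = "wilcoxon")
      expect_equal(res$p_value, oracle_wilcox_p(x, y), tolerance = 1e-12,
                   label = paste0("n1=", n1, ", n2=", n2))
    }
  }
})

test_that("per-family tests filter, correct and orient as specified", {
  withr::local_seed(23)
  base <- rnorm(30)
  famA <- rnorm(5) - 2   # clearly lower
  famB <- rnorm(2)       # below min_windows
  famC <- rnorm(4) + 2   # higher
  w <- fam_table(c(base, famA, famB, famC),
                 c(rep(list(character()), 30),
                   rep(list("A"), 5), rep(list("B"), 2), rep(list("C"), 4)))
  res <- per_family_tests(w, min_windows = 3)
  expect_setequal(res$family, c("A", "C"))  # B filtered out
  expect_equal(attr(res, "m"), 2L)
  expect_equal(res$p_adjusted, pmin(1, 2 * res$p_raw))
  expect_equal(res$direction[res$family == "A"], "lower")
  expect_equal(res$direction[res$family == "C"], "higher")
  expect_equal(res$n_windows[res$family == "A"], 5L)

  # lowering the filter adds families but never changes surviving raw p-values
  res2 <- per_family_tests(w, min_windows = 2)
  expect_setequal(res2$family, c("A", "B", "C"))
  expect_equal(res2$p_raw[match(c("A", "C"), res2$family)],
               res$p_raw[match(c("A", "C"), res$family)])
  expect_equal(attr(res2, "m"), 3L)

  w_none <- fam_table(rnorm(10), rep(list(character()), 10))
  expect_warning(res3 <- per_family_tests(w_none), "min_windows")
  expect_equal(nrow(res3), 0)
})

test_that("a window shared by two families enters both tests", {
  withr::local_seed(29)
  w <- fam_table(rnorm(20),
                 c(rep(list(character()), 12),
                   rep(list("A"), 3), rep(list(c("A", "B")), 3), rep(list("B"), 2)))
  res <- per_family_tests(w, min_windows = 3)
  expect_equal(res$n_windows[res$family == "A"], 6L)
  expect_equal(res$n_windows[res$family == "B"], 5L)
})

test_that("family bias counts use strict inequality against the reference", {
  w <- fam_table(c(0, 0, 10, -10), list(character(), character(), "High", "Low"))
  fb <- family_bias_counts(w)
  expect_equal(fb$n, 2)
  expect_equal(fb$k, 1)  # only "Low" is strictly below the mean of 0
  # a family exactly at the reference is not counted
  w2 <- fam_table(c(-1, 1, 0), list(character(), character(), "Tie"))
  fb2 <- family_bias_counts(w2)
  expect_equal(fb2$reference, 0)
  expect_equal(fb2$k, 0)
  expect_equal(fb2$n, 1)
})

test_that("family bias counts match brute-force recomputation on synthetic data", {
  cfg <- simulation_config(seed = 33, assembly = assembly("c1", 1e6),
                           family_specs = dplyr::bind_rows(
                             te_family("A", "LINE", 10, -1),
                             te_family("B", "LTR", 10, 0),
                             te_family("C", "DNA", 10, -0.5)))
  ds <- simulate_dataset(cfg)
  sc <- compute_pairing_scores(ds$contacts, ds$grid)
  w <- join_pairing(build_window_features(ds$grid, tes = ds$tes), sc)
  fb <- family_bias_counts(w)
  ref <- mean(w$score, na.rm = TRUE)
  k_brute <- 0
  for (fam in c("A", "B", "C")) {
    in_fam <- vapply(w$families, function(f) fam %in% f, logical(1))
    if (mean(w$score[in_fam], na.rm = TRUE) < ref) k_brute <- k_brute + 1
  }
  expect_equal(fb$k, k_brute)
  expect_equal(fb$n, 3)
})

test_that("the exact binomial bias test matches pmf summation and is symmetric", {
  res <- binomial_bias_test(5, 10)
  expect_equal(res$estimate, 0.5)
  expect_equal(res$p_value, 1)
  for (n in c(7, 12, 20)) {
    for (k in 0:n) {
      expect_equal(binomial_bias_test(k, n)$p_value, oracle_binom_p(k, n),
                   tolerance = 1e-12, label = paste0("k=", k, ", n=", n))
      expect_equal(binomial_bias_test(k, n)$p_value,
                   binomial_bias_test(n - k, n)$p_value, tolerance = 1e-12)
    }
  }
  expect_error(binomial_bias_test(11, 10), "k")
  expect_error(binomial_bias_test(0, 0), "n")
})

test_that("trend tests report direction, handle monotone transforms, reject constants", {
  w <- tibble::tibble(score = 1:10, rna_depth = 3 * (1:10) + 2)
  expect_equal(trend_test(w, "rna_depth")$estimate, 1)
  res_ols <- suppressWarnings(trend_test(w, "rna_depth", method = "ols_slope"))
  expect_equal(res_ols$estimate, 1 / 3, tolerance = 1e-12)

  withr::local_seed(37)
  w2 <- tibble::tibble(score = rnorm(40), cov = rexp(40))
  s1 <- trend_test(w2, "cov", method = "spearman")
  w2$cov <- exp(w2$cov)  # monotone transform leaves Spearman untouched
  s2 <- trend_test(w2, "cov", method = "spearman")
  expect_equal(s1$estimate, s2$estimate)
  expect_equal(s1$p_value, s2$p_value)

  w3 <- tibble::tibble(score = rnorm(10), cov = rep(2, 10))
  expect_error(trend_test(w3, "cov"), "zero variance")
})

test_that("independent covariates give small correlations and uniform-ish p", {
  withr::local_seed(43)
  ps <- replicate(100, {
    w <- tibble::tibble(score = rnorm(60), cov = rnorm(60))
    trend_test(w, "cov")$p_value
  })
  expect_gt(mean(ps < 0.05), 0)   # some rejections happen
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps > 0.5), 0.3)  # and the bulk of the p mass is high
})

test_that("genotype class tests compare each class to no-TE with m = classes tested", {
  withr::local_seed(47)
  gt <- function(cls) list(cls)
  w <- tibble::tibble(
    score = c(rnorm(20), rnorm(4) - 2, rnorm(4) - 2, rnorm(4) - 2, rnorm(1)),
    has_te = c(rep(FALSE, 20), rep(TRUE, 13)),
    genotype_classes = c(rep(list(character()), 20),
                         rep(gt("maternal_only"), 4), rep(gt("paternal_only"), 4),
                         rep(gt("both"), 4), gt("unknown")))
  expect_warning(res <- genotype_class_tests(w), "unknown")
  expect_equal(nrow(res), 3)
  expect_equal(res$p_adjusted, pmin(1, 3 * res$p_raw))
  expect_true(all(res$direction == "lower"))
})

test_that("bonferroni is capped arithmetic and agrees with p.adjust", {
  expect_equal(bonferroni(0.01, 24), 0.24)
  expect_equal(bonferroni(c(0.5, 0.9), 2), c(1, 1))
  withr::local_seed(51)
  p <- runif(20)
  expect_equal(bonferroni(p), unname(stats::p.adjust(p, method = "bonferroni")))
  expect_equal(bonferroni(p, 40), pmin(1, 40 * p))
  expect_error(bonferroni(c(0.1, 1.2)), "0, 1")
})
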