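# broom-style tidiers. Result objects are already tibbles, so tidy() mostly
# standardizes column names; glance() gives the one-row model-level summary.

#' @rdname tepair_tidiers
#' @param x A tepair result object.
#' @param ... Unused.
#' @method tidy tepair_comparison
#' @export
tidy.tepair_comparison <- function(x, ...) {
  as_tibble(x) |>
    mutate(estimate = .data$mean1 - .data$mean2) |>
    select(group1 = "group1", group2 = "group2", "estimate", "statistic",
           p.value = "p_value", method = "test", "alternative")
}

#' @rdname tepair_tidiers
#' @method glance tepair_comparison
#' @export
glance.tepair_comparison <- function(x, ...) {
  as_tibble(x)[c("n1", "n2", "statistic", "p_value")]
}

#' Tidiers for tepair results
#'
#' [generics::tidy()] and [generics::glance()] methods for the result objects
#' returned by [compare_groups()], [per_family_tests()],
#' [binomial_bias_test()] and [trend_test()].
#'
#' @name tepair_tidiers
#' @method tidy tepair_family_tests
#' @export
tidy.tepair_family_tests <- function(x, ...) {
  as_tibble(x) |>
    select(term = "family", "te_class", "n_windows", "statistic",
           p.value = "p_raw", p.adjusted = "p_adjusted",
           estimate = "median_score", "direction")
}

#' @rdname tepair_tidiers
#' @method glance tepair_family_tests
#' @export
glance.tepair_family_tests <- function(x, ...) {
  tibble(n_families = nrow(x),
         m = attr(x, "m") %||% nrow(x),
         n_significant = sum(x$p_adjusted < 0.05),
         n_lower = sum(x$direction == "lower"),
         baseline_median = attr(x, "baseline_median") %||% NA_real_)
}

#' @rdname tepair_tidiers
#' @method tidy tepair_bias
#' @export
tidy.tepair_bias <- function(x, ...) {
  as_tibble(x) |>
    select(estimate = "estimate", "k", "n", p.value = "p_value", null.value = "p0")
}

#' @rdname tepair_tidiers
#' @method tidy tepair_trend
#' @export
tidy.tepair_trend <- function(x, ...) {
  as_tibble(x) |>
    select(term = "covariate", "method", "estimate", p.value = "p_value", "n")
}

#' @rdname tepair_tidiers
#' @method glance tepair_run
#' @export
glance.tepair_run <- function(x, ...) {
  tibble(
    n_windows = nrow(x$windows),
    n_scored = sum(!is.na(x$windows$score)),
    n_te_windows = sum(x$windows$has_te),
    n_no_te_windows = sum(!x$windows$has_te),
    n_families_tested = if (!is.null(x$family_tests)) nrow(x$family_tests) else 0L,
    n_families_significant = if (!is.null(x$family_tests)) {
      sum(x$family_tests$p_adjusted < 0.05)
    } else 0L,
    te_comparison_p = if (!is.null(x$te_comparison)) x$te_comparison$p_value else NA_real_,
    bias_estimate = if (!is.null(x$bias)) x$bias$estimate else NA_real_,
    bias_p = if (!is.null(x$bias)) x$bias$p_value else NA_real_
  )
}
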