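# ggplot2 views of the main result types. Kept deliberately plain: these are
# working plots for inspecting a run, not publication figures.

#' Plot a pairing track along the genome
#'
#' @param track A pairing track from [compute_pairing_scores()].
#' @return A ggplot: score against window midpoint, faceted by chromosome.
#' @export
plot_pairing_track <- function(track) {
  df <- as_tibble(track) |> filter(!is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "pairing score (log2)")
}

#' Pairing score distributions for TE vs no-TE windows
#'
#' @param windows Joined windows table (see [join_pairing()]).
#' @return A ggplot of the two score distributions.
#' @export
plot_score_by_te <- function(windows) {
  df <- as_tibble(windows) |> filter(!is.na(.data$score))
  df$group <- ifelse(df$has_te, "TE", "no TE")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "pairing score (log2)")
}

#' Pairing score against a per-window covariate
#'
#' @param windows Joined windows table.
#' @param covariate Covariate column name (e.g. `"rna_depth"`).
#' @return A ggplot scatter with a linear-trend overlay.
#' @export
plot_trend <- function(windows, covariate = "rna_depth") {
  df <- as_tibble(windows) |> filter(!is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[covariate]], y = .data$score)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = covariate, y = "pairing score (log2)")
}

#' @rdname autoplot_tepair
#' @method autoplot tepair_family_tests
#' @export
autoplot.tepair_family_tests <- function(object, ...) {
  df <- as_tibble(object)
  df$family <- factor(df$family, levels = rev(df$family))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adjusted),
                                   y = .data$family,
                                   colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL)
}

#' Autoplot methods for tepair results
#'
#' @param object A tepair result object.
#' @param ... Unused.
#' @name autoplot_tepair
#' @method autoplot tepair_comparison
#' @export
autoplot.tepair_comparison <- function(object, ...) {
  df <- tibble(group = c(object$group1, object$group2),
               median = c(object$median1, object$median2),
               mean = c(object$mean1, object$mean2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::labs(x = NULL, y = "mean pairing score (log2)")
}
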