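#' Specify a TE family for simulation
#'
#' @param family Family name (e.g. `"Baggins1"`).
#' @param te_class One of `"LINE"`, `"LTR"`, `"DNA"`, `"SINE"`, `"Satellite"`.
#' @param n_insertions Number of insertions to place.
#' @param effect Shift, in log2 units, added to the true pairing score of
#'   every window the family overlaps; typically <= 0 (TEs loosen pairing).
#' @return A one-row tibble usable in `family_specs` of [simulation_config()].
#' @export
te_family <- function(family, te_class = c("LINE", "LTR", "DNA", "SINE", "Satellite"),
                      n_insertions, effect = 0) {
  te_class <- match.arg(te_class)
  stopifnot(n_insertions >= 1)
  tibble(family = family, te_class = te_class,
         n_insertions = as.integer(n_insertions), effect = effect)
}

#' Configure a synthetic diploid Hi-C dataset
#'
#' Defines every parameter of the generative model behind
#' [simulate_dataset()]. The model: each window's true pairing score is an
#' independent Normal(baseline_pairing_mean, baseline_pairing_sd) draw on the
#' log2 scale, plus the `effect` of every TE family overlapping the window
#' (each family once, however many of its insertions overlap). The emitted
#' trans-homolog contact frequency of a window is
#' `2 ^ (true score + Normal(0, noise_sd))`. SNP counts are
#' Poisson(snp_mean_per_window) with a fraction of windows forced to zero
#' (the zero-inflation seen in real per-window SNP histograms). RNA read
#' depth increases with the true pairing score, TE-derived read depth is
#' nonzero only in TE windows and increases as pairing is depressed.
#'
#' @param seed Integer seed; identical seed + config give identical output.
#' @param assembly An [assembly()] tibble.
#' @param window_size Window width in bp (default 4000).
#' @param baseline_pairing_mean,baseline_pairing_sd Mean and SD (log2 units)
#'   of the per-window baseline pairing score (defaults 0 and 0.5).
#' @param family_specs Tibble of TE families, one row per family
#'   (see [te_family()]); may be empty.
#' @param te_length_range Min/max insertion length in bp, drawn log-uniform
#'   (default 500–7000, spanning real LINE/LTR scales).
#' @param snp_mean_per_window Poisson mean SNPs per window (default 20).
#' @param snp_zero_window_fraction Fraction of windows forced to zero SNPs
#'   (default 0.1).
#' @param rna_depth_base,rna_depth_slope RNA reads per window: base count and
#'   reads per log2 unit of true pairing (defaults 100 and 30; slope > 0).
#' @param te_depth_base,te_depth_slope TE-derived reads per TE-containing
#'   window: base and slope (defaults 50 and -30; slope < 0 adds depth where
#'   pairing is depressed).
#' @param depth_noise_sd SD of the additive read-depth noise (default 5).
#' @param noise_sd SD (log2 units) of residual contact noise (default 0.3).
#' @param band_halfwidth If > 0, contact signal is additionally emitted at
#'   diagonal offsets 1..b with geometric decay 0.5^offset (default 0: only
#'   the homologous diagonal cell carries signal).
#' @param het_fractions Named numeric: probability an insertion is classed
#'   `maternal_only`, `paternal_only` or `both` (must sum to 1).
#' @return A validated config object (class `tepair_sim_config`).
#' @export
simulation_config <- function(seed = 1L,
                              assembly = tepair::assembly("chrS", 2e6),
                              window_size = 4000,
                              baseline_pairing_mean = 0,
                              baseline_pairing_sd = 0.5,
                              family_specs = NULL,
                              te_length_range = c(500, 7000),
                              snp_mean_per_window = 20,
                              snp_zero_window_fraction = 0.1,
                              rna_depth_base = 100,
                              rna_depth_slope = 30,
                              te_depth_base = 50,
                              te_depth_slope = -30,
                              depth_noise_sd = 5,
                              noise_sd = 0.3,
                              band_halfwidth = 0,
                              het_fractions = c(maternal_only = 0.25,
                                                paternal_only = 0.25,
                                                both = 0.5)) {
  assembly <- as_tibble(assembly)
  if (window_size <= 0) abort("`window_size` must be positive")
  if (window_size > max(assembly$length)) abort("degenerate grid: `window_size` exceeds every chromosome length")
  if (baseline_pairing_sd < 0 || noise_sd < 0 || depth_noise_sd < 0) abort("standard deviations must be nonnegative")
  if (snp_mean_per_window < 0 || rna_depth_base < 0 || te_depth_base < 0) abort("counts and depths must be nonnegative")
  if (snp_zero_window_fraction < 0 || snp_zero_window_fraction > 1) abort("`snp_zero_window_fraction` must be in [0, 1]")
  if (length(te_length_range) != 2 || te_length_range[[1]] <= 0 ||
      te_length_range[[1]] > te_length_range[[2]]) abort("invalid `te_length_range`")
  if (abs(sum(het_fractions) - 1) > 1e-8 || any(het_fractions < 0)) abort("`het_fractions` must be nonnegative and sum to 1")
  stopifnot(all(c("maternal_only", "paternal_only", "both") %in% names(het_fractions)))
  if (is.null(family_specs)) {
    family_specs <- tibble(family = character(), te_class = character(),
                           n_insertions = integer(), effect = numeric())
  }
  family_specs <- as_tibble(family_specs)
  stopifnot(all(c("family", "te_class", "n_insertions", "effect") %in% names(family_specs)))
  if (anyDuplicated(family_specs$family)) abort("family names must be unique")
  structure(list(
    seed = as.integer(seed), assembly = assembly, window_size = window_size,
    baseline_pairing_mean = baseline_pairing_mean,
    baseline_pairing_sd = baseline_pairing_sd,
    family_specs = family_specs, te_length_range = te_length_range,
    snp_mean_per_window = snp_mean_per_window,
    snp_zero_window_fraction = snp_zero_window_fraction,
    rna_depth_base = rna_depth_base, rna_depth_slope = rna_depth_slope,
    te_depth_base = te_depth_base, te_depth_slope = te_depth_slope,
    depth_noise_sd = depth_noise_sd, noise_sd = noise_sd,
    band_halfwidth = as.integer(band_halfwidth), het_fractions = het_fractions
  ), class = "tepair_sim_config")
}

#' Simulate a synthetic diploid dataset with known ground truth
#'
#' Draws one realization of the generative model described in
#' [simulation_config()] and returns every input the analysis pipeline
#' consumes — contact records, TE intervals, SNP calls, RNA and TE-read
#' coverage — together with the ground truth (per-window pre-noise pairing
#' score, per-family effect, per-insertion genotype class) so parameter
#' recovery can be tested.
#'
#' @param config A [simulation_config()].
#' @return A list of class `tepair_dataset`: `grid`, `contacts`, `tes`,
#'   `snps`, `rna_coverage`, `te_coverage`, `truth` (list `windows`,
#'   `families`, `insertions`), and the `config`.
#' @examples
#' cfg <- simulation_config(seed = 7, assembly = assembly("chrS", 2e5),
#'                          noise_sd = 0,
#'                          family_specs = te_family("Baggins1", "LINE", 5, -1))
#' ds <- simulate_dataset(cfg)
#' head(ds$truth$windows)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "tepair_sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  grid <- make_windows(cfg$assembly, cfg$window_size)
  n <- nrow(grid)

  # --- TE insertions: uniform placement, log-uniform lengths ---------------
  fs <- cfg$family_specs
  tes <- if (nrow(fs) > 0) {
    purrr::pmap_dfr(fs, function(family, te_class, n_insertions, effect) {
      len <- round(exp(runif(n_insertions, log(cfg$te_length_range[[1]]),
                             log(cfg$te_length_range[[2]]))))
      chrom_i <- sample.int(nrow(cfg$assembly), n_insertions, replace = TRUE,
                            prob = cfg$assembly$length)
      chrom_len <- cfg$assembly$length[chrom_i]
      len <- pmin(len, chrom_len)
      start <- floor(runif(n_insertions, 0, chrom_len - len + 1))
      tibble(chrom = cfg$assembly$chrom[chrom_i], start = start,
             end = start + len, family = family, te_class = te_class)
    })
  } else {
    tibble(chrom = character(), start = numeric(), end = numeric(),
           family = character(), te_class = character())
  }
  classes <- c("maternal_only", "paternal_only", "both")
  tes$genotype_class <- if (nrow(tes) > 0) {
    sample(classes, nrow(tes), replace = TRUE, prob = cfg$het_fractions[classes])
  } else character()
  tes <- arrange(tes, .data$chrom, .data$start)

  # --- true pairing score: normal baseline + additive family effects ------
  at <- assign_tes(grid, tes)
  effect_of <- setNames(fs$effect, fs$family)
  fam_effect <- vapply(at$families, function(f) sum(effect_of[f]), numeric(1))
  fam_effect[is.na(fam_effect)] <- 0
  baseline <- rnorm(n, cfg$baseline_pairing_mean, cfg$baseline_pairing_sd)
  true_score <- baseline + fam_effect

  # --- contact emission ----------------------------------------------------
  observed <- true_score + rnorm(n, 0, cfg$noise_sd)
  freq <- 2^observed
  contacts <- tibble(chrom_a = grid$chrom, start_a = grid$start,
                     chrom_b = grid$chrom, start_b = grid$start,
                     frequency = freq)
  b <- cfg$band_halfwidth
  if (b > 0) {
    per_chrom_n <- as.integer(table(grid$chrom)[grid$chrom])
    extra <- purrr::map_dfr(seq_len(b), function(o) {
      ok <- grid$index + o <= per_chrom_n - 1L
      tibble(chrom_a = grid$chrom[ok], start_a = grid$start[ok],
             chrom_b = grid$chrom[ok],
             start_b = grid$start[ok] + o * cfg$window_size,
             frequency = freq[ok] * 0.5^o)
    })
    contacts <- bind_rows(contacts, extra)
  }
  contacts <- canonicalize_contacts(contacts)

  # --- SNPs: Poisson counts with a zero-inflated point mass ----------------
  snp_count <- rpois(n, cfg$snp_mean_per_window)
  n_zero <- round(cfg$snp_zero_window_fraction * n)
  if (n_zero > 0) snp_count[sample.int(n, n_zero)] <- 0L
  snp_rows <- which(snp_count > 0)
  snps <- if (length(snp_rows) > 0) {
    reps <- snp_count[snp_rows]
    win_len <- grid$end[snp_rows] - grid$start[snp_rows]
    pos <- rep(grid$start[snp_rows], reps) +
      floor(runif(sum(reps), 0, rep(win_len, reps)))
    bases <- c("A", "C", "G", "T")
    ref_i <- sample.int(4, sum(reps), replace = TRUE)
    alt_i <- (ref_i - 1 + sample.int(3, sum(reps), replace = TRUE)) %% 4 + 1
    tibble(chrom = rep(grid$chrom[snp_rows], reps), pos = pos,
           ref = bases[ref_i], alt = bases[alt_i]) |>
      distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
      arrange(.data$chrom, .data$pos)
  } else {
    tibble(chrom = character(), pos = numeric(), ref = character(), alt = character())
  }

  # --- coverage: RNA coupled positively, TE reads negatively ---------------
  rna <- pmax(0, round(cfg$rna_depth_base + cfg$rna_depth_slope * true_score +
                         rnorm(n, 0, cfg$depth_noise_sd)))
  te_depth <- ifelse(at$has_te,
                     pmax(0, round(cfg$te_depth_base + cfg$te_depth_slope * true_score +
                                     rnorm(n, 0, cfg$depth_noise_sd))),
                     0)
  cov_tbl <- function(count) {
    out <- as_tibble(grid)[c("chrom", "start", "end")]
    out$count <- as.integer(count)
    out
  }

  truth_windows <- as_tibble(grid)
  truth_windows$true_score <- true_score
  truth_windows$families <- at$families

  structure(list(
    grid = grid,
    contacts = contacts,
    tes = tes,
    snps = snps,
    rna_coverage = cov_tbl(rna),
    te_coverage = cov_tbl(te_depth),
    truth = list(windows = truth_windows,
                 families = fs[c("family", "te_class", "effect")],
                 insertions = tes),
    config = cfg
  ), class = "tepair_dataset")
}
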