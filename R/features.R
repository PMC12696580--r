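#' @keywords internal
#' @noRd
grid_granges <- function(grid) {
  GenomicRanges::GRanges(grid$chrom, IRanges::IRanges(start = grid$start + 1, end = grid$end))
}

intervals_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(start = x$start + 1, end = x$end))
}

# Drop features on chromosomes absent from the grid, with a warning tally.
drop_off_grid <- function(x, grid, what = "feature") {
  off <- !(x$chrom %in% unique(grid$chrom))
  if (any(off)) {
    warn(paste0(sum(off), " ", what, "(s) on chromosomes absent from the grid were skipped"))
    x <- x[!off, , drop = FALSE]
  }
  x
}

#' Count features per window
#'
#' Counts how many of the supplied features overlap each window of the grid.
#' A point feature (a SNP) at 0-based position p is counted in exactly the
#' window containing p; an interval is counted once in every window it
#' overlaps by at least 1 bp (`bedtools multicov` semantics). Features on
#' chromosomes not in the grid are skipped with a warning.
#'
#' @param grid A [make_windows()] grid.
#' @param features A tibble with `chrom` plus either `pos` (0-based point) or
#'   `start`/`end` (0-based half-open interval) columns.
#' @return The grid with an added integer `count` column.
#' @export
count_overlaps <- function(grid, features) {
  features <- as_tibble(features)
  if (!"start" %in% names(features)) {
    stopifnot("pos" %in% names(features))
    features$start <- features$pos
    features$end <- features$pos + 1
  }
  features <- drop_off_grid(features, grid)
  out <- as_tibble(grid)
  out$count <- if (nrow(features) == 0) {
    integer(nrow(grid))
  } else {
    GenomicRanges::countOverlaps(grid_granges(grid), intervals_granges(features))
  }
  out
}

#' Assign TE annotations to windows
#'
#' Marks every window a TE overlaps (>= 1 bp) with that TE's family, class and
#' genotype class. A window "contains" a TE under any-overlap semantics; a TE
#' spanning several windows contributes to each, and multiple insertions of
#' one family in one window count the family once (set semantics).
#'
#' @param grid A [make_windows()] grid.
#' @param tes TE intervals: tibble with `chrom`, `start`, `end`, `family`, and
#'   optionally `te_class` and `genotype_class`.
#' @return The grid with list-columns `families`, `te_classes`,
#'   `genotype_classes` (character vectors, possibly empty) and a logical
#'   `has_te`.
#' @export
assign_tes <- function(grid, tes) {
  tes <- as_tibble(tes)
  stopifnot(all(c("chrom", "start", "end", "family") %in% names(tes)))
  if (nrow(tes) > 0 && any(!nzchar(tes$family) | is.na(tes$family))) {
    abort("TE intervals must carry a nonempty family label")
  }
  if (!"te_class" %in% names(tes)) tes$te_class <- "other"
  if (!"genotype_class" %in% names(tes)) tes$genotype_class <- "unknown"
  tes <- drop_off_grid(tes, grid, "TE")
  out <- as_tibble(grid)
  n <- nrow(out)
  fam <- rep(list(character()), n)
  cls <- rep(list(character()), n)
  gen <- rep(list(character()), n)
  if (nrow(tes) > 0) {
    class_of <- setNames(tes$te_class, tes$family)  # first class wins per family
    class_of <- class_of[!duplicated(names(class_of))]
    hits <- GenomicRanges::findOverlaps(grid_granges(grid), intervals_granges(tes))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    fam_hit <- split(tes$family[s], factor(q, levels = seq_len(n)))
    gen_hit <- split(tes$genotype_class[s], factor(q, levels = seq_len(n)))
    fam <- lapply(fam_hit, function(x) sort(unique(x)))
    # aligned with `families`: the class of each family, not a unique set
    cls <- lapply(fam, function(x) unname(class_of[x]))
    gen <- lapply(gen_hit, function(x) sort(unique(x)))
  }
  out$families <- unname(fam)
  out$te_classes <- unname(cls)
  out$genotype_classes <- unname(gen)
  out$has_te <- lengths(out$families) > 0
  out
}

#' Per-family window counts
#'
#' Number of distinct windows each TE family overlaps.
#'
#' @param grid,tes As in [assign_tes()].
#' @return A tibble `family`, `te_class`, `n_windows`.
#' @export
family_window_counts <- function(grid, tes) {
  at <- assign_tes(grid, tes)
  cls <- tes |>
    as_tibble() |>
    mutate(te_class = if ("te_class" %in% names(tes)) .data$te_class else "other") |>
    distinct(.data$family, .data$te_class)
  tibble(family = unlist(at$families)) |>
    count(.data$family, name = "n_windows") |>
    left_join(cls, by = "family") |>
    select("family", "te_class", "n_windows")
}

#' Per-window read counts
#'
#' Either passes through precomputed BED4 window counts (after checking the
#' intervals match the grid exactly) or counts read intervals per window with
#' multicov semantics: a read is counted once in every window it overlaps.
#'
#' @param grid A [make_windows()] grid.
#' @param x Read intervals (`chrom`, `start`, `end`) or precomputed window
#'   counts (`chrom`, `start`, `end`, `count` matching the grid row-for-row
#'   after ordering).
#' @return The grid with an integer `count` column.
#' @export
window_read_counts <- function(grid, x) {
  x <- as_tibble(x)
  if ("count" %in% names(x)) {
    idx <- lookup_window(grid, x$chrom, x$start)
    if (anyNA(idx) || nrow(x) != nrow(grid) || anyDuplicated(idx) ||
        any(x$end != grid$end[idx])) {
      abort("grid mismatch: BED4 windows do not tile the supplied grid")
    }
    out <- as_tibble(grid)
    out$count <- integer(nrow(grid))
    out$count[idx] <- as.integer(x$count)
    return(out)
  }
  count_overlaps(grid, x)
}

#' Classify TE genotype by parental concordance
#'
#' Matches maternal against paternal TE calls of the same family at a
#' reciprocal-overlap threshold: a matched pair is one insertion present in
#' both parental genomes; unmatched calls are heterozygous
#' (maternal-only / paternal-only).
#'
#' @param tes_maternal,tes_paternal TE interval tibbles (`chrom`, `start`,
#'   `end`, `family`, optional `te_class`).
#' @param reciprocal_overlap Minimum fraction of *each* interval covered by
#'   the other for a match (default 0.5).
#' @return One tibble of TE intervals with `genotype_class` set to
#'   `"both"` (maternal coordinates kept), `"maternal_only"` or
#'   `"paternal_only"`.
#' @export
classify_genotype <- function(tes_maternal, tes_paternal, reciprocal_overlap = 0.5) {
  m <- as_tibble(tes_maternal); p <- as_tibble(tes_paternal)
  stopifnot(reciprocal_overlap > 0, reciprocal_overlap <= 1)
  if (!"te_class" %in% names(m)) m$te_class <- "other"
  if (!"te_class" %in% names(p)) p$te_class <- "other"
  matched_m <- logical(nrow(m)); matched_p <- logical(nrow(p))
  if (nrow(m) > 0 && nrow(p) > 0) {
    hits <- GenomicRanges::findOverlaps(intervals_granges(m), intervals_granges(p))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- pmin(m$end[q], p$end[s]) - pmax(m$start[q], p$start[s])
    ok <- m$family[q] == p$family[s] &
      ov >= reciprocal_overlap * (m$end[q] - m$start[q]) &
      ov >= reciprocal_overlap * (p$end[s] - p$start[s])
    matched_m[q[ok]] <- TRUE
    matched_p[s[ok]] <- TRUE
  }
  m$genotype_class <- ifelse(matched_m, "both", "maternal_only")
  p$genotype_class <- "paternal_only"
  bind_rows(m, p[!matched_p, , drop = FALSE]) |>
    select("chrom", "start", "end", "family", "te_class", "genotype_class") |>
    arrange(.data$chrom, .data$start)
}

#' Build the per-window feature table
#'
#' Aggregates TE annotations, SNP calls and RNA / TE-derived read coverage
#' into one row per window of the grid — the table every statistical test in
#' the package consumes (optionally joined with a pairing track via
#' [join_pairing()]).
#'
#' @param grid A [make_windows()] grid.
#' @param tes TE intervals (see [assign_tes()]); optional.
#' @param snps SNP positions: tibble with `chrom`, `pos` (0-based); optional.
#' @param rna_coverage,te_coverage Read intervals or BED4 window counts (see
#'   [window_read_counts()]); optional.
#' @return A tibble, one row per window: grid columns, `snp_count`,
#'   `rna_depth`, `te_depth`, `has_te`, `families`, `te_classes`,
#'   `genotype_classes`.
#' @export
build_window_features <- function(grid, tes = NULL, snps = NULL,
                                  rna_coverage = NULL, te_coverage = NULL) {
  out <- assign_tes(grid, tes %||% tibble(chrom = character(), start = numeric(),
                                          end = numeric(), family = character()))
  out$snp_count <- if (is.null(snps)) 0L else count_overlaps(grid, snps)$count
  out$rna_depth <- if (is.null(rna_coverage)) 0L else window_read_counts(grid, rna_coverage)$count
  out$te_depth <- if (is.null(te_coverage)) 0L else window_read_counts(grid, te_coverage)$count
  out[c("chrom", "index", "start", "end", "window_id", "snp_count", "rna_depth",
        "te_depth", "has_te", "families", "te_classes", "genotype_classes")]
}

#' Join a pairing track onto a window feature table
#'
#' @param features Output of [build_window_features()].
#' @param track Output of [compute_pairing_scores()] on the same grid.
#' @return The feature table with a `score` column.
#' @export
join_pairing <- function(features, track) {
  sc <- as_tibble(track)[c("chrom", "start", "score")]
  out <- left_join(as_tibble(features), sc, by = c("chrom", "start"))
  if (nrow(out) != nrow(features)) abort("pairing track does not match the feature grid")
  out
}
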