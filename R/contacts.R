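#' Read Hi-C contact records
#'
#' Reads trans-homolog (or cis) contact frequencies into the sparse triplet
#' representation used throughout the package: one row per pair of genome bins
#' with a positive contact frequency.
#'
#' Two on-disk layouts are supported:
#' \describe{
#'   \item{`triplet`}{Tab-separated text with five columns
#'     `chrom_a, start_a, chrom_b, start_b, frequency` (bin starts in bp,
#'     0-based). A header line is detected and skipped.}
#'   \item{`dense`}{A whitespace-separated square matrix for a single
#'     chromosome; `chrom` and `resolution` must be supplied (the sidecar
#'     header of the matrix file). Cell (i, j) maps to bin starts
#'     ((i-1) * resolution, (j-1) * resolution).}
#' }
#' Zero-frequency cells are dropped. Symmetric duplicates — the same unordered
#' bin pair appearing as both (a, b) and (b, a) — are collapsed keeping one
#' record in canonical (lower bin first) orientation.
#'
#' @param path Input file path.
#' @param format `"triplet"` (default) or `"dense"`.
#' @param chrom,resolution Required for `format = "dense"`: the chromosome the
#'   matrix describes and its bin width in bp.
#' @return A tibble of contact records: `chrom_a`, `start_a`, `chrom_b`,
#'   `start_b`, `frequency`.
#' @export
read_contacts <- function(path, format = c("triplet", "dense"),
                          chrom = NULL, resolution = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("contact file not found: ", path))
  if (format == "triplet") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      warn(paste0("empty contact file: ", path))
      return(tibble(chrom_a = character(), start_a = numeric(),
                    chrom_b = character(), start_b = numeric(),
                    frequency = numeric()))
    }
    first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    if (length(first) >= 5 && is.na(suppressWarnings(as.numeric(first[[2]])))) {
      lines <- lines[-1]  # header
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 5)
    if (length(bad)) abort(paste0("malformed contact line ", bad[[1]], ": expected 5 fields"))
    rec <- tibble(
      chrom_a = vapply(parts, `[[`, "", 1L),
      start_a = as.numeric(vapply(parts, `[[`, "", 2L)),
      chrom_b = vapply(parts, `[[`, "", 3L),
      start_b = as.numeric(vapply(parts, `[[`, "", 4L)),
      frequency = as.numeric(vapply(parts, `[[`, "", 5L))
    )
    neg <- which(rec$frequency < 0)
    if (length(neg)) abort(paste0("negative contact frequency at line ", neg[[1]]))
  } else {
    if (is.null(chrom) || is.null(resolution)) {
      abort("dense format requires `chrom` and `resolution`")
    }
    m <- as.matrix(utils::read.table(path, header = FALSE, sep = ""))
    if (any(m < 0)) {
      bad <- which(apply(m < 0, 1, any))[[1]]
      abort(paste0("negative contact frequency at line ", bad))
    }
    idx <- which(m != 0, arr.ind = TRUE)
    rec <- tibble(
      chrom_a = chrom,
      start_a = (idx[, "row"] - 1) * resolution,
      chrom_b = chrom,
      start_b = (idx[, "col"] - 1) * resolution,
      frequency = m[idx]
    )
  }
  canonicalize_contacts(rec[rec$frequency > 0, , drop = FALSE])
}

# Canonical orientation (chrom_a, start_a) <= (chrom_b, start_b); collapse
# symmetric duplicates keeping the first occurrence.
canonicalize_contacts <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0) return(records)
  flip <- records$chrom_a > records$chrom_b |
    (records$chrom_a == records$chrom_b & records$start_a > records$start_b)
  if (any(flip)) {
    tmp_c <- records$chrom_a[flip]; tmp_s <- records$start_a[flip]
    records$chrom_a[flip] <- records$chrom_b[flip]
    records$start_a[flip] <- records$start_b[flip]
    records$chrom_b[flip] <- tmp_c
    records$start_b[flip] <- tmp_s
  }
  records[!duplicated(records[c("chrom_a", "start_a", "chrom_b", "start_b")]), , drop = FALSE]
}

#' Re-bin contact records to a coarser resolution
#'
#' Sums contact frequencies of fine bins into the window-pair cells of a
#' coarser grid, so matrices published at a finer resolution can feed a wider
#' window grid. The window size must be an integer multiple of the source
#' resolution.
#'
#' @param records Contact-record tibble (see [read_contacts()]).
#' @param resolution Source bin width in bp.
#' @param window_size Target bin width in bp; `window_size / resolution` must
#'   be a whole number.
#' @return Contact records re-binned at `window_size`, frequencies summed
#'   within each coarse cell, canonical orientation.
#' @export
aggregate_bins <- function(records, resolution, window_size) {
  k <- window_size / resolution
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    abort("incompatible binning: `window_size` must be an integer multiple of `resolution`")
  }
  records <- as_tibble(records)
  if (nrow(records) == 0) return(records)
  records |>
    mutate(start_a = floor(.data$start_a / window_size) * window_size,
           start_b = floor(.data$start_b / window_size) * window_size) |>
    canonicalize_contacts_sum()
}

# Like canonicalize_contacts() but sums frequencies of coinciding cells
# (needed after re-binning, where distinct fine cells legitimately merge).
canonicalize_contacts_sum <- function(records) {
  flip <- records$chrom_a > records$chrom_b |
    (records$chrom_a == records$chrom_b & records$start_a > records$start_b)
  if (any(flip)) {
    tmp_c <- records$chrom_a[flip]; tmp_s <- records$start_a[flip]
    records$chrom_a[flip] <- records$chrom_b[flip]
    records$start_a[flip] <- records$start_b[flip]
    records$chrom_b[flip] <- tmp_c
    records$start_b[flip] <- tmp_s
  }
  records |>
    group_by(.data$chrom_a, .data$start_a, .data$chrom_b, .data$start_b) |>
    summarise(frequency = sum(.data$frequency), .groups = "drop")
}

#' Compute per-window pairing scores
#'
#' The pairing score of a window is the log2 of the average trans-homolog
#' contact frequency observed for that window: higher scores mean tighter
#' physical pairing of the two homologs. By default the average is taken over
#' the single homologous cell of the window (the diagonal cell pairing the
#' window with itself on the homologous chromosome). With
#' `band_halfwidth = b > 0` the average additionally runs over the cells at
#' offsets 1..b on either side along the same chromosome; cells inside the
#' band that carry no record count as zero frequency, while cells that fall
#' off the chromosome end are excluded from the support.
#'
#' Windows whose averaged contact mass is zero get a missing (`NA`) score
#' rather than -Inf, and are excluded from downstream tests; supply a positive
#' `pseudocount` to force a finite score everywhere.
#'
#' @param records Contact-record tibble; bin starts must be multiples of the
#'   grid's window size (use [aggregate_bins()] first for finer matrices).
#' @param grid A [make_windows()] grid.
#' @param band_halfwidth Integer >= 0; half-width, in windows, of the diagonal
#'   band averaged per window. Default 0 (homologous cell only).
#' @param pseudocount Nonnegative value added to the mean frequency before
#'   taking log2. Default 0.
#' @return A pairing track: the grid columns plus `n_cells` (band support) and
#'   `score` (log2 units, `NA` where undefined).
#' @examples
#' g <- make_windows(assembly("chrA", 12000), 4000)
#' rec <- tibble::tibble(chrom_a = "chrA", start_a = c(0, 4000, 8000),
#'                       chrom_b = "chrA", start_b = c(0, 4000, 8000),
#'                       frequency = c(1, 4, 2))
#' compute_pairing_scores(rec, g)$score  # log2 of each diagonal frequency
#' @export
compute_pairing_scores <- function(records, grid, band_halfwidth = 0, pseudocount = 0) {
  stopifnot(band_halfwidth >= 0, pseudocount >= 0)
  ws <- window_size_of(grid)
  records <- canonicalize_contacts(as_tibble(records))
  if (nrow(records) > 0) {
    if (any(records$start_a %% ws != 0 | records$start_b %% ws != 0)) {
      abort("incompatible binning: record bin starts are not multiples of the window size (re-bin with aggregate_bins())")
    }
    unknown <- setdiff(unique(c(records$chrom_a, records$chrom_b)), unique(grid$chrom))
    if (length(unknown)) {
      abort(paste0("unknown chromosome in contact records: ", paste(unknown, collapse = ", ")))
    }
  }
  b <- as.integer(band_halfwidth)

  n_win <- nrow(grid)
  mass <- numeric(n_win)
  # records within the band: same chromosome, |offset| <= b
  if (nrow(records) > 0) {
    same <- records$chrom_a == records$chrom_b
    off <- (records$start_b - records$start_a) / ws
    keep <- same & off <= b
    ra <- records[keep, , drop = FALSE]
    off <- off[keep]
    ia <- lookup_window(grid, ra$chrom_a, ra$start_a)
    ib <- lookup_window(grid, ra$chrom_b, ra$start_b)
    ok <- !is.na(ia) & !is.na(ib)
    ia <- ia[ok]; ib <- ib[ok]; fr <- ra$frequency[ok]; off <- off[ok]
    # cell (w, w+o) contributes to window w; for o > 0 also to window w+o
    mass <- mass + as.numeric(tapply(c(fr, fr[off > 0]),
                                     factor(c(ia, ib[off > 0]), levels = seq_len(n_win)),
                                     sum, default = 0))
  }
  # band support per window: offsets -b..b clipped to the chromosome
  per_chrom_n <- table(grid$chrom)[grid$chrom]
  n_cells <- pmin(b, grid$index) + pmin(b, as.integer(per_chrom_n) - 1L - grid$index) + 1L
  mean_freq <- mass / n_cells
  score <- ifelse(mean_freq + pseudocount > 0, log2(mean_freq + pseudocount), NA_real_)
  out <- as_tibble(grid)
  out$n_cells <- n_cells
  out$score <- score
  class(out) <- c("tepair_track", class(out))
  out
}

#' Write a pairing track as bedGraph
#'
#' Missing-score windows are omitted, per the bedGraph convention.
#'
#' @param track A pairing track from [compute_pairing_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  def <- track[!is.na(track$score), c("chrom", "start", "end", "score")]
  readr::write_tsv(def, path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph pairing track onto a window grid
#'
#' @param path bedGraph file (chrom, start, end, score; no header).
#' @param grid The window grid the track was computed on.
#' @return A pairing track tibble; windows absent from the file get `NA`.
#' @export
read_bedgraph <- function(path, grid) {
  bg <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "score"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  idx <- lookup_window(grid, bg$chrom, bg$start)
  if (anyNA(idx)) abort("bedGraph interval does not match the window grid")
  out <- as_tibble(grid)
  out$score <- NA_real_
  out$score[idx] <- bg$score
  class(out) <- c("tepair_track", class(out))
  out
}
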