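#' Define a genome assembly
#'
#' An assembly is the ordered set of chromosomes (or scaffolds) the analysis
#' runs over, with their lengths in base pairs. All downstream coordinates are
#' 0-based half-open on these chromosomes.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp, all positive.
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' assembly(c("chr2L", "chr2R"), c(23011544, 21146708))
#' @export
assembly <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    abort("`chrom` and `length` must have the same length.")
  }
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("chromosome lengths must be positive")
  }
  tibble(chrom = chrom, length = length)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a tab- or space-separated file with chromosome name and
#'   length per line (the UCSC `chrom.sizes` convention).
#' @return An [assembly()] tibble.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "", col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  assembly(df$chrom, df$length)
}

#' Partition an assembly into fixed-size windows
#'
#' Tiles every chromosome with consecutive `window_size`-bp windows, 0-based
#' half-open, starting at 0. The last window of a chromosome is truncated at
#' the chromosome end, so window lengths always sum exactly to the chromosome
#' length. Window width is chosen to match the resolution of the contact data
#' (4 kb for the fly pairing-score track, 40 kb mouse, 32 kb yeast).
#'
#' @param assembly An [assembly()] tibble (or anything with `chrom`/`length`).
#' @param window_size Window width in bp, > 0.
#' @return A tibble with one row per window: `chrom`, `index` (0-based within
#'   chromosome), `start`, `end`, and a global 1-based `window_id`. Carries the
#'   window size and assembly as attributes; class `tepair_grid`.
#' @examples
#' make_windows(assembly("chrA", 10000), 4000)
#' @export
make_windows <- function(assembly, window_size) {
  assembly <- as_tibble(assembly)
  stopifnot(all(c("chrom", "length") %in% names(assembly)))
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size <= 0) {
    abort("`window_size` must be a single positive number.")
  }
  grid <- purrr::pmap_dfr(assembly, function(chrom, length) {
    n <- ceiling(length / window_size)
    start <- (seq_len(n) - 1) * window_size
    tibble(chrom = chrom, index = seq_len(n) - 1L,
           start = start, end = pmin(start + window_size, length))
  })
  grid$window_id <- seq_len(nrow(grid))
  attr(grid, "window_size") <- window_size
  attr(grid, "assembly") <- assembly
  class(grid) <- c("tepair_grid", class(grid))
  grid
}

window_size_of <- function(grid) {
  ws <- attr(grid, "window_size")
  if (is.null(ws)) ws <- max(grid$end - grid$start)
  ws
}

assembly_of <- function(grid) {
  asm <- attr(grid, "assembly")
  if (is.null(asm)) {
    asm <- grid |>
      group_by(.data$chrom) |>
      summarise(length = max(.data$end), .groups = "drop")
  }
  asm
}

# Map (chrom, bin start) pairs to global window ids; NA where off-grid.
lookup_window <- function(grid, chrom, start) {
  key <- paste0(grid$chrom, ":", grid$start)
  match(paste0(chrom, ":", start), key)
}
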