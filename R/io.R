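# Plain-text readers/writers for the small formats the pipeline exchanges.
# All genomic coordinates inside the package are 0-based half-open; VCF
# positions are converted (1-based -> 0-based) on read and back on write.

te_class_codes <- c(LINE = 1L, LTR = 2L, DNA = 3L, SINE = 4L, Satellite = 5L)

#' Read TE intervals from BED
#'
#' Accepts BED3 (intervals only, family set to `"unknown"`) or BED6 where the
#' name column carries the family and the score column an integer TE-class
#' code (1 LINE, 2 LTR, 3 DNA, 4 SINE, 5 Satellite, anything else "other").
#'
#' @param path BED file path.
#' @return TE interval tibble: `chrom`, `start`, `end`, `family`, `te_class`.
#' @export
read_te_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", colClasses = "character")
  out <- tibble(chrom = df[[1]], start = as.numeric(df[[2]]), end = as.numeric(df[[3]]))
  if (ncol(df) >= 4) out$family <- df[[4]] else out$family <- "unknown"
  if (ncol(df) >= 5) {
    code <- suppressWarnings(as.integer(df[[5]]))
    cls <- names(te_class_codes)[match(code, te_class_codes)]
    out$te_class <- ifelse(is.na(cls), "other", cls)
  } else {
    out$te_class <- "other"
  }
  if (any(out$start >= out$end)) abort("invalid BED interval: start >= end")
  out
}

write_te_bed <- function(tes, path) {
  code <- te_class_codes[tes$te_class]
  code[is.na(code)] <- 0L
  readr::write_tsv(tibble(tes$chrom, format(tes$start, scientific = FALSE, trim = TRUE),
                          format(tes$end, scientific = FALSE, trim = TRUE),
                          tes$family, code, "."),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read SNPs from a VCF
#'
#' Minimal VCF 4.2 reader for SNP density work: keeps rows whose REF and ALT
#' are single bases, skips indels/other records with a tally, and converts
#' POS to 0-based.
#'
#' @param path VCF file path (uncompressed).
#' @return Tibble `chrom`, `pos` (0-based), `ref`, `alt`.
#' @export
read_snp_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), pos = numeric(), ref = character(), alt = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 8)) abort("malformed VCF record: fewer than 8 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  pos <- as.numeric(vapply(parts, `[[`, "", 2L))
  ref <- vapply(parts, `[[`, "", 4L)
  alt <- vapply(parts, `[[`, "", 5L)
  snp <- nchar(ref) == 1 & nchar(alt) == 1 & alt != "."
  if (any(!snp)) inform(paste0(sum(!snp), " non-SNP VCF record(s) skipped"))
  tibble(chrom = chrom[snp], pos = pos[snp] - 1, ref = ref[snp], alt = alt[snp])
}

write_snp_vcf <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps) > 0) {
    writeLines(paste(snps$chrom, format(snps$pos + 1, scientific = FALSE, trim = TRUE),
                     ".", snps$ref, snps$alt, ".", "PASS", ".", sep = "\t"), con)
  }
  invisible(path)
}

#' Read BED4 window coverage
#'
#' @param path BED4 file: chrom, start, end, integer count; no header.
#' @return Tibble `chrom`, `start`, `end`, `count`.
#' @export
read_bed4 <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "count"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  as_tibble(df)
}

write_bed4 <- function(grid, counts, path) {
  readr::write_tsv(tibble(grid$chrom, format(grid$start, scientific = FALSE, trim = TRUE),
                          format(grid$end, scientific = FALSE, trim = TRUE), counts),
                   path, col_names = FALSE)
  invisible(path)
}

write_contacts <- function(records, path) {
  readr::write_tsv(
    tibble(records$chrom_a, format(records$start_a, scientific = FALSE, trim = TRUE),
           records$chrom_b, format(records$start_b, scientific = FALSE, trim = TRUE),
           records$frequency),
    path, col_names = FALSE)
  invisible(path)
}

write_chrom_sizes <- function(assembly, path) {
  readr::write_tsv(tibble(assembly$chrom,
                          format(assembly$length, scientific = FALSE, trim = TRUE)),
                   path, col_names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Emits the plain-text artifacts a real study would supply: sparse contact
#' triplets, TE BED6, SNP VCF, RNA and TE-read BED4 coverage, chrom.sizes,
#' and the simulation ground truth (per-window true score and per-family
#' effect), so the pipeline can be exercised end-to-end from files.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    contacts = file.path(dir, "contacts.tsv"),
    tes = file.path(dir, "tes.bed"),
    snps = file.path(dir, "snps.vcf"),
    rna_coverage = file.path(dir, "rna_coverage.bed4"),
    te_coverage = file.path(dir, "te_coverage.bed4"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    truth_windows = file.path(dir, "truth_windows.tsv"),
    truth_families = file.path(dir, "truth_families.tsv")
  )
  write_contacts(dataset$contacts, paths[["contacts"]])
  write_te_bed(dataset$tes, paths[["tes"]])
  write_snp_vcf(dataset$snps, paths[["snps"]])
  write_bed4(dataset$grid, dataset$rna_coverage$count, paths[["rna_coverage"]])
  write_bed4(dataset$grid, dataset$te_coverage$count, paths[["te_coverage"]])
  write_chrom_sizes(assembly_of(dataset$grid), paths[["chrom_sizes"]])
  tw <- dataset$truth$windows
  readr::write_tsv(tibble(chrom = tw$chrom, start = tw$start, end = tw$end,
                          true_score = tw$true_score), paths[["truth_windows"]])
  readr::write_tsv(dataset$truth$families, paths[["truth_families"]])
  invisible(paths)
}
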