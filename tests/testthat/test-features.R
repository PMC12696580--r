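test_that("make_windows tiles chromosomes with a truncated final window", {
  g <- make_windows(assembly("c1", 12000), 4000)
  expect_equal(nrow(g), 3)
  g <- make_windows(assembly("c1", 10000), 4000)
  expect_equal(g$start, c(0, 4000, 8000))
  expect_equal(g$end, c(4000, 8000, 10000))
  g <- make_windows(assembly(c("c1", "c2"), c(9000, 5000)), 4000)
  expect_equal(nrow(g), 5)
  # lengths sum exactly to the chromosome lengths, no gaps or overlaps
  sums <- tapply(g$end - g$start, g$chrom, sum)
  expect_equal(as.vector(sums[c("c1", "c2")]), c(9000, 5000))
  expect_true(all(g$start == g$index * 4000))
})

test_that("points are counted in the single window containing them", {
  g <- make_windows(assembly("c1", 12000), 4000)
  cnt <- count_overlaps(g, tibble::tibble(chrom = "c1", pos = 4000))$count
  expect_equal(cnt, c(0, 1, 0))  # half-open: position 4000 is in window 1
  cnt <- count_overlaps(g, tibble::tibble(chrom = "c1", pos = 3999))$count
  expect_equal(cnt, c(1, 0, 0))
})

test_that("intervals are counted in every window they overlap by >= 1 bp", {
  g <- make_windows(assembly("c1", 12000), 4000)
  cnt <- count_overlaps(g, tibble::tibble(chrom = "c1", start = 3999, end = 4001))$count
  expect_equal(cnt, c(1, 1, 0))
})

test_that("features off the grid chromosomes are skipped with a warning", {
  g <- make_windows(assembly("c1", 12000), 4000)
  expect_warning(
    cnt <- count_overlaps(g, tibble::tibble(chrom = c("c1", "cX"), pos = c(0, 0)))$count,
    "skipped")
  expect_equal(sum(cnt), 1)
})

test_that("random interval counts match the per-base oracle", {
  withr::local_seed(21)
  g <- make_windows(assembly(c("c1", "c2"), c(60000, 40000)), 4000)
  for (rep in 1:3) {
    n_f <- 120
    chrom <- sample(c("c1", "c2"), n_f, replace = TRUE)
    len <- sample(50:9000, n_f, replace = TRUE)
    maxlen <- ifelse(chrom == "c1", 60000, 40000)
    start <- floor(runif(n_f, 0, maxlen - len))
    feats <- tibble::tibble(chrom = chrom, start = start, end = start + len)
    expect_equal(count_overlaps(g, feats)$count, oracle_overlap_counts(g, feats))
  }
})

test_that("assign_tes marks every overlapped window with set semantics", {
  g <- make_windows(assembly("c1", 16000), 4000)
  tes <- tibble::tibble(chrom = "c1", start = c(2000, 500, 900),
                        end = c(9000, 700, 1100),
                        family = c("A", "B", "B"), te_class = c("LINE", "LTR", "LTR"))
  at <- assign_tes(g, tes)
  expect_equal(at$families, list(c("A", "B"), "A", "A", character()))
  expect_equal(at$has_te, c(TRUE, TRUE, TRUE, FALSE))
  # two same-family insertions in window 0 count the family once
  expect_equal(at$te_classes[[1]], c("LINE", "LTR"))
  fw <- family_window_counts(g, tes)
  expect_equal(fw$n_windows[fw$family == "A"], 3L)
  expect_equal(fw$n_windows[fw$family == "B"], 1L)
})

test_that("per-family window counts agree with brute force on random placements", {
  withr::local_seed(31)
  g <- make_windows(assembly("c1", 80000), 4000)
  len <- sample(200:7000, 60, replace = TRUE)
  start <- floor(runif(60, 0, 80000 - len))
  tes <- tibble::tibble(chrom = "c1", start = start, end = start + len,
                        family = sample(c("F1", "F2", "F3"), 60, replace = TRUE))
  fw <- family_window_counts(g, tes)
  for (fam in c("F1", "F2", "F3")) {
    counts <- oracle_overlap_counts(g, tes[tes$family == fam, ])
    expect_equal(fw$n_windows[fw$family == fam], sum(counts > 0),
                 label = fam)
  }
})

test_that("read counting follows multicov semantics", {
  g <- make_windows(assembly("c1", 16000), 4000)
  reads <- tibble::tibble(chrom = "c1", start = c(8100, 3900), end = c(8200, 4100))
  cnt <- window_read_counts(g, reads)$count
  expect_equal(cnt, c(1, 1, 1, 0))  # boundary-spanning read counted twice
  withr::local_seed(13)
  len <- sample(30:400, 500, replace = TRUE)
  start <- floor(runif(500, 0, 16000 - len))
  reads <- tibble::tibble(chrom = "c1", start = start, end = start + len)
  expect_equal(window_read_counts(g, reads)$count, oracle_overlap_counts(g, reads))
})

test_that("BED4 coverage passes through only when it matches the grid", {
  g <- make_windows(assembly("c1", 12000), 4000)
  bed4 <- tibble::tibble(chrom = "c1", start = c(0, 4000, 8000),
                         end = c(4000, 8000, 12000), count = c(5, 0, 2))
  expect_equal(window_read_counts(g, bed4)$count, c(5, 0, 2))
  expect_error(window_read_counts(g, bed4[-2, ]), "grid mismatch")
  bad <- bed4; bad$start[2] <- 4100
  expect_error(window_read_counts(g, bad), "grid mismatch")
})

test_that("genotype classification applies the reciprocal-overlap rule", {
  m <- tibble::tibble(chrom = "c1", start = c(100, 5000), end = c(600, 5600),
                      family = c("A", "A"), te_class = "LINE")
  p <- tibble::tibble(chrom = "c1", start = 100, end = 600,
                      family = "A", te_class = "LINE")
  res <- classify_genotype(m, p)
  expect_equal(res$genotype_class[res$start == 100], "both")
  expect_equal(res$genotype_class[res$start == 5000], "maternal_only")
  expect_equal(nrow(res), 2)  # matched paternal call not re-emitted

  # 60% reciprocal overlap: both at threshold 0.5, two het calls at 0.9
  m2 <- tibble::tibble(chrom = "c1", start = 0, end = 1000, family = "A")
  p2 <- tibble::tibble(chrom = "c1", start = 400, end = 1400, family = "A")
  expect_equal(classify_genotype(m2, p2, 0.5)$genotype_class, "both")
  expect_setequal(classify_genotype(m2, p2, 0.9)$genotype_class,
                  c("maternal_only", "paternal_only"))
  # family identity is required even at full overlap
  p3 <- tibble::tibble(chrom = "c1", start = 0, end = 1000, family = "B")
  expect_setequal(classify_genotype(m2, p3, 0.5)$genotype_class,
                  c("maternal_only", "paternal_only"))
})

test_that("the feature table preserves totals and the TE partition", {
  withr::local_seed(17)
  cfg <- simulation_config(seed = 17, assembly = assembly("c1", 2e5),
                           family_specs = te_family("A", "LINE", 6, -1))
  ds <- simulate_dataset(cfg)
  ft <- build_window_features(ds$grid, tes = ds$tes, snps = ds$snps,
                              rna_coverage = ds$rna_coverage,
                              te_coverage = ds$te_coverage)
  expect_equal(nrow(ft), nrow(ds$grid))
  expect_equal(sum(ft$snp_count), nrow(ds$snps))
  expect_identical(ft$has_te, lengths(ft$families) > 0)
  expect_equal(sum(ft$has_te) + sum(!ft$has_te), nrow(ft))
  expect_equal(ft$rna_depth, ds$rna_coverage$count)
})

test_that("VCF and BED round-trips preserve coordinates and family labels", {
  snps <- tibble::tibble(chrom = "c1", pos = c(0, 3999, 4000),
                         ref = c("A", "C", "G"), alt = c("T", "G", "A"))
  f <- withr::local_tempfile(fileext = ".vcf")
  tepair:::write_snp_vcf(snps, f)
  expect_equal(read_snp_vcf(f), snps)

  tes <- tibble::tibble(chrom = "c1", start = c(10, 500), end = c(200, 5500),
                        family = c("FamA", "FamB"), te_class = c("LINE", "Satellite"))
  fb <- withr::local_tempfile(fileext = ".bed")
  tepair:::write_te_bed(tes, fb)
  expect_equal(read_te_bed(fb), tes)
})
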