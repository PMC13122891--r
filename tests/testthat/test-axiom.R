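test_that("genotype matrices read sorted, with duplicates rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    marker_id = c("m3", "m1", "m2"),
    chrom = "chr1", pos = c(300, 100, 200),
    FN1 = c("A/A", "T/T", "---"), FN2 = c("A/A", "T/T", "G/G")
  ), f)
  m <- read_genotype_matrix(f)
  expect_equal(m$marker_id, c("m1", "m2", "m3"))
  expect_equal(m$pos, c(100, 200, 300))
  expect_equal(attr(m, "line_ids"), c("FN1", "FN2"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    marker_id = c("m1", "m1"), chrom = "chr1", pos = c(100, 200),
    FN1 = "A/A"), f2)
  expect_error(read_genotype_matrix(f2), "duplicate")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    marker_id = c("m1", "m2"), chrom = "chr1", pos = c(100, NA),
    FN1 = "A/A"), f3)
  expect_error(read_genotype_matrix(f3), "position")
})

test_that("markers heterozygous in every line are filtered", {
  m <- marker_matrix_from_calls(list(
    FN1 = c("A/G", "A/A", "T/G"),
    FN2 = c("A/G", "A/A", "T/T"),
    FN3 = c("A/G", "A/G", "T/T")
  ))
  flt <- filter_fixed_heterozygotes(m)
  expect_equal(flt$removed$marker_id, "MK-0001")   # het in all three
  expect_equal(nrow(flt$matrix), 2)                # het in some lines: kept
})

test_that("null runs are assembled with the marker screen's rules", {
  m <- marker_matrix_from_calls(list(
    FN1 = c("A/A", "---", "---", "---", "A/A"),
    FN2 = rep("A/A", 5)
  ))
  calls <- null_runs(m, "FN1")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$n_null, 3L)
  expect_equal(calls$n_interruptions, 0L)
  expect_equal(c(calls$start, calls$end), c(2000, 4000))
  expect_equal(nrow(null_runs(m, "FN2")), 0)
  expect_error(null_runs(m, "FN9"), "unknown line")
})

test_that("a single valid call does not break a null run", {
  m <- marker_matrix_from_calls(list(
    FN1 = c("---", "---", "A/G", "---", "---"),
    FN2 = rep("A/A", 5)
  ))
  calls <- null_runs(m, "FN1")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$n_null, 4L)
  expect_equal(calls$n_interruptions, 1L)

  zero_tol <- null_runs(m, "FN1", interruption_tolerance = 0, min_run = 2,
                        merge_gap_markers = 0)
  expect_equal(nrow(zero_tol), 2)
})

test_that("isolated nulls are annotations, not calls", {
  m <- marker_matrix_from_calls(list(
    FN1 = c("A/A", "---", "A/A", "A/A", "A/A", "A/A", "A/A"),
    FN2 = rep("A/A", 7)
  ))
  calls <- null_runs(m, "FN1")
  expect_equal(nrow(calls), 0)
  iso <- attr(calls, "isolated_nulls")
  expect_equal(iso$marker_id, "MK-0002")
})

test_that("nearby candidates merge by marker distance, never across chromosomes", {
  calls_vec <- c(rep("---", 3), rep("A/A", 3), rep("---", 3), rep("A/A", 11))
  m <- marker_matrix_from_calls(list(FN1 = calls_vec,
                                     FN2 = rep("A/A", 20)))
  merged <- null_runs(m, "FN1", merge_gap_markers = 5)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_null, 6L)
  expect_equal(merged$n_components, 2L)
  split_runs <- null_runs(m, "FN1", merge_gap_markers = 2)
  expect_equal(nrow(split_runs), 2)

  # same layout but the second block on another chromosome
  m2 <- marker_matrix_from_calls(
    list(FN1 = c(rep("---", 3), rep("---", 3), rep("A/A", 14)),
         FN2 = rep("A/A", 20)),
    chrom = c(rep("chr1", 3), rep("chr2", 17)))
  cross <- null_runs(m2, "FN1", merge_gap_markers = 5)
  expect_equal(nrow(cross), 2)
  expect_equal(sort(cross$chrom), c("chr1", "chr2"))
})

test_that("candidate scoring uses the isolated-null rate", {
  calls_vec <- rep("A/A", 100)
  calls_vec[10:14] <- "---"     # one real-looking run of 5
  calls_vec[c(40, 60)] <- "---" # two stray nulls
  m <- marker_matrix_from_calls(list(FN1 = calls_vec, FN2 = rep("A/A", 100)))
  calls <- null_runs(m, "FN1")
  p <- 2 / 95
  expect_equal(calls$p_hat, p)
  expect_equal(calls$E, 100 * p^5 * (1 - p)^2)
  expect_equal(calls$sig_tags[[1]], c(0.05, 0.01))
})

test_that("interrupting markers are classified for reliability", {
  m <- marker_matrix_from_calls(list(
    FN1 = c("---", "---", "T/G", "---", "A/A", "---", "G/G", "---", "---"),
    FN2 = c("A/A", "A/A", "T/T", "C/C", "A/A", "G/G", "T/T", "A/A", "C/C"),
    FN3 = c("A/A", "A/A", "T/T", "C/C", "A/A", "G/G", "T/T", "A/A", "C/C")
  ))
  calls <- null_runs(m, "FN1", interruption_tolerance = 1,
                     merge_gap_markers = 1)
  ann <- classify_interruptions(m, calls)
  intr <- dplyr::bind_rows(ann$interruptions)
  expect_equal(intr$reliability[intr$call == "T/G"], "line_specific_het")
  expect_equal(intr$reliability[intr$call == "A/A"], "valid")
  expect_equal(intr$reliability[intr$call == "G/G"], "inconsistent")
})

test_that("heterozygous interruptions shared with other lines stay valid", {
  m <- marker_matrix_from_calls(list(
    FN1 = c("---", "---", "T/G", "---", "---"),
    FN2 = c("A/A", "A/A", "T/G", "C/C", "A/A"),
    FN3 = c("A/A", "A/A", "T/G", "C/C", "A/A"),
    FN4 = c("A/A", "A/A", "T/T", "C/C", "A/A")
  ))
  ann <- classify_interruptions(m, null_runs(m, "FN1"))
  expect_equal(ann$interruptions[[1]]$reliability, "valid")
  expect_false(ann$likely_contiguous[1])

  strict <- classify_interruptions(m, null_runs(m, "FN1"), max_other_het = 2)
  expect_equal(strict$interruptions[[1]]$reliability, "line_specific_het")
  expect_true(strict$likely_contiguous[1])
})

test_that("a clean matrix yields no candidates and a deleted block yields one", {
  gen <- make_genome(c(chr1 = 1e7), window_size = 1e4)
  clean <- simulate_marker_calls(gen, NULL, line_ids = c("A", "B"),
                                 n_markers = 800, null_rate = 0,
                                 het_rate = 0, fixed_het_fraction = 0.01,
                                 seed = 3)
  res <- call_axiom(clean)
  expect_equal(nrow(res$calls), 0)

  tr <- tibble::tibble(line_id = "A", chrom = "chr1", start = 3e6, end = 5e6,
                       size = 2e6, kind = "hom_del", copy_factor = 0)
  mm <- simulate_marker_calls(gen, tr, line_ids = c("A", "B"),
                              n_markers = 800, null_rate = 0.005,
                              het_rate = 0.005, fixed_het_fraction = 0.01,
                              seed = 4)
  res2 <- call_axiom(mm)
  hit <- res2$calls[res2$calls$line_id == "A" & res2$calls$E <= 0.01, ]
  expect_equal(nrow(hit), 1)
  expect_lt(abs(hit$start - 3e6), 1e5)
  expect_lt(abs(hit$end - 5e6), 1e5)
})
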