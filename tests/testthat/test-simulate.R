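gen50 <- make_genome(c(chr1 = 3e7, chr2 = 2e7), window_size = 1e4)

test_that("implanted events respect bounds, kinds and non-overlap", {
  tr <- implant_events(gen50, n_lines = 8, events_per_line = 4,
                       min_size = 3e4, max_size = 2e6, seed = 2)
  expect_equal(nrow(tr), 32)
  lens <- attr(gen50, "chrom_lengths")
  expect_true(all(tr$start >= 0 & tr$end <= lens[tr$chrom]))
  expect_true(all(tr$size >= 3e4 & tr$size <= 2e6))
  expect_true(all(tr$copy_factor[tr$kind == "hom_del"] == 0))
  expect_true(all(tr$copy_factor[tr$kind == "hemi_del"] == 0.5))
  expect_true(all(tr$copy_factor[tr$kind == "dup"] >= 2))
  # no two events of one line overlap on the same chromosome
  clash <- tr |>
    dplyr::group_by(line_id, chrom) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(bad = dplyr::n() > 1 && any(start[-1] < cummax(end)[-dplyr::n()]),
                     .groups = "drop")
  expect_false(any(clash$bad))
})

test_that("degenerate size laws and empty truth sets work", {
  expect_equal(nrow(implant_events(gen50, 3, events_per_line = 0, seed = 1)), 0)
  tr <- implant_events(gen50, 2, events_per_line = 3, min_size = 5e4,
                       max_size = 5e4, seed = 1)
  expect_true(all(tr$size == 5e4))
  expect_error(implant_events(gen50, 1, 1, min_size = 5e3), "window")
})

test_that("sizes follow the truncated reciprocal law", {
  set.seed(7)
  s <- skimcnv:::sample_sizes(10000, 3e4, 3e6, exponent = 1)
  # inverse-CDF oracle: F(x) = log(x/min) / log(max/min)
  ks <- suppressWarnings(
    ks.test(s, function(x) log(x / 3e4) / log(3e6 / 3e4)))
  expect_gt(ks$p.value, 0.01)
  # counts in fixed-width size bins fall off with log-log slope about -1
  breaks <- seq(3e4, 3e6, by = 5e4)
  mids <- head(breaks, -1) + 2.5e4
  counts <- as.numeric(table(cut(s, breaks)))
  keep <- counts >= 10
  fit <- lm(log10(counts[keep]) ~ log10(mids[keep]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.1)
})

test_that("depth simulation follows the Poisson copy-number model", {
  gen <- make_genome(c(chr1 = 1e8), window_size = 1e4)
  d0 <- simulate_depth(gen, NULL, n_lines = 1, mean_depth = 67, seed = 9)
  expect_true(all(d0$count >= 0 & d0$count == floor(d0$count)))
  expect_lt(abs(mean(d0$count) - 67), 3 * sqrt(67 / 1e4))

  # one homozygous and one hemizygous deletion, each spanning 500 windows
  tr <- tibble::tibble(
    line_id = "line_001",
    chrom = "chr1",
    start = c(10e6, 50e6), end = c(15e6, 55e6),
    size = c(5e6, 5e6),
    kind = c("hom_del", "hemi_del"),
    copy_factor = c(0, 0.5)
  )
  d <- simulate_depth(gen, tr, line_ids = "line_001", mean_depth = 67,
                      seed = 10)
  hom <- d$count[d$start >= 10e6 & d$end <= 15e6]
  expect_true(all(hom == 0))
  hemi <- d$count[d$start >= 50e6 & d$end <= 55e6]
  expect_equal(mean(hemi), 33.5, tolerance = 3 * sqrt(33.5 / 500) / 33.5)

  d_again <- simulate_depth(gen, tr, line_ids = "line_001", mean_depth = 67,
                            seed = 10)
  expect_identical(d$count, d_again$count)
})

test_that("duplicated spans double the expected depth and partial overlap blends", {
  gen <- make_genome(c(chr1 = 2e7), window_size = 1e4)
  tr <- tibble::tibble(line_id = "line_001", chrom = "chr1",
                       start = 5e6, end = 10e6, size = 5e6,
                       kind = "dup", copy_factor = 2)
  d <- simulate_depth(gen, tr, line_ids = "line_001", mean_depth = 67,
                      seed = 4)
  dup <- d$count[d$start >= 5e6 & d$end <= 10e6]
  expect_equal(mean(dup), 134, tolerance = 3 * sqrt(134 / 500) / 134)

  # event covering exactly half of one window: factor (1-q) + q*cf = 0.5
  tr2 <- tibble::tibble(line_id = "line_001", chrom = "chr1",
                        start = 0, end = 5e3, size = 5e3,
                        kind = "hom_del", copy_factor = 0)
  f <- skimcnv:::copy_factor_profile(gen, tr2, "line_001")
  expect_equal(f[1], 0.5)
  expect_equal(f[2], 1)
})

test_that("marker simulation scores deletions as runs of null calls", {
  gen <- make_genome(c(chr1 = 1e7), window_size = 1e4)
  tr <- tibble::tibble(line_id = c("A", "B"), chrom = "chr1",
                       start = c(2e6, 4e6), end = c(4e6, 5e6),
                       size = c(2e6, 1e6),
                       kind = c("hom_del", "hemi_del"),
                       copy_factor = c(0, 0.5))
  mm <- simulate_marker_calls(gen, tr, line_ids = c("A", "B"),
                              n_markers = 500, null_rate = 0,
                              het_rate = 0, fixed_het_fraction = 0, seed = 5)
  inside <- mm$pos >= 2e6 & mm$pos < 4e6
  expect_true(all(mm$A[inside] == "---"))          # hom_del: certain nulls
  expect_true(all(mm$A[!inside] != "---"))         # no noise channel
  expect_true(all(mm$B != "---"))                  # hemi_del stays callable
  # the null block is consecutive in marker order
  null_idx <- which(mm$A == "---")
  expect_equal(null_idx, seq(min(null_idx), max(null_idx)))
  expect_true(!is.unsorted(mm$pos))
})

test_that("null and heterozygous noise rates match their binomials", {
  gen <- make_genome(c(chr1 = 5e7), window_size = 1e4)
  mm <- simulate_marker_calls(gen, NULL, line_ids = "A", n_markers = 20000,
                              null_rate = 0.01, het_rate = 0,
                              fixed_het_fraction = 0, seed = 6)
  n_null <- sum(mm$A == "---")
  expect_lt(abs(n_null - 200), 3 * sqrt(20000 * 0.01 * 0.99))

  mm2 <- simulate_marker_calls(gen, NULL, line_ids = c("A", "B"),
                               n_markers = 20000, null_rate = 0,
                               het_rate = 0, fixed_het_fraction = 0.02,
                               seed = 7)
  flt <- filter_fixed_heterozygotes(mm2)
  frac <- nrow(flt$removed) / 20000
  expect_lt(abs(frac - 0.02), 3 * sqrt(0.02 * 0.98 / 20000))
})

test_that("every null call is attributed in the ledger", {
  gen <- make_genome(c(chr1 = 1e7), window_size = 1e4)
  tr <- tibble::tibble(line_id = "A", chrom = "chr1", start = 2e6, end = 3e6,
                       size = 1e6, kind = "hom_del", copy_factor = 0)
  mm <- simulate_marker_calls(gen, tr, line_ids = c("A", "B"),
                              n_markers = 1000, null_rate = 0.02,
                              het_rate = 0.01, fixed_het_fraction = 0,
                              seed = 8)
  ledger <- attr(mm, "null_ledger")
  for (lid in c("A", "B")) {
    nulls <- mm$marker_id[mm[[lid]] == "---"]
    expect_setequal(nulls, ledger$marker_id[ledger$line_id == lid])
  }
  led_a <- ledger[ledger$line_id == "A", ]
  pos_a <- mm$pos[match(led_a$marker_id, mm$marker_id)]
  expect_true(all((led_a$cause == "deletion") == (pos_a >= 2e6 & pos_a < 3e6)))
  expect_true(all(ledger$cause[ledger$line_id == "B"] == "noise"))
})
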