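test_that("the three depth classes flag by their printed rules", {
  tr <- toy_track(c(1, 0.5, 0.75, 2, 0.65, 1.999, 0.7))
  hom <- flag_windows(tr$depth, tr$stats, "hom_del")
  hemi <- flag_windows(tr$depth, tr$stats, "hemi_del")
  dup <- flag_windows(tr$depth, tr$stats, "dup")

  expect_false(any(hom$flag[1], hemi$flag[1], dup$flag[1]))  # x = mu
  expect_true(hemi$flag[2])                 # x = mu/2, distance zero
  expect_false(hemi$flag[3])                # tie at 3mu/4 is not "closer"
  expect_true(dup$flag[4])                  # x = 2mu, boundary inclusive
  expect_false(dup$flag[6])                 # just under twice the mean
  expect_true(hom$flag[5])                  # 0.65 < 1 - 3*0.1
  expect_false(hom$flag[7])                 # 0.7 is not < 0.7
  expect_error(flag_windows(tr$depth, tr$stats, "inversion"))
})

test_that("masked windows are never flagged", {
  tr <- toy_track(c(0, 0, 1, 1), masked = c(TRUE, FALSE, FALSE, FALSE))
  hom <- flag_windows(tr$depth, tr$stats, "hom_del")
  expect_false(hom$flag[1])
  expect_true(hom$flag[2])
})

test_that("calls are scored with the expected chance-run count", {
  vals <- rep(1, 20)
  vals[c(5, 6, 7, 15)] <- 0.5
  tr <- toy_track(vals)
  calls <- call_cnv(tr$depth, tr$stats, "hemi_del")
  calls <- calls[order(calls$start), ]
  expect_equal(nrow(calls), 2)
  expect_equal(calls$n_windows, c(3L, 1L))
  expect_equal(calls$start, c(4e4, 14e4))
  expect_equal(calls$end, c(7e4, 15e4))
  # no run reaches 0.05, so p stays at the raw rate 4/20
  p <- 4 / 20
  expect_equal(calls$p_hat, c(p, p))
  expect_equal(calls$E, 20 * p^c(3, 1) * (1 - p)^2)
  expect_true(all(lengths(calls$sig_tags) == 0))
})

test_that("p is re-estimated once after provisional acceptance", {
  vals <- rep(1, 100)
  vals[40:49] <- 0.5
  vals[c(70, 80)] <- 0.5
  tr <- toy_track(vals)
  calls <- call_cnv(tr$depth, tr$stats, "hemi_del")
  calls <- calls[order(calls$start), ]
  expect_equal(nrow(calls), 3)
  # provisional p = 12/100 accepts the 10-run; refit excludes its 10 windows
  p1 <- 2 / 90
  expect_equal(unique(calls$p_hat), p1)
  expect_equal(calls$E, 100 * p1^c(10, 1, 1) * (1 - p1)^2)
  expect_equal(calls$sig_tags[[1]], c(0.05, 0.01))
  expect_true(all(lengths(calls$sig_tags[-1]) == 0))
})

test_that("runs never join across chromosomes", {
  gen <- make_genome(c(a = 3e4, b = 3e4), window_size = 1e4)
  depth <- as_skim_depth(tibble::tibble(
    line_id = "L1", chrom = gen$chrom, start = gen$start, end = gen$end,
    depth = c(1, 0.5, 0.5, 0.5, 0.5, 1)
  ), gen, state = "normalized")
  stats <- tibble::tibble(chrom = gen$chrom, start = gen$start, end = gen$end,
                          partial = FALSE, mu = 1, sigma = 0.1, masked = FALSE)
  calls <- call_cnv(depth, stats, "hemi_del")
  expect_equal(nrow(calls), 2)
  expect_equal(sort(calls$chrom), c("a", "b"))
  expect_true(all(calls$n_windows == 2))
})

test_that("nearby same-line calls merge transitively with min-E evidence", {
  base <- tibble::tibble(
    line_id = "L1", chrom = "chr1", mode = "hom_del",
    start = c(0, 1e5, 4e5), end = c(5e4, 2e5, 5e5),
    n_windows = c(5L, 10L, 10L), n_interruptions = 0L,
    p_hat = 0.01, E = c(1e-3, 1e-6, 1e-4),
    sig_tags = list(c(0.05, 0.01), c(0.05, 0.01), c(0.05, 0.01))
  )
  m <- merge_nearby(toy_calls(base), max_gap_bp = 2e5)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 5e5))
  expect_equal(m$n_components, 3L)
  expect_equal(m$E, 1e-6)
  expect_equal(nrow(m$components[[1]]), 3)

  far <- merge_nearby(toy_calls(base), max_gap_bp = 4e4)
  expect_equal(nrow(far), 3)
  expect_true(all(far$n_components == 1))

  two <- toy_calls(base[1:2, ])
  expect_equal(nrow(merge_nearby(two, max_gap_bp = 2e5)), 1)
  expect_equal(nrow(merge_nearby(two, max_gap_bp = 4e4)), 2)
})

test_that("a significance gate keeps weak calls out of merging", {
  base <- tibble::tibble(
    line_id = "L1", chrom = "chr1", mode = "hemi_del",
    start = c(0, 1e5), end = c(5e4, 2e5),
    n_windows = c(5L, 1L), n_interruptions = 0L,
    p_hat = 0.02, E = c(1e-4, 2.5),
    sig_tags = list(c(0.05, 0.01), numeric(0))
  )
  m <- merge_nearby(toy_calls(base), max_gap_bp = 2e5, min_sig = 0.05)
  expect_equal(nrow(m), 2)
  expect_equal(sort(m$n_components), c(1L, 1L))
  m2 <- merge_nearby(toy_calls(base), max_gap_bp = 2e5)
  expect_equal(nrow(m2), 1)
})

test_that("homozygous calls are associated with containing hemizygous spans", {
  hom <- toy_calls(tibble::tibble(
    line_id = c("L1", "L1", "L2"), chrom = "chr1", mode = "hom_del",
    start = c(1e5, 3e6, 1e5), end = c(2e5, 3.1e6, 2e5),
    n_windows = 10L, n_interruptions = 0L, p_hat = 0.01, E = 1e-4,
    sig_tags = list(numeric(0), numeric(0), numeric(0))))
  hemi <- toy_calls(tibble::tibble(
    line_id = "L1", chrom = "chr1", mode = "hemi_del",
    start = 0, end = 1e6,
    n_windows = 100L, n_interruptions = 0L, p_hat = 0.02, E = 1e-10,
    sig_tags = list(c(0.05, 0.01))))
  ann <- hom_within_hemi(hom, hemi)
  expect_equal(ann$within_hemi[1], hemi$call_id[1])
  expect_true(is.na(ann$within_hemi[2]))  # disjoint
  expect_true(is.na(ann$within_hemi[3]))  # other line

  # partial overlap: containment fraction against the 50% rule
  hom2 <- toy_calls(tibble::tibble(
    line_id = "L1", chrom = "chr1", mode = "hom_del",
    start = c(9.4e5, 9.9e5), end = c(1.04e6, 1.09e6),
    n_windows = 10L, n_interruptions = 0L, p_hat = 0.01, E = 1e-4,
    sig_tags = list(numeric(0), numeric(0))))
  ann2 <- hom_within_hemi(hom2, hemi)
  expect_equal(ann2$within_hemi[1], hemi$call_id[1])  # 60% contained
  expect_true(is.na(ann2$within_hemi[2]))             # 10% contained
})

test_that("unique deletions collapse by reciprocal overlap", {
  sib <- toy_calls(tibble::tibble(
    line_id = c("L1", "L2", "L3", "L4", "L5"), chrom = "chr1",
    mode = "hom_del",
    start = c(1e5, 1e5, 1.1e5, 5e6, 8e6),
    end = c(2e5, 2e5, 2.1e5, 5.1e6, 8.1e6),
    n_windows = 10L, n_interruptions = 0L, p_hat = 0.01,
    E = c(1e-4, 1e-5, 1e-3, 1e-4, 1e-4),
    sig_tags = list(numeric(0), numeric(0), numeric(0), numeric(0),
                    numeric(0))))
  spect <- unique_deletions(sib, genome_bp = 1e7)
  expect_equal(spect$n_unique, 3)
  expect_equal(spect$unique_deleted_bp, 1.1e5 + 1e5 + 1e5)
  expect_equal(spect$genome_fraction, spect$unique_deleted_bp / 1e7)
  reps <- spect$representatives
  expect_equal(reps$n_lines[reps$start == 1e5][1], 3)

  # order independence and idempotence of the collapse
  shuffled <- unique_deletions(sib[c(4, 2, 5, 1, 3), ], genome_bp = 1e7)
  expect_equal(glance(shuffled), glance(spect))

  again <- unique_deletions(toy_calls(dplyr::mutate(
    spect$representatives[, c("chrom", "start", "end", "E")],
    line_id = "rep", mode = "hom_del", n_windows = 1L,
    n_interruptions = 0L, p_hat = 0.01,
    sig_tags = list(numeric(0)))), genome_bp = 1e7)
  expect_equal(again$n_unique, spect$n_unique)
  expect_equal(again$unique_deleted_bp, sum(again$representatives$size))
})

test_that("deletion size bins carry a reciprocal reference curve", {
  sizes <- c(3e4, 3e4, 3e4, 6e4, 6e4, 1.2e5)
  calls <- toy_calls(tibble::tibble(
    line_id = paste0("L", 1:6), chrom = "chr1", mode = "hom_del",
    start = seq(0, by = 1e6, length.out = 6),
    end = seq(0, by = 1e6, length.out = 6) + sizes,
    n_windows = 3L, n_interruptions = 0L, p_hat = 0.01, E = 1e-4,
    sig_tags = rep(list(numeric(0)), 6)))
  spect <- unique_deletions(calls, genome_bp = 1e7)
  expect_equal(sum(spect$bins$count), spect$n_unique)
  expect_equal(spect$bins$count[spect$bins$size_class == 3e4], 3)
  expect_true(all(diff(spect$bins$reciprocal_curve) < 0))
})

test_that("duplication spacing counts gaps around the 1 Mb threshold", {
  single <- toy_calls(tibble::tibble(
    line_id = "L1", chrom = "chr1", mode = "dup",
    start = 0, end = 1e4, n_windows = 1L, n_interruptions = 0L,
    p_hat = 0.001, E = 1e-4, sig_tags = list(numeric(0))))
  expect_equal(duplication_spacing(single)$n_gaps, 0)

  dups <- toy_calls(tibble::tibble(
    line_id = "L1", chrom = "chr1", mode = "dup",
    start = c(0, 1.01e6, 1.5e6), end = c(1e4, 1.02e6, 1.6e6),
    n_windows = 1L, n_interruptions = 0L, p_hat = 0.001, E = 1e-4,
    sig_tags = rep(list(numeric(0)), 3)))
  sp <- duplication_spacing(dups)
  expect_equal(sp$n_gaps, 2)
  expect_equal(sort(sp$gaps$gap), c(4.8e5, 1e6))
  expect_equal(sp$n_at_or_above, 1)  # exactly 1.0 Mb counts as >= 1 Mb
  expect_equal(sp$n_below, 1)
  # merging at 1 Mb would fuse the fragments into one call
  expect_equal(sp$merge_profile$n_calls[sp$merge_profile$max_gap_bp == 1e6], 1)
})

test_that("single-window depth dips convert to a sub-window size estimate", {
  # a 1.4-fold depth reduction in one 10 kb window
  expect_equal(subwindow_deletion_bp(1 / 1.4, 1, 1e4), 1e4 * (1 - 1 / 1.4))
  expect_equal(round(subwindow_deletion_bp(1 / 1.4, 1, 1e4)), 2857)
  expect_equal(subwindow_deletion_bp(1, 1, 1e4), 0)
})
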