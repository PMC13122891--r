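# Independent run-enumeration oracle: a literal state-machine reading of the
# run definition (maximal flagged groups, internal gaps <= tol bridged,
# masked positions transparent). Kept deliberately different in structure
# from the vectorized implementation it checks.
oracle_runs <- function(flags, tol = 1, masked = rep(FALSE, length(flags))) {
  runs <- list()
  cur <- NULL
  gap <- 0
  for (i in seq_along(flags)) {
    if (masked[i]) next
    if (flags[i]) {
      if (is.null(cur)) {
        cur <- list(first = i, last = i, n = 1L, intr = 0L)
      } else {
        cur$intr <- cur$intr + gap
        cur$n <- cur$n + 1L
        cur$last <- i
      }
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (!is.null(cur) && gap > tol) {
        runs[[length(runs) + 1]] <- cur
        cur <- NULL
        gap <- 0
      }
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  if (length(runs) == 0) {
    return(tibble::tibble(first = integer(), last = integer(),
                          n_flagged = integer(), n_interruptions = integer()))
  }
  tibble::tibble(
    first = vapply(runs, function(r) as.integer(r$first), integer(1)),
    last = vapply(runs, function(r) as.integer(r$last), integer(1)),
    n_flagged = vapply(runs, function(r) r$n, integer(1)),
    n_interruptions = vapply(runs, function(r) r$intr, integer(1))
  )
}

# Depth table on a single chromosome from a lines x windows count matrix.
depth_from_matrix <- function(mat, window_size = 1e4, chrom_name = "chr1") {
  genome <- make_genome(stats::setNames(ncol(mat) * window_size, chrom_name),
                        window_size = window_size)
  df <- purrr::map_dfr(seq_len(nrow(mat)), function(i) {
    tibble::tibble(
      line_id = sprintf("L%02d", i),
      chrom = chrom_name,
      start = (seq_len(ncol(mat)) - 1) * window_size,
      end = seq_len(ncol(mat)) * window_size,
      count = mat[i, ]
    )
  })
  list(depth = as_skim_depth(df, genome, state = "raw"), genome = genome)
}

# Wide marker matrix from a list of per-line call vectors.
marker_matrix_from_calls <- function(calls, chrom = NULL, pos = NULL) {
  n <- length(calls[[1]])
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  out <- dplyr::bind_cols(
    tibble::tibble(marker_id = sprintf("MK-%04d", seq_len(n)),
                   chrom = chrom, pos = pos),
    tibble::as_tibble(calls)
  )
  structure(out, class = unique(c("marker_matrix", class(out))),
            line_ids = names(calls))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built normalized single-line depth over a known grid, with
# hand-built cross-line stats.
toy_track <- function(values, mu = 1, sigma = 0.1, masked = NULL,
                      window_size = 1e4) {
  n <- length(values)
  gen <- make_genome(c(chr1 = n * window_size), window_size = window_size)
  depth <- as_skim_depth(tibble::tibble(
    line_id = "L1", chrom = "chr1",
    start = gen$start, end = gen$end, depth = values
  ), gen, state = "normalized")
  stats <- tibble::tibble(
    chrom = "chr1", start = gen$start, end = gen$end, partial = FALSE,
    mu = rep(mu, n), sigma = rep(sigma, n),
    masked = masked %||% rep(FALSE, n)
  )
  list(depth = depth, stats = stats)
}

# A cnv_calls tibble from a plain data frame of call fields.
toy_calls <- function(df, alpha_levels = c(0.05, 0.01)) {
  df <- dplyr::mutate(df,
    call_id = sprintf("%s:%s:%.0f-%.0f:%s", line_id, chrom, start, end, mode))
  structure(tibble::as_tibble(df),
            class = unique(c("cnv_calls", class(tibble::tibble()))),
            alpha_levels = alpha_levels)
}

# Breakpoint agreement in window units: both boundaries of a call within
# one window of the truth boundary's containing window.
breakpoints_within <- function(call_start, call_end, truth_start, truth_end,
                               w, tol = 1) {
  abs(call_start / w - floor(truth_start / w)) <= tol &
    abs(call_end / w - ceiling(truth_end / w)) <= tol
}
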