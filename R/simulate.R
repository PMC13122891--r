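#' Sample event sizes from a truncated reciprocal (power) law
#'
#' Deletion frequency in fast-neutron populations declines approximately as
#' the reciprocal of deletion size, so sizes are drawn from a density
#' proportional to `size^-exponent`, truncated to `[min_size, max_size]`,
#' by inverse-CDF sampling.
#'
#' @param n Number of draws.
#' @param min_size,max_size Truncation bounds in bp.
#' @param exponent Power-law exponent (1 = reciprocal law).
#' @return Numeric vector of sizes (bp, not rounded).
#' @keywords internal
sample_sizes <- function(n, min_size, max_size, exponent = 1) {
  stopifnot(min_size > 0, max_size >= min_size, exponent >= 0)
  if (min_size == max_size) return(rep(min_size, n))
  u <- stats::runif(n)
  if (abs(exponent - 1) < 1e-12) {
    min_size * (max_size / min_size)^u
  } else {
    a <- 1 - exponent
    (min_size^a + u * (max_size^a - min_size^a))^(1 / a)
  }
}

#' Implant a truth set of deletions and duplications
#'
#' Draws copy-number events for each line: sizes from a truncated reciprocal
#' size law (`frequency ~ size^-size_exponent`), positions uniform over the
#' genome, kinds from `zygosity_mix`. Events within a line are rejected and
#' redrawn if they overlap a previously placed event on the same chromosome.
#' The returned truth table is the ground truth that recovery tests compare
#' calls against.
#'
#' @param genome A `genome_windows` grid from [make_genome()].
#' @param n_lines Number of mutant lines.
#' @param events_per_line Events implanted per line.
#' @param min_size,max_size Event size bounds in bp; `min_size` must be at
#'   least one window, `max_size` at most the longest chromosome.
#' @param zygosity_mix Named probabilities over `hom_del`, `hemi_del`, `dup`.
#' @param size_exponent Power-law exponent of the size law (default 1,
#'   the reciprocal law).
#' @param dup_copy Copy factor assigned to duplications (default 2).
#' @param seed Optional integer seed.
#' @param max_tries Placement retries per event before declaring the packing
#'   infeasible.
#' @return Tibble with columns `line_id`, `chrom`, `start`, `end`, `size`,
#'   `kind`, `copy_factor`; attribute `size_exponent`.
#' @export
implant_events <- function(genome, n_lines, events_per_line,
                           min_size = 3e4, max_size = NULL,
                           zygosity_mix = c(hom_del = 0.4, hemi_del = 0.4,
                                            dup = 0.2),
                           size_exponent = 1, dup_copy = 2, seed = NULL,
                           max_tries = 200) {
  lens <- attr(genome, "chrom_lengths")
  w <- genome_window_size(genome)
  if (is.null(max_size)) max_size <- max(lens)
  if (min_size < w) stop("min_size must be at least one window")
  if (max_size > max(lens)) stop("max_size exceeds the longest chromosome")
  kinds <- c("hom_del", "hemi_del", "dup")
  if (!all(names(zygosity_mix) %in% kinds)) stop("unknown kind in zygosity_mix")
  mix <- zygosity_mix / sum(zygosity_mix)

  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }

  line_ids <- sprintf("line_%03d", seq_len(n_lines))
  cf <- c(hom_del = 0, hemi_del = 0.5, dup = dup_copy)

  events <- purrr::map_dfr(line_ids, function(lid) {
    placed <- list()
    for (k in seq_len(events_per_line)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        size <- round(sample_sizes(1, min_size, max_size, size_exponent))
        feasible <- names(lens)[lens >= size]
        if (length(feasible) == 0) next
        chrom <- sample(feasible, 1, prob = lens[feasible])
        start <- floor(stats::runif(1, 0, lens[[chrom]] - size + 1))
        end <- start + size
        clash <- any(vapply(placed, function(e) {
          e$chrom == chrom && e$start < end && start < e$end
        }, logical(1)))
        if (!clash) {
          kind <- sample(names(mix), 1, prob = mix)
          placed[[k]] <- list(chrom = chrom, start = start, end = end,
                              kind = kind)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("infeasible packing: could not place event ", k,
                    " for ", lid, " after ", max_tries, " tries")
    }
    if (length(placed) == 0) return(tibble::tibble())
    tibble::tibble(
      line_id = lid,
      chrom = purrr::map_chr(placed, "chrom"),
      start = purrr::map_dbl(placed, "start"),
      end = purrr::map_dbl(placed, "end"),
      kind = purrr::map_chr(placed, "kind")
    )
  })
  if (nrow(events) == 0) {
    events <- tibble::tibble(line_id = character(), chrom = character(),
                             start = double(), end = double(),
                             kind = character())
  }
  out <- dplyr::mutate(events,
    size = .data$end - .data$start,
    copy_factor = unname(cf[.data$kind])
  )
  out <- dplyr::select(out, "line_id", "chrom", "start", "end", "size",
                       "kind", "copy_factor")
  structure(out, size_exponent = size_exponent, line_ids = line_ids)
}

#' Simulate per-window read counts over a truth set
#'
#' Produces the raw windowed read-count tracks a ~1x skim-sequencing run would
#' yield: for line j and window i the count is Poisson with rate
#' `mean_depth * mappability_i * f_ij * width_i / window_size`, where `f_ij`
#' is the effective copy factor of the window (1 outside events; inside an
#' event the factor blends proportionally with the overlapped fraction, so a
#' window half covered by a homozygous deletion has factor 0.5). `mean_depth`
#' is the expected reads per full window at copy number two.
#'
#' @param genome A `genome_windows` grid.
#' @param truth Truth table from [implant_events()] (may have zero rows).
#' @param n_lines Number of lines to simulate; defaults to the lines recorded
#'   in the truth set.
#' @param line_ids Explicit line identifiers (overrides `n_lines`).
#' @param mean_depth Expected reads per full window at copy number 2.
#' @param seed Optional integer seed.
#' @return A long tibble of class `skim_depth` with columns `line_id`,
#'   `chrom`, `start`, `end`, `width`, `partial`, `count`; attribute
#'   `state = "raw"`.
#' @export
simulate_depth <- function(genome, truth = NULL, n_lines = NULL,
                           line_ids = NULL, mean_depth = 67, seed = NULL) {
  stopifnot(mean_depth > 0)
  if (is.null(line_ids)) {
    if (!is.null(attr(truth, "line_ids"))) {
      line_ids <- attr(truth, "line_ids")
    } else if (!is.null(n_lines)) {
      line_ids <- sprintf("line_%03d", seq_len(n_lines))
    } else if (!is.null(truth) && nrow(truth) > 0) {
      line_ids <- unique(truth$line_id)
    } else {
      stop("give line_ids or n_lines when the truth set carries no lines")
    }
  }
  if (!is.null(n_lines) && length(line_ids) > n_lines) {
    line_ids <- line_ids[seq_len(n_lines)]
  }
  check_truth_on_genome(genome, truth)

  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }

  w <- genome_window_size(genome)
  base_rate <- mean_depth * genome$mappability * genome$width / w

  out <- purrr::map_dfr(line_ids, function(lid) {
    f <- copy_factor_profile(genome, truth, lid)
    tibble::tibble(
      line_id = lid,
      chrom = genome$chrom,
      start = genome$start,
      end = genome$end,
      width = genome$width,
      partial = genome$partial,
      count = stats::rpois(nrow(genome), base_rate * f)
    )
  })
  new_skim_depth(out, state = "raw", genome = genome, line_ids = line_ids)
}

# Effective copy factor per window for one line: 1 - sum_e q_e * (1 - cf_e)
# with q_e the fraction of the window overlapped by event e.
copy_factor_profile <- function(genome, truth, line_id) {
  f <- rep(1, nrow(genome))
  if (is.null(truth) || nrow(truth) == 0) return(f)
  ev <- truth[truth$line_id == line_id, , drop = FALSE]
  if (nrow(ev) == 0) return(f)
  for (k in seq_len(nrow(ev))) {
    idx <- which(genome$chrom == ev$chrom[k] &
                 genome$start < ev$end[k] & genome$end > ev$start[k])
    if (length(idx) == 0) next
    q <- (pmin(genome$end[idx], ev$end[k]) -
          pmax(genome$start[idx], ev$start[k])) / genome$width[idx]
    f[idx] <- f[idx] - q * (1 - ev$copy_factor[k])
  }
  pmax(f, 0)
}

check_truth_on_genome <- function(genome, truth) {
  if (is.null(truth) || nrow(truth) == 0) return(invisible(TRUE))
  lens <- attr(genome, "chrom_lengths")
  bad <- !(truth$chrom %in% names(lens)) | truth$start < 0 |
    truth$end > lens[truth$chrom] | truth$start >= truth$end
  if (any(bad)) {
    stop("truth event off the genome: ", truth$chrom[which(bad)[1]], ":",
         truth$start[which(bad)[1]], "-", truth$end[which(bad)[1]])
  }
  invisible(TRUE)
}

new_skim_depth <- function(x, state, genome = NULL, line_ids = NULL,
                           window_size = NULL, chrom_lengths = NULL) {
  structure(
    x,
    class = unique(c("skim_depth", class(tibble::as_tibble(x)))),
    state = state,
    window_size = window_size %||% genome_window_size(genome),
    chrom_lengths = chrom_lengths %||% attr(genome, "chrom_lengths"),
    line_ids = line_ids %||% unique(x$line_id)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an SNP-array genotype call matrix
#'
#' Places `n_markers` array markers uniformly over the genome and scores each
#' line: markers inside a homozygous deletion score `"---"` (a null call —
#' both assay channels dark) with certainty; markers on intact sequence score
#' the line's homozygous base call, but fail to `"---"` with probability
#' `null_rate` or are mis-scored heterozygous with probability `het_rate`.
#' Markers inside hemizygous deletions or duplications still yield a valid
#' call (one intact homologue is enough signal). A fraction `fixed_het_fraction`
#' of markers is heterozygous in every line, emulating array features that
#' match neither progenitor allele exactly.
#'
#' @param genome A `genome_windows` grid.
#' @param truth Truth table from [implant_events()] (may be `NULL`).
#' @param line_ids Line identifiers to score; defaults to the truth set's.
#' @param n_markers Number of markers.
#' @param null_rate Probability an intact marker scores `"---"`.
#' @param het_rate Probability an intact marker is mis-scored heterozygous.
#' @param fixed_het_fraction Fraction of markers heterozygous in all lines.
#' @param seed Optional integer seed.
#' @return A tibble of class `marker_matrix`: columns `marker_id`, `chrom`,
#'   `pos` (0-based bp) and one call column per line. Attribute `null_ledger`
#'   attributes every `"---"` to `"deletion"` or `"noise"`.
#' @export
simulate_marker_calls <- function(genome, truth = NULL, line_ids = NULL,
                                  n_markers = 2000, null_rate = 0.005,
                                  het_rate = 0.005, fixed_het_fraction = 0.02,
                                  seed = NULL) {
  stopifnot(n_markers > 0, null_rate >= 0, null_rate < 1,
            het_rate >= 0, het_rate < 1,
            fixed_het_fraction >= 0, fixed_het_fraction < 1)
  if (is.null(line_ids)) {
    line_ids <- attr(truth, "line_ids") %||% unique(truth$line_id)
    if (is.null(line_ids) || length(line_ids) == 0) {
      stop("give line_ids when the truth set carries no lines")
    }
  }
  check_truth_on_genome(genome, truth)

  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }

  lens <- attr(genome, "chrom_lengths")
  cum <- cumsum(as.numeric(lens))
  u <- sort(stats::runif(n_markers, 0, sum(lens)))
  ci <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
  pos <- floor(u - c(0, cum)[ci])
  mk <- tibble::tibble(chrom = names(lens)[ci], pos = pos)
  mk <- dplyr::arrange(mk, match(.data$chrom, names(lens)), .data$pos)
  mk$marker_id <- sprintf("MK-%06d", seq_len(n_markers))

  alleles <- c("A", "C", "G", "T")
  base <- sample(alleles, n_markers, replace = TRUE)
  fixed_het <- stats::runif(n_markers) < fixed_het_fraction
  alt <- vapply(base, function(a) sample(setdiff(alleles, a), 1), character(1))
  base_call <- ifelse(fixed_het, paste0(base, "/", alt), paste0(base, "/", base))

  ledger <- list()
  calls <- purrr::map(line_ids, function(lid) {
    cl <- base_call
    deleted <- rep(FALSE, n_markers)
    if (!is.null(truth) && nrow(truth) > 0) {
      ev <- truth[truth$line_id == lid & truth$kind == "hom_del", ,
                  drop = FALSE]
      for (k in seq_len(nrow(ev))) {
        hit <- mk$chrom == ev$chrom[k] & mk$pos >= ev$start[k] &
          mk$pos < ev$end[k]
        deleted <- deleted | hit
      }
    }
    cl[deleted] <- "---"
    open <- !deleted & !fixed_het
    null_noise <- open & stats::runif(n_markers) < null_rate
    cl[null_noise] <- "---"
    het_noise <- open & !null_noise & stats::runif(n_markers) < het_rate
    if (any(het_noise)) {
      cl[het_noise] <- paste0(base[het_noise], "/", alt[het_noise])
    }
    sel <- deleted | null_noise
    ledger[[lid]] <<- tibble::tibble(
      marker_id = mk$marker_id[sel],
      line_id = rep(lid, sum(sel)),
      cause = c("noise", "deletion")[deleted[sel] + 1]
    )
    cl
  })
  names(calls) <- line_ids

  out <- dplyr::bind_cols(
    mk[, c("marker_id", "chrom", "pos")],
    tibble::as_tibble(calls)
  )
  structure(out,
            class = unique(c("marker_matrix", class(out))),
            line_ids = line_ids,
            null_ledger = dplyr::bind_rows(ledger))
}
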