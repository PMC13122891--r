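#' Flag windows into a copy-number candidate class
#'
#' Classifies every unmasked window of every line against the cross-line
#' statistics, one flagging mode at a time:
#'
#' * `hom_del` — depth below the mean minus three standard deviations
#'   (`x < mu - 3*sigma`): candidate homozygous deletion.
#' * `hemi_del` — depth strictly closer to half the mean than to the mean
#'   (`|x - mu/2| < |x - mu|`, i.e. `x < 3*mu/4`): candidate hemizygous
#'   deletion. A tie at `3*mu/4` exactly is not flagged.
#' * `dup` — depth at least twice the mean (`x >= 2*mu`, boundary inclusive):
#'   candidate duplication.
#'
#' @param depth A normalized `skim_depth` table.
#' @param stats A `window_stats` table on the same grid.
#' @param mode One of `"hom_del"`, `"hemi_del"`, `"dup"`.
#' @return A tibble of class `flag_track`: `line_id`, `chrom`, `start`,
#'   `end`, `depth`, `mu`, `sigma`, `masked`, `flag`; attribute `mode`.
#' @export
flag_windows <- function(depth, stats, mode) {
  mode <- match.arg(mode, c("hom_del", "hemi_del", "dup"))
  if (attr(depth, "state") != "normalized") {
    stop("flag_windows needs normalized depth")
  }
  x <- dplyr::inner_join(
    tibble::as_tibble(depth)[, c("line_id", "chrom", "start", "end", "depth")],
    tibble::as_tibble(stats)[, c("chrom", "start", "end", "mu", "sigma",
                                 "masked")],
    by = c("chrom", "start", "end")
  )
  if (nrow(x) != nrow(depth)) {
    stop("depth and stats are not on the same window grid")
  }
  flag <- switch(mode,
    hom_del = x$depth < x$mu - 3 * x$sigma,
    hemi_del = abs(x$depth - x$mu / 2) < abs(x$depth - x$mu),
    dup = x$depth >= 2 * x$mu
  )
  x$flag <- flag & !x$masked
  chrom_order <- unique(stats$chrom)
  x <- dplyr::arrange(x, .data$line_id, match(.data$chrom, chrom_order),
                      .data$start)
  structure(x,
            class = unique(c("flag_track", class(x))),
            mode = mode,
            window_size = attr(depth, "window_size"),
            chrom_lengths = attr(depth, "chrom_lengths"))
}

#' Score flagged runs as CNV calls
#'
#' Assembles each line's flags into runs per chromosome (runs never cross a
#' chromosome boundary), estimates the line's chance-flag probability `p`,
#' and scores every run with its expected chance count `E = N * p^n * (1-p)^2`
#' where `n` is the run's flagged length and `N` the line's unmasked window
#' count. After provisional calling, `p` is re-estimated once excluding the
#' intervals of provisionally accepted runs and all runs are re-scored. A call
#' is tagged at a level `alpha` when `E <= alpha`. The genomic span is the
#' first to last flagged window (interruptions are counted, not spanned
#' beyond).
#'
#' @param flags A `flag_track` from [flag_windows()].
#' @param alpha_levels Significance levels to tag (default 0.05 and 0.01).
#' @param gap_tolerance Interruption tolerance passed to [find_runs()].
#' @return A tibble of class `cnv_calls`: `call_id`, `line_id`, `chrom`,
#'   `start`, `end`, `mode`, `n_windows`, `n_interruptions`, `p_hat`, `E` and
#'   the list-column `sig_tags` (alpha levels passed).
#' @export
call_events <- function(flags, alpha_levels = c(0.05, 0.01),
                        gap_tolerance = 1) {
  stopifnot(inherits(flags, "flag_track"))
  mode <- attr(flags, "mode")
  alpha_max <- max(alpha_levels)

  calls <- flags |>
    dplyr::group_by(.data$line_id) |>
    dplyr::group_map(function(d, key) {
      unmasked <- !d$masked
      N <- sum(unmasked)
      if (N == 0) return(NULL)
      runs <- purrr::imap_dfr(split(seq_len(nrow(d)), factor(d$chrom, levels = unique(d$chrom))),
        function(idx, chrom) {
          r <- find_runs(d$flag[idx], gap_tolerance = gap_tolerance,
                         masked = d$masked[idx])
          if (nrow(r) == 0) return(r)
          dplyr::mutate(r, chrom = chrom,
                        start = d$start[idx][.data$first],
                        end = d$end[idx][.data$last],
                        core_start = d$start[idx][.data$core_first],
                        core_end = d$end[idx][.data$core_last],
                        .first_global = idx[.data$first],
                        .last_global = idx[.data$last])
        })
      if (nrow(runs) == 0) return(NULL)
      p0 <- estimate_p(d$flag[unmasked])
      runs$E <- expected_runs(p0, runs$n_flagged, N)
      # one re-estimation pass: drop provisionally accepted runs from the
      # noise-rate estimate, then re-score
      accepted <- runs[runs$E <= alpha_max, , drop = FALSE]
      exclude <- rep(FALSE, nrow(d))
      for (k in seq_len(nrow(accepted))) {
        exclude[accepted$.first_global[k]:accepted$.last_global[k]] <- TRUE
      }
      if (any(exclude) && any(!exclude[unmasked])) {
        p1 <- estimate_p(d$flag[unmasked], exclude[unmasked])
        runs$E <- expected_runs(p1, runs$n_flagged, N)
      } else {
        p1 <- p0
      }
      tibble::tibble(
        line_id = key$line_id,
        chrom = runs$chrom,
        start = runs$start,
        end = runs$end,
        core_start = runs$core_start,
        core_end = runs$core_end,
        mode = mode,
        n_windows = runs$n_flagged,
        n_interruptions = runs$n_interruptions,
        p_hat = p1,
        E = runs$E,
        sig_tags = purrr::map(runs$E, function(e) alpha_levels[e <= alpha_levels])
      )
    }) |>
    dplyr::bind_rows()

  if (nrow(calls) == 0) {
    calls <- tibble::tibble(
      line_id = character(), chrom = character(), start = double(),
      end = double(), core_start = double(), core_end = double(),
      mode = character(), n_windows = integer(),
      n_interruptions = integer(), p_hat = double(), E = double(),
      sig_tags = list()
    )
  }
  calls <- dplyr::mutate(calls,
    call_id = sprintf("%s:%s:%.0f-%.0f:%s", .data$line_id, .data$chrom,
                      .data$start, .data$end, .data$mode),
    .before = 1)
  structure(calls,
            class = unique(c("cnv_calls", class(calls))),
            alpha_levels = alpha_levels,
            window_size = attr(flags, "window_size"),
            chrom_lengths = attr(flags, "chrom_lengths"))
}

#' Flag and call one mode in a single step
#'
#' Convenience wrapper: [flag_windows()] then [call_events()].
#'
#' @inheritParams flag_windows
#' @inheritParams call_events
#' @return A `cnv_calls` tibble.
#' @export
call_cnv <- function(depth, stats, mode, alpha_levels = c(0.05, 0.01),
                     gap_tolerance = 1) {
  call_events(flag_windows(depth, stats, mode), alpha_levels = alpha_levels,
              gap_tolerance = gap_tolerance)
}

#' Merge nearby same-line, same-mode calls
#'
#' Calls of the same line and mode on the same chromosome separated by at most
#' `max_gap_bp` are candidates for a single event rather than independent
#' events, and are merged transitively. The merged call spans the component
#' extremes, keeps the component spans in the `components` list-column (so
#' split-deletion structure is preserved), and carries the minimum `E` of its
#' components — the strongest component carries the evidence.
#'
#' @param calls A `cnv_calls` tibble.
#' @param max_gap_bp Maximum gap merged across, in bp (default 200 kb).
#' @param min_sig Optional significance gate: only calls with `E <= min_sig`
#'   participate in merging; the rest pass through unmerged. Prevents isolated
#'   chance flags near a real event from stretching its merged span.
#' @return A `cnv_calls` tibble with `n_components` and `components` columns.
#' @export
merge_nearby <- function(calls, max_gap_bp = 2e5, min_sig = NULL) {
  stopifnot(max_gap_bp >= 0)
  if (nrow(calls) == 0) {
    out <- dplyr::mutate(tibble::as_tibble(calls), n_components = integer(),
                         components = list())
    return(preserve_call_attrs(out, calls))
  }
  base <- tibble::as_tibble(calls)
  if (!"core_start" %in% names(base)) {
    base$core_start <- base$start
    base$core_end <- base$end
  }
  if (!is.null(min_sig)) {
    keep <- base$E <= min_sig
    pass <- base[!keep, , drop = FALSE]
    pass$n_components <- rep(1L, nrow(pass))
    pass$components <- purrr::pmap(pass[, c("start", "end", "E")],
                                   function(start, end, E) {
                                     tibble::tibble(start = start, end = end,
                                                    E = E)
                                   })
    merged <- merge_nearby(preserve_call_attrs(base[keep, , drop = FALSE],
                                               calls), max_gap_bp)
    out <- dplyr::arrange(dplyr::bind_rows(tibble::as_tibble(merged), pass),
                          .data$line_id, .data$chrom, .data$start)
    return(preserve_call_attrs(out, calls))
  }
  alpha_levels <- attr(calls, "alpha_levels") %||% c(0.05, 0.01)
  merged <- base |>
    dplyr::group_by(.data$line_id, .data$mode, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$start)
      grp <- cumsum(c(0, d$start[-1] - cummax(d$end)[-nrow(d)] > max_gap_bp))
      d |>
        dplyr::mutate(.grp = grp) |>
        dplyr::group_by(.data$.grp) |>
        dplyr::summarise(
          components = list(dplyr::pick("start", "end", "E")),
          start = min(.data$start),
          end = max(.data$end),
          core_start = min(.data$core_start),
          core_end = max(.data$core_end),
          n_windows = sum(.data$n_windows),
          n_interruptions = sum(.data$n_interruptions),
          p_hat = .data$p_hat[1],
          E = min(.data$E),
          n_components = dplyr::n(),
          .groups = "drop"
        ) |>
        dplyr::select(-".grp")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      sig_tags = purrr::map(.data$E, function(e) alpha_levels[e <= alpha_levels]),
      call_id = sprintf("%s:%s:%.0f-%.0f:%s", .data$line_id, .data$chrom,
                        .data$start, .data$end, .data$mode)
    ) |>
    dplyr::relocate("call_id", "line_id", "chrom", "start", "end", "mode")
  preserve_call_attrs(merged, calls)
}

preserve_call_attrs <- function(out, calls) {
  structure(out,
            class = unique(c("cnv_calls", class(tibble::as_tibble(out)))),
            alpha_levels = attr(calls, "alpha_levels"),
            window_size = attr(calls, "window_size"),
            chrom_lengths = attr(calls, "chrom_lengths"))
}

#' Associate homozygous calls with containing hemizygous calls
#'
#' A long hemizygous deletion's span often contains distinct homozygous
#' deletion calls. Each homozygous call is annotated with the id of a
#' same-line hemizygous call that contains at least `min_containment` of it.
#'
#' @param hom_calls,hemi_calls `cnv_calls` tibbles of the two modes.
#' @param min_containment Minimum fraction of the homozygous call covered by
#'   the hemizygous call (default 0.5).
#' @return `hom_calls` with an added `within_hemi` column (containing call id
#'   or `NA`).
#' @export
hom_within_hemi <- function(hom_calls, hemi_calls, min_containment = 0.5) {
  within <- purrr::pmap_chr(
    list(hom_calls$line_id, hom_calls$chrom, hom_calls$start, hom_calls$end),
    function(lid, chrom, s, e) {
      cand <- hemi_calls[hemi_calls$line_id == lid &
                         hemi_calls$chrom == chrom, , drop = FALSE]
      if (nrow(cand) == 0) return(NA_character_)
      ov <- pmin(cand$end, e) - pmax(cand$start, s)
      frac <- ov / (e - s)
      hit <- which(frac >= min_containment)
      if (length(hit) == 0) return(NA_character_)
      cand$call_id[hit[which.max(frac[hit])]]
    }
  )
  dplyr::mutate(tibble::as_tibble(hom_calls), within_hemi = within)
}

#' Collapse calls across lines into unique deletions and summarize the spectrum
#'
#' Sibling lineages of one mutagenized family carry the same deletion; calls
#' from different lines at the same locus with reciprocal overlap at or above
#' `reciprocal` are collapsed into one unique deletion (transitively). The
#' summary reports the unique-deletion size histogram in `bin_width` classes
#' with a fitted reciprocal reference curve, the union of deleted bp, and the
#' fraction of the genome covered.
#'
#' @param calls A `cnv_calls` tibble of deletion calls (any mix of lines).
#' @param genome_bp Total genome size in bp, or a `genome_windows` object
#'   (defaults to the chromosome lengths recorded on `calls`).
#' @param reciprocal Reciprocal-overlap threshold for collapsing (default 0.5).
#' @param bin_width Size-class width in bp (default 10 kb).
#' @return An object of class `deletion_spectrum`; see [tidy()][generics::tidy]
#'   and [glance()][generics::glance] methods and [ggplot2::autoplot()].
#' @export
unique_deletions <- function(calls, genome_bp = NULL, reciprocal = 0.5,
                             bin_width = 1e4) {
  if (is.null(genome_bp)) {
    lens <- attr(calls, "chrom_lengths")
    if (is.null(lens)) stop("give genome_bp (calls carry no genome lengths)")
    genome_bp <- sum(lens)
  } else if (inherits(genome_bp, "genome_windows")) {
    genome_bp <- genome_total_bp(genome_bp)
  }
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) {
    return(structure(list(
      representatives = calls, bins = tibble::tibble(),
      n_calls = 0L, n_unique = 0L, unique_deleted_bp = 0,
      genome_bp = genome_bp, genome_fraction = 0, curve_constant = NA_real_
    ), class = "deletion_spectrum"))
  }

  cluster <- rep(NA_integer_, nrow(calls))
  nxt <- 0L
  deleted_bp <- 0
  for (chrom in unique(calls$chrom)) {
    idx <- which(calls$chrom == chrom)
    ir <- IRanges::IRanges(start = calls$start[idx] + 1, end = calls$end[idx])
    deleted_bp <- deleted_bp + sum(IRanges::width(IRanges::reduce(ir)))
    hits <- IRanges::findOverlaps(ir, ir)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(ir[qi], ir[si]))
    keep <- ov >= reciprocal * IRanges::width(ir[qi]) &
            ov >= reciprocal * IRanges::width(ir[si])
    comp <- union_find(length(ir), qi[keep], si[keep])
    cluster[idx] <- nxt + comp
    nxt <- nxt + max(comp)
  }

  reps <- calls |>
    dplyr::mutate(cluster = cluster, size = .data$end - .data$start) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(if ("E" %in% names(calls)) .data$E else -.data$size,
                   .by_group = TRUE) |>
    dplyr::summarise(
      chrom = .data$chrom[1], start = .data$start[1], end = .data$end[1],
      size = .data$size[1], n_lines = dplyr::n_distinct(.data$line_id),
      n_calls = dplyr::n(),
      E = if ("E" %in% names(calls)) min(.data$E) else NA_real_,
      .groups = "drop")

  bins <- reps |>
    dplyr::mutate(size_class = ceiling(.data$size / bin_width) * bin_width) |>
    dplyr::count(.data$size_class, name = "count")
  # least-squares constant for the reciprocal reference curve c / size
  cc <- sum(bins$count / bins$size_class) / sum(1 / bins$size_class^2)
  bins$reciprocal_curve <- cc / bins$size_class

  structure(list(
    representatives = reps,
    bins = bins,
    n_calls = nrow(calls),
    n_unique = nrow(reps),
    unique_deleted_bp = deleted_bp,
    genome_bp = genome_bp,
    genome_fraction = deleted_bp / genome_bp,
    curve_constant = cc
  ), class = "deletion_spectrum")
}

# Minimal union-find over edge lists; returns 1-based component labels.
union_find <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' @export
print.deletion_spectrum <- function(x, ...) {
  cat(sprintf(
    "Deletion spectrum: %d calls -> %d unique deletions; %.1f Mb deleted (%.1f%% of %.1f Mb)\n",
    x$n_calls, x$n_unique, x$unique_deleted_bp / 1e6,
    100 * x$genome_fraction, x$genome_bp / 1e6))
  invisible(x)
}

#' Spacing between duplication calls
#'
#' Reports the gaps between consecutive same-chromosome duplication calls of
#' each line, how many fall below / at-or-above a threshold (default 1 Mb,
#' boundary counted as at-or-above), and — because tight spacing suggests one
#' fragmented event rather than many independent ones — what merging at a
#' range of gap distances would do to the call count.
#'
#' @param calls A `cnv_calls` tibble of duplication calls.
#' @param threshold Gap threshold in bp (default 1 Mb).
#' @param merge_gaps Gap distances (bp) at which to report the merged call
#'   count.
#' @return An object of class `dup_spacing` with elements `gaps` (tibble),
#'   `n_gaps`, `n_below`, `n_at_or_above`, `merge_profile`.
#' @export
duplication_spacing <- function(calls, threshold = 1e6,
                                merge_gaps = c(1e5, 2e5, 5e5, 1e6)) {
  # gap = next call's start minus previous call's end, per line and chromosome
  gaps <- calls |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$line_id, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::reframe(gap = if (dplyr::n() > 1) {
      .data$start[-1] - .data$end[-dplyr::n()]
    } else numeric(0)) |>
    dplyr::ungroup()

  profile <- tibble::tibble(
    max_gap_bp = merge_gaps,
    n_calls = vapply(merge_gaps,
                     function(g) nrow(merge_nearby(calls, max_gap_bp = g)),
                     numeric(1))
  )
  structure(list(
    gaps = gaps,
    n_gaps = nrow(gaps),
    n_below = sum(gaps$gap < threshold),
    n_at_or_above = sum(gaps$gap >= threshold),
    threshold = threshold,
    merge_profile = profile
  ), class = "dup_spacing")
}

#' @export
print.dup_spacing <- function(x, ...) {
  cat(sprintf("Duplication spacing: %d gaps, %d < %.1f Mb, %d >= %.1f Mb\n",
              x$n_gaps, x$n_below, x$threshold / 1e6, x$n_at_or_above,
              x$threshold / 1e6))
  invisible(x)
}

#' Sub-window deletion size diagnostic
#'
#' For a single window with depth moderately below the cross-line mean, the
#' implied deleted length within that window is `window_size * (1 - x / mu)`
#' (a homozygous deletion removing that fraction of the window's mappable
#' sequence). A diagnostic only: single-window dips are below the method's
#' reliable detection limit.
#'
#' @param x Normalized depth of the window in the affected line.
#' @param mu Cross-line mean depth of the window.
#' @param window_size Window width in bp.
#' @return Estimated deleted bp within the window.
#' @export
subwindow_deletion_bp <- function(x, mu, window_size = 1e4) {
  stopifnot(mu > 0, window_size > 0)
  window_size * (1 - x / mu)
}
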