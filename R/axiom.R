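#' Read a genotype-call matrix
#'
#' Reads a TSV with columns `marker_id`, `chrom`, `pos` and one call column
#' per line (calls like `"A/A"`, `"T/G"`, or `"---"` for a null score).
#' Markers are sorted by genomic position; duplicate marker ids and missing
#' positions are rejected.
#'
#' @param path Path to the TSV.
#' @return A tibble of class `marker_matrix`.
#' @export
read_genotype_matrix <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("marker_id", "chrom", "pos")
  if (!all(need %in% names(m))) {
    stop("genotype matrix must have columns marker_id, chrom, pos")
  }
  if (anyDuplicated(m$marker_id)) {
    stop("duplicate marker id: ", m$marker_id[duplicated(m$marker_id)][1])
  }
  if (anyNA(m$pos)) {
    stop("missing position for marker ",
         m$marker_id[which(is.na(m$pos))[1]])
  }
  line_ids <- setdiff(names(m), need)
  if (length(line_ids) == 0) stop("no line call columns found")
  if (any(is.na(m[line_ids]) | m[line_ids] == "")) stop("empty genotype call")
  m <- dplyr::arrange(m, .data$chrom, .data$pos)
  structure(m,
            class = unique(c("marker_matrix", class(m))),
            line_ids = line_ids)
}

#' Write a marker matrix as TSV
#' @param matrix A `marker_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_marker_matrix <- function(matrix, path) {
  readr::write_tsv(tibble::as_tibble(matrix), path)
  invisible(path)
}

marker_line_ids <- function(matrix) {
  attr(matrix, "line_ids") %||%
    setdiff(names(matrix), c("marker_id", "chrom", "pos"))
}

is_het_call <- function(call) {
  parts <- strsplit(call, "/", fixed = TRUE)
  vapply(parts, function(p) length(p) == 2 && p[1] != p[2], logical(1)) &
    call != "---"
}

#' Remove markers heterozygous in every line
#'
#' A marker scored heterozygous in all lines of an inbred population cannot be
#' a real segregating heterozygote; it marks an array feature that matches
#' neither progenitor haplotype exactly. Such markers are removed from the
#' deletion screen and returned separately.
#'
#' @param matrix A `marker_matrix` with at least 2 lines.
#' @return A list with elements `matrix` (filtered) and `removed` (tibble of
#'   the fixed-heterozygous markers).
#' @export
filter_fixed_heterozygotes <- function(matrix) {
  lids <- marker_line_ids(matrix)
  if (length(lids) < 2) stop("need at least 2 lines")
  het <- vapply(lids, function(l) is_het_call(matrix[[l]]),
                FUN.VALUE = logical(nrow(matrix)))
  if (nrow(matrix) == 1) het <- matrix(het, nrow = 1)
  fixed <- rowSums(het) == length(lids)
  kept <- matrix[!fixed, , drop = FALSE]
  attr(kept, "line_ids") <- lids
  class(kept) <- class(matrix)
  list(matrix = kept, removed = tibble::as_tibble(matrix[fixed, , drop = FALSE]))
}

#' Candidate deletions from runs of null genotype calls
#'
#' Scans one line's calls for runs of `"---"` scores: a failed assay is
#' expected of a deleted marker but can also be a technical failure, so only
#' runs of at least `min_run` nulls (default 3) become candidates, tolerating
#' up to `interruption_tolerance` intervening valid calls (default 1). Runs
#' never join across chromosomes. Nearby candidates separated by at most
#' `merge_gap_markers` markers are merged as candidates for a single deletion.
#' Each candidate is scored with the expected chance count
#' `E = N * p^n * (1-p)^2`, where `p` is the line's isolated-null rate
#' (nulls outside candidate runs over markers outside candidate runs) and `N`
#' the marker count. Isolated single nulls are reported as low-confidence
#' annotations in the `isolated_nulls` attribute, never as calls.
#'
#' Run [filter_fixed_heterozygotes()] first so `N` reflects informative
#' markers only; [call_axiom()] does both steps for all lines.
#'
#' @param matrix A `marker_matrix`.
#' @param line Line identifier (a call column name).
#' @param min_run Minimum null count for a candidate (default 3).
#' @param interruption_tolerance Valid calls tolerated inside a run (default 1).
#' @param merge_gap_markers Merge candidates separated by at most this many
#'   markers (default 5).
#' @param alpha_levels Significance levels to tag.
#' @return A tibble of class `axiom_calls`: `line_id`, `chrom`, `start`,
#'   `end` (positions of first/last null marker), `marker_first`,
#'   `marker_last`, `n_null`, `n_interruptions`, `n_components`, `p_hat`,
#'   `E`, `sig_tags`.
#' @export
null_runs <- function(matrix, line, min_run = 3, interruption_tolerance = 1,
                      merge_gap_markers = 5, alpha_levels = c(0.05, 0.01)) {
  lids <- marker_line_ids(matrix)
  if (!line %in% lids) stop("unknown line id: ", line)
  stopifnot(min_run >= 1, interruption_tolerance >= 0)
  is_null <- matrix[[line]] == "---"
  N <- nrow(matrix)

  runs <- purrr::map_dfr(split(seq_len(N), factor(matrix$chrom, levels = unique(matrix$chrom))),
    function(idx) {
      r <- find_runs(is_null[idx], gap_tolerance = interruption_tolerance)
      if (nrow(r) == 0) return(r)
      dplyr::mutate(r,
        chrom = matrix$chrom[idx[1]],
        first_global = idx[.data$first],
        last_global = idx[.data$last])
    })

  if (nrow(runs) == 0) {
    runs <- tibble::tibble(first = integer(), last = integer(),
                           n_flagged = integer(), n_interruptions = integer(),
                           core_first = integer(), core_last = integer(),
                           chrom = character(), first_global = integer(),
                           last_global = integer())
  }
  cand <- runs[runs$n_flagged >= min_run, , drop = FALSE]
  isolated <- runs[runs$n_flagged < min_run, , drop = FALSE]

  # merge candidates separated by few markers (marker-count gap, not bp)
  if (nrow(cand) > 1) {
    cand <- dplyr::arrange(cand, .data$first_global)
    same_chrom <- cand$chrom[-1] == cand$chrom[-nrow(cand)]
    gap <- cand$first_global[-1] - cand$last_global[-nrow(cand)] - 1L
    grp <- cumsum(c(0L, !(same_chrom & gap <= merge_gap_markers)))
    cand <- cand |>
      dplyr::mutate(.grp = grp) |>
      dplyr::group_by(.data$.grp) |>
      dplyr::summarise(
        chrom = .data$chrom[1],
        first_global = min(.data$first_global),
        last_global = max(.data$last_global),
        n_flagged = sum(.data$n_flagged),
        n_interruptions = (max(.data$last_global) - min(.data$first_global) + 1L) -
          sum(.data$n_flagged),
        n_components = dplyr::n(),
        .groups = "drop") |>
      dplyr::select(-".grp")
  } else {
    cand$n_components <- rep(1L, nrow(cand))
  }

  in_run <- rep(FALSE, N)
  for (k in seq_len(nrow(cand))) {
    in_run[cand$first_global[k]:cand$last_global[k]] <- TRUE
  }
  p_hat <- if (all(in_run)) 0 else estimate_p(is_null, exclude = in_run)
  ev <- if (nrow(cand) > 0) expected_runs(p_hat, cand$n_flagged, N) else numeric(0)

  out <- tibble::tibble(
    line_id = rep(line, nrow(cand)),
    chrom = cand$chrom,
    start = matrix$pos[cand$first_global],
    end = matrix$pos[cand$last_global],
    marker_first = matrix$marker_id[cand$first_global],
    marker_last = matrix$marker_id[cand$last_global],
    n_null = cand$n_flagged,
    n_interruptions = cand$n_interruptions,
    n_components = cand$n_components,
    first_global = cand$first_global,
    last_global = cand$last_global,
    p_hat = rep(p_hat, nrow(cand)),
    E = ev,
    sig_tags = purrr::map(ev, function(e) alpha_levels[e <= alpha_levels])
  )
  iso <- tibble::tibble(
    line_id = line,
    chrom = isolated$chrom,
    marker_id = matrix$marker_id[isolated$first_global],
    pos = matrix$pos[isolated$first_global],
    n_null = isolated$n_flagged
  )
  structure(out,
            class = unique(c("axiom_calls", class(out))),
            isolated_nulls = iso,
            n_markers = N,
            alpha_levels = alpha_levels)
}

#' Classify the valid calls interrupting a null run
#'
#' An interrupting marker inside a candidate deletion may be a genotyping
#' mis-score rather than evidence of intact sequence. Each interrupting marker
#' is labelled:
#'
#' * `line_specific_het` — heterozygous in this line while at most
#'   `max_other_het` other lines are heterozygous there: an unreliable call
#'   (a deleted marker's residual signal is often mis-clustered as
#'   heterozygous).
#' * `inconsistent` — differs from the modal call of the other lines:
#'   unreliable.
#' * `valid` — consistent with the other lines.
#'
#' Candidates whose interruptions are all unreliable are flagged
#' `likely_contiguous`.
#'
#' @param matrix The `marker_matrix` the calls came from.
#' @param calls An `axiom_calls` tibble from [null_runs()].
#' @param max_other_het Maximum number of other heterozygous lines for the
#'   `line_specific_het` label (default 0: this line only).
#' @return `calls` with list-column `interruptions` (tibble: `marker_id`,
#'   `pos`, `call`, `reliability`) and logical `likely_contiguous`.
#' @export
classify_interruptions <- function(matrix, calls, max_other_het = 0) {
  lids <- marker_line_ids(matrix)
  ann <- purrr::pmap(
    list(calls$line_id, calls$first_global, calls$last_global),
    function(line, i0, i1) {
      idx <- i0:i1
      inter <- idx[matrix[[line]][idx] != "---"]
      if (length(inter) == 0) {
        return(tibble::tibble(marker_id = character(), pos = double(),
                              call = character(), reliability = character()))
      }
      others <- setdiff(lids, line)
      rel <- vapply(inter, function(i) {
        this <- matrix[[line]][i]
        other_calls <- vapply(others, function(l) matrix[[l]][i], character(1))
        if (is_het_call(this)) {
          n_other_het <- sum(is_het_call(other_calls))
          if (n_other_het <= max_other_het) return("line_specific_het")
          return("valid")
        }
        informative <- other_calls[other_calls != "---"]
        if (length(informative) == 0) return("valid")
        modal <- names(sort(table(informative), decreasing = TRUE))[1]
        if (this != modal) "inconsistent" else "valid"
      }, character(1))
      tibble::tibble(marker_id = matrix$marker_id[inter],
                     pos = matrix$pos[inter],
                     call = matrix[[line]][inter],
                     reliability = rel)
    })
  out <- dplyr::mutate(tibble::as_tibble(calls),
    interruptions = ann,
    likely_contiguous = purrr::map_lgl(ann, function(a) {
      nrow(a) > 0 && all(a$reliability != "valid")
    }))
  structure(out,
            class = unique(c("axiom_calls", class(out))),
            isolated_nulls = attr(calls, "isolated_nulls"),
            n_markers = attr(calls, "n_markers"),
            alpha_levels = attr(calls, "alpha_levels"))
}

#' Run the full array deletion screen over all lines
#'
#' Filters fixed heterozygotes, then finds, merges, scores and annotates null
#' runs for every line.
#'
#' @inheritParams null_runs
#' @return A list: `calls` (annotated `axiom_calls` over all lines),
#'   `isolated_nulls`, `fixed_het_removed`, `n_markers`.
#' @export
call_axiom <- function(matrix, min_run = 3, interruption_tolerance = 1,
                       merge_gap_markers = 5, alpha_levels = c(0.05, 0.01)) {
  flt <- filter_fixed_heterozygotes(matrix)
  lids <- marker_line_ids(flt$matrix)
  per_line <- purrr::map(lids, function(l) {
    calls <- null_runs(flt$matrix, l, min_run = min_run,
                       interruption_tolerance = interruption_tolerance,
                       merge_gap_markers = merge_gap_markers,
                       alpha_levels = alpha_levels)
    list(calls = classify_interruptions(flt$matrix, calls),
         isolated = attr(calls, "isolated_nulls"))
  })
  calls <- dplyr::bind_rows(purrr::map(per_line, "calls"))
  list(
    calls = calls,
    isolated_nulls = dplyr::bind_rows(purrr::map(per_line, "isolated")),
    fixed_het_removed = flt$removed,
    n_markers = nrow(flt$matrix)
  )
}
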