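#' Chance frequency of an exact-length run of failed detections
#'
#' Under the assumption that detection failures are scattered independently at
#' random with per-interval probability `p`, the expected frequency of a
#' maximal run of exactly `n` consecutive failures (bounded on both sides by
#' successes) is `F = p^n * (1 - p)^2`, a convenient approximation from the
#' theory of runs. Deletions, by contrast, produce contiguous failure runs far
#' longer than chance predicts, so `F` separates real events from noise.
#'
#' @param p Per-interval failure probability, in `[0, 1]`.
#' @param n Run length, a positive integer (vectorized).
#' @return The expected frequency `p^n (1-p)^2` per interval position.
#' @examples
#' run_frequency(0.5, 3)  # 0.03125
#' @export
run_frequency <- function(p, n) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (any(n < 1) || any(n != floor(n))) stop("n must be a positive integer")
  p^n * (1 - p)^2
}

#' Expected number of chance runs of a given length in a track
#'
#' Scales the per-position run frequency up to a whole track: in `N` assayed
#' intervals the expected count of maximal chance runs of exactly `n` failures
#' is `E = N * p^n * (1-p)^2`. A run is accepted as a real event at level
#' `alpha` when `E <= alpha`.
#'
#' @inheritParams run_frequency
#' @param N Number of assayed intervals (markers or unmasked windows).
#' @return Expected chance-run count `N * F`.
#' @examples
#' expected_runs(0.5, 3, N = 1000)  # 31.25
#' @export
expected_runs <- function(p, n, N) {
  if (any(N < 1)) stop("N must be at least 1")
  N * run_frequency(p, n)
}

#' Smallest run length significant at a given level
#'
#' Scans run lengths upward and returns the smallest `n` whose expected
#' chance-run count `N * p^n * (1-p)^2` is at most `alpha`. Multiplied by the
#' window size this is the method's detection limit: shorter events cannot be
#' distinguished from chance failure runs.
#'
#' @inheritParams expected_runs
#' @param alpha Significance level (expected chance runs tolerated), in (0,1).
#' @return The minimal significant run length (1 when `p = 0`).
#' @examples
#' min_significant_run(N = 445000, p = 0.004, alpha = 0.05)  # 3
#' @export
min_significant_run <- function(N, p, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (p < 0 || p >= 1) stop("p must be in [0, 1)")
  if (p == 0) return(1L)
  for (n in seq_len(ceiling(N))) {
    if (expected_runs(p, n, N) <= alpha) return(as.integer(n))
  }
  stop("no run length up to N = ", N, " reaches alpha = ", alpha,
       " at p = ", p)
}

#' Estimate the per-interval chance-failure probability
#'
#' Estimates `p` as the fraction of flagged intervals among intervals lying
#' outside accepted runs: flags inside an accepted event are evidence of the
#' event, not of the noise channel, so they are excluded from both numerator
#' and denominator.
#'
#' @param flags Logical vector of per-interval flags for one line (unmasked
#'   intervals only).
#' @param exclude Optional logical vector marking intervals inside accepted
#'   runs.
#' @return The estimated probability `p`.
#' @export
estimate_p <- function(flags, exclude = NULL) {
  if (length(flags) == 0) stop("empty flag track")
  if (is.null(exclude)) exclude <- rep(FALSE, length(flags))
  keep <- !exclude
  if (!any(keep)) stop("no intervals left outside accepted runs")
  sum(flags[keep]) / sum(keep)
}

#' Assemble flagged intervals into runs with interruption tolerance
#'
#' Groups flagged intervals into maximal runs, allowing internal gaps of at
#' most `gap_tolerance` consecutive unflagged intervals without breaking the
#' run (the "interrupted by a single valid call" rule, at the default
#' tolerance of 1). Masked intervals are transparent: they neither flag nor
#' count toward a gap. The run's extent is reported by its first and last
#' flagged interval (conservative breakpoints); internal unflagged, unmasked
#' intervals are counted as interruptions.
#'
#' In addition to the flagged extremes, each run reports a trimmed "core":
#' leading or trailing contiguous flagged segments no longer than
#' `gap_tolerance` — single stray flags attached to the run body across a
#' bridged gap, more often chance than event — are dropped from the core
#' extremes (never from the run's flagged count). Downstream breakpoint
#' reporting uses the core; the full extremes remain the run's span.
#'
#' @param flags Logical vector of per-interval flags (one chromosome's track).
#' @param gap_tolerance Maximum internal gap, in unflagged unmasked intervals,
#'   bridged without breaking a run (default 1).
#' @param masked Optional logical vector of intervals to treat as transparent.
#' @return A tibble with one row per run: `first`, `last` (indices into
#'   `flags`, flagged extremes), `n_flagged`, `n_interruptions`,
#'   `core_first`, `core_last`.
#' @examples
#' find_runs(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE), gap_tolerance = 1)
#' @export
find_runs <- function(flags, gap_tolerance = 1, masked = NULL) {
  stopifnot(gap_tolerance >= 0)
  if (is.null(masked)) masked <- rep(FALSE, length(flags))
  stopifnot(length(masked) == length(flags))
  if (any(flags & masked, na.rm = TRUE)) stop("masked intervals cannot be flagged")
  empty <- tibble::tibble(first = integer(), last = integer(),
                          n_flagged = integer(), n_interruptions = integer(),
                          core_first = integer(), core_last = integer())
  pos <- which(!masked)            # unmasked positions, in order
  fl <- flags[pos]
  hit <- which(fl)
  if (length(hit) == 0) return(empty)
  gap <- diff(hit) - 1L            # unflagged unmasked intervals between flags
  grp <- cumsum(c(0L, gap > gap_tolerance))
  purrr::map_dfr(split(hit, grp), function(h) {
    seg <- split(h, cumsum(c(0L, diff(h) > 1L)))
    while (length(seg) > 1 && length(seg[[1]]) <= gap_tolerance) {
      seg <- seg[-1]
    }
    while (length(seg) > 1 && length(seg[[length(seg)]]) <= gap_tolerance) {
      seg <- seg[-length(seg)]
    }
    core <- unlist(seg, use.names = FALSE)
    tibble::tibble(
      first = pos[h[1]],
      last = pos[h[length(h)]],
      n_flagged = length(h),
      n_interruptions = (h[length(h)] - h[1] + 1L) - length(h),
      core_first = pos[core[1]],
      core_last = pos[core[length(core)]]
    )
  })
}
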