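#' Per-family deleted genome fraction
#'
#' The fraction of the genome deleted by an average family in the screened
#' sample: total unique deleted bp divided by (genome size x families
#' screened).
#'
#' @param deleted_bp Total unique deleted bp found in the screened sample.
#' @param genome_bp Assembled genome size in bp.
#' @param n_families Number of families screened.
#' @return The per-family deleted fraction `f`.
#' @examples
#' per_family_fraction(734e6, 734e6 / 0.165, 210)
#' @export
per_family_fraction <- function(deleted_bp, genome_bp, n_families) {
  if (deleted_bp < 0 || genome_bp <= 0 || n_families <= 0) {
    stop("inputs must be positive (deleted_bp may be 0)")
  }
  if (deleted_bp > genome_bp * n_families) {
    stop("deleted_bp exceeds genome_bp * n_families")
  }
  deleted_bp / (genome_bp * n_families)
}

#' Probability a given locus is deleted somewhere in the population
#'
#' Under independent, uniformly placed deletions — each family deleting a
#' fraction `f` of the genome — the chance that a given sequence is deleted in
#' at least one of `M` families is `P = 1 - (1 - f)^M`.
#'
#' @param f Per-family deleted fraction, in `[0, 1]`.
#' @param M Number of families in the population.
#' @return The hit probability.
#' @examples
#' f <- per_family_fraction(734e6, 734e6 / 0.165, 210)
#' hit_probability(f, 5000)  # ~0.98
#' @export
hit_probability <- function(f, M) {
  if (any(f < 0 | f > 1)) stop("f must be in [0, 1]")
  if (any(M < 1)) stop("M must be at least 1")
  1 - (1 - f)^M
}

#' Families needed to reach a target hit probability
#'
#' Inverse of [hit_probability()]: the smallest integer `M` with
#' `1 - (1-f)^M >= target_p`.
#'
#' @param f Per-family deleted fraction, in (0, 1).
#' @param target_p Target hit probability, in (0, 1).
#' @return Integer number of families.
#' @export
families_needed <- function(f, target_p) {
  if (f <= 0 || f >= 1) stop("f must be in (0, 1)")
  if (target_p <= 0 || target_p >= 1) stop("target_p must be in (0, 1)")
  m <- ceiling(log1p(-target_p) / log1p(-f))
  m <- max(m, 1)
  while (hit_probability(f, m) < target_p) m <- m + 1
  while (m > 1 && hit_probability(f, m - 1) >= target_p) m <- m - 1
  as.integer(m)
}

#' Detection limit of the windowed method in bp
#'
#' The smallest reliably detectable event is the minimal significant run
#' length (see [min_significant_run()]) times the window size.
#'
#' @inheritParams min_significant_run
#' @param window_size Window width in bp.
#' @return Detection limit in bp (a multiple of `window_size`).
#' @examples
#' detection_limit_bp(N = 445000, p = 0.004, alpha = 0.05, window_size = 1e4)
#' @export
detection_limit_bp <- function(N, p, alpha = 0.05, window_size = 1e4) {
  stopifnot(window_size > 0)
  min_significant_run(N, p, alpha) * window_size
}

#' Build a genome-saturation model for a mutant population
#'
#' Bundles the screened sample's deleted fraction with the full population
#' size for hit-probability arithmetic. Assumes deletions are placed
#' independently and uniformly across families — an idealization: real
#' deletion placement is constrained by viability, and sibling lineages share
#' events.
#'
#' @inheritParams per_family_fraction
#' @param n_population Families in the full population.
#' @return An object of class `saturation_model` with [tidy()][generics::tidy]
#'   and [glance()][generics::glance] methods.
#' @examples
#' m <- saturation_model(734e6, 734e6 / 0.165, 210, 5000)
#' glance(m)
#' @export
saturation_model <- function(deleted_bp, genome_bp, n_families, n_population) {
  f <- per_family_fraction(deleted_bp, genome_bp, n_families)
  structure(list(
    deleted_bp = deleted_bp,
    genome_bp = genome_bp,
    n_families = n_families,
    n_population = n_population,
    sample_fraction = deleted_bp / genome_bp,
    f = f,
    p_hit = hit_probability(f, n_population)
  ), class = "saturation_model")
}

#' @export
print.saturation_model <- function(x, ...) {
  cat(sprintf(
    paste0("Saturation model: %.1f Mb deleted across %d families ",
           "(%.1f%% of a %.0f Mb genome)\n",
           "  per-family deleted fraction f = %.3g\n",
           "  P(locus deleted in >=1 of %d families) = %.4f (%.0f%%)\n"),
    x$deleted_bp / 1e6, x$n_families, 100 * x$sample_fraction,
    x$genome_bp / 1e6, x$f, x$n_population, x$p_hit, round(100 * x$p_hit)))
  invisible(x)
}
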