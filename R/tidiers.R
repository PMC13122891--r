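#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a saturation model
#'
#' @param x A `saturation_model`.
#' @param ... Unused.
#' @return One row per model quantity (`term`, `value`).
#' @export
tidy.saturation_model <- function(x, ...) {
  tibble::tibble(
    term = c("deleted_bp", "genome_bp", "n_families", "n_population",
             "sample_fraction", "per_family_fraction", "hit_probability"),
    value = c(x$deleted_bp, x$genome_bp, x$n_families, x$n_population,
              x$sample_fraction, x$f, x$p_hit)
  )
}

#' @rdname tidy.saturation_model
#' @return For `glance()`: a one-row summary with the hit probability and its
#'   whole-percent rounding.
#' @export
glance.saturation_model <- function(x, ...) {
  tibble::tibble(
    f = x$f,
    p_hit = x$p_hit,
    p_hit_percent = round(100 * x$p_hit),
    sample_fraction = x$sample_fraction,
    n_families = x$n_families,
    n_population = x$n_population
  )
}

#' Tidy a deletion spectrum
#'
#' @param x A `deletion_spectrum` from [unique_deletions()].
#' @param ... Unused.
#' @return For `tidy()`: the size-class histogram with the fitted reciprocal
#'   curve. For `glance()`: a one-row summary (unique deletions, deleted bp,
#'   genome fraction).
#' @export
tidy.deletion_spectrum <- function(x, ...) x$bins

#' @rdname tidy.deletion_spectrum
#' @export
glance.deletion_spectrum <- function(x, ...) {
  tibble::tibble(
    n_calls = x$n_calls,
    n_unique = x$n_unique,
    unique_deleted_bp = x$unique_deleted_bp,
    genome_bp = x$genome_bp,
    genome_fraction = x$genome_fraction,
    mean_size = if (x$n_unique > 0) mean(x$representatives$size) else NA_real_
  )
}

#' Tidy a CNV scan
#'
#' @param x A `cnv_scan` from [run_pipeline()].
#' @param ... Unused.
#' @return For `tidy()`: the resolved deletion table. For `glance()`: a
#'   one-row scan summary.
#' @export
tidy.cnv_scan <- function(x, ...) x$deletions

#' @rdname tidy.cnv_scan
#' @export
glance.cnv_scan <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_lines = length(unique(x$depth$line_id)),
      n_deletions = nrow(x$deletions),
      n_hom = sum(x$deletions$kind == "hom_del"),
      n_hemi = sum(x$deletions$kind == "hemi_del"),
      n_duplications = nrow(x$duplications)
    ),
    glance(x$spectrum)[, c("n_unique", "unique_deleted_bp", "genome_fraction")]
  )
}

#' Tidy duplication spacing
#'
#' @param x A `dup_spacing` from [duplication_spacing()].
#' @param ... Unused.
#' @return For `tidy()`: the per-line gap table. For `glance()`: gap counts
#'   around the threshold.
#' @export
tidy.dup_spacing <- function(x, ...) x$gaps

#' @rdname tidy.dup_spacing
#' @export
glance.dup_spacing <- function(x, ...) {
  tibble::tibble(n_gaps = x$n_gaps, n_below = x$n_below,
                 n_at_or_above = x$n_at_or_above, threshold = x$threshold)
}
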