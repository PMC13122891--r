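#' Build a windowed genome model
#'
#' Splits each chromosome into fixed-width windows (last window truncated at
#' the chromosome end and flagged `partial`) and attaches a shared per-window
#' mappability factor. The window grid is the coordinate system for the whole
#' pipeline: depth simulation, normalization, cross-line statistics and CNV
#' calling all operate on these windows. Coordinates are 0-based, half-open.
#'
#' Mappability factors are drawn once per window from a lognormal distribution
#' with mean 1 and standard deviation `mappability_sd`; they are shared by all
#' lines, emulating systematic per-window variation in how many reads a window
#' attracts (repeat content, assembly quality) as opposed to per-line noise.
#'
#' @param chrom_lengths Numeric vector of chromosome lengths in bp. Names are
#'   used as chromosome names; unnamed vectors get `chr1`, `chr2`, ...
#' @param window_size Window width in bp (default 10000, i.e. 10 kb).
#' @param mappability_sd Standard deviation of the mean-1 lognormal
#'   mappability factor. `0` gives factor exactly 1 in every window.
#' @param seed Optional integer seed for the mappability draw.
#' @return A tibble of class `genome_windows` with columns `chrom`, `start`,
#'   `end`, `width`, `partial`, `mappability`, and attributes `window_size`
#'   and `chrom_lengths`.
#' @examples
#' gen <- make_genome(c(chr1 = 1e6), window_size = 1e4)
#' nrow(gen)  # 100 windows
#' @export
make_genome <- function(chrom_lengths, window_size = 1e4, mappability_sd = 0,
                        seed = NULL) {
  if (is.data.frame(chrom_lengths)) {
    stopifnot(all(c("chrom", "length") %in% names(chrom_lengths)))
    lens <- stats::setNames(chrom_lengths$length, chrom_lengths$chrom)
  } else {
    lens <- chrom_lengths
    if (is.null(names(lens))) names(lens) <- paste0("chr", seq_along(lens))
  }
  if (any(lens <= 0)) stop("chromosome lengths must be positive")
  if (window_size <= 0) stop("window_size must be positive")
  if (mappability_sd < 0) stop("mappability_sd must be non-negative")

  windows <- purrr::map2_dfr(names(lens), unname(lens), function(nm, len) {
    starts <- seq(0, len - 1, by = window_size)
    tibble::tibble(
      chrom = nm,
      start = starts,
      end = pmin(starts + window_size, len)
    )
  })
  windows <- dplyr::mutate(windows,
    width = .data$end - .data$start,
    partial = .data$width < window_size
  )

  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  if (mappability_sd > 0) {
    sdlog <- sqrt(log(1 + mappability_sd^2))
    windows$mappability <- stats::rlnorm(nrow(windows),
                                         meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    windows$mappability <- 1
  }

  structure(windows,
            class = c("genome_windows", class(windows)),
            window_size = window_size,
            chrom_lengths = lens)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' @export
print.genome_windows <- function(x, ...) {
  lens <- attr(x, "chrom_lengths")
  cat(sprintf("Genome model: %d chromosome(s), %.1f Mb total, %d windows of %s bp\n",
              length(lens), sum(lens) / 1e6, nrow(x),
              format(attr(x, "window_size"), big.mark = ",")))
  NextMethod()
}

genome_total_bp <- function(genome) sum(attr(genome, "chrom_lengths"))

genome_window_size <- function(genome) attr(genome, "window_size")

#' Convert interval coordinates between 0-based half-open and 1-based inclusive
#'
#' Internally all intervals are 0-based half-open (BED convention). Published
#' genomic coordinates are usually 1-based inclusive; these helpers convert a
#' data frame's `start` column at the boundary (the `end` column is identical
#' under the two conventions).
#'
#' @param x A data frame with `start` and `end` columns.
#' @return The data frame with `start` shifted.
#' @export
to_1based <- function(x) dplyr::mutate(x, start = .data$start + 1)

#' @rdname to_1based
#' @export
to_0based <- function(x) dplyr::mutate(x, start = .data$start - 1)
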