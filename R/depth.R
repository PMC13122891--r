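#' Read per-window read-count tracks into a depth table
#'
#' Reads one bedGraph (or headerless 4-column TSV: chrom, start, end, count)
#' file per line and assembles the long lines-by-windows depth table. Every
#' file must cover exactly the grid of `genome`: a missing or extra interval
#' is an error naming the first offending interval, a malformed row an error
#' with its line number.
#'
#' @param paths Character vector of file paths, one per line. Names are used
#'   as line identifiers; unnamed paths use the file name without extension.
#' @param genome A `genome_windows` grid the tracks must match.
#' @return A `skim_depth` tibble in `raw` state.
#' @export
read_window_counts <- function(paths, genome) {
  ids <- names(paths)
  if (is.null(ids)) ids <- rep("", length(paths))
  blank <- !nzchar(ids)
  ids[blank] <- sub("\\.(bedgraph|bedGraph|tsv|txt)$", "", basename(paths[blank]))

  key <- paste(genome$chrom, genome$start, genome$end)
  out <- purrr::map2_dfr(paths, ids, function(path, lid) {
    tr <- read_track_file(path)
    idx <- match(key, paste(tr$chrom, tr$start, tr$end))
    if (anyNA(idx)) {
      miss <- which(is.na(idx))[1]
      stop("track ", path, " is missing window ", genome$chrom[miss], ":",
           genome$start[miss], "-", genome$end[miss])
    }
    if (nrow(tr) > nrow(genome)) {
      extra <- setdiff(paste(tr$chrom, tr$start, tr$end), key)[1]
      stop("track ", path, " has a window not on the grid: ", extra)
    }
    tibble::tibble(
      line_id = lid,
      chrom = genome$chrom, start = genome$start, end = genome$end,
      width = genome$width, partial = genome$partial,
      count = tr$count[idx]
    )
  })
  new_skim_depth(out, state = "raw", genome = genome, line_ids = ids)
}

read_track_file <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|#)", lines)]
  has_header <- length(lines) > 0 && grepl("^chrom\\b", lines[1])
  if (has_header) lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    stop("malformed row at line ", bad + has_header, " of ", path,
         ": expected 4 tab-separated fields, got ", nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 2:4, drop = FALSE], 2, as.numeric))
  if (length(lines) == 1) num <- matrix(num, nrow = 1)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stop("malformed row at line ", bad + has_header, " of ", path,
         ": non-numeric coordinate or count")
  }
  tibble::tibble(chrom = m[, 1], start = num[, 1], end = num[, 2],
                 count = num[, 3])
}

#' Count reads per window from a BAM file
#'
#' Convenience ingestion hook for mapped reads: each read is assigned to the
#' window containing its leftmost aligned position, optionally filtered by
#' mapping quality. Requires the Rsamtools package.
#'
#' @param bam_paths Character vector of BAM paths (named by line id; unnamed
#'   paths use the file name).
#' @param genome A `genome_windows` grid.
#' @param mapq Minimum mapping quality (default 0, i.e. keep everything
#'   mapped).
#' @return A `skim_depth` tibble in `raw` state.
#' @export
count_bam_windows <- function(bam_paths, genome, mapq = 0) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM ingestion requires the Rsamtools package")
  }
  ids <- names(bam_paths)
  if (is.null(ids)) ids <- rep("", length(bam_paths))
  blank <- !nzchar(ids)
  ids[blank] <- sub("\\.bam$", "", basename(bam_paths[blank]))
  w <- genome_window_size(genome)
  lens <- attr(genome, "chrom_lengths")

  out <- purrr::map2_dfr(bam_paths, ids, function(path, lid) {
    b <- Rsamtools::scanBam(
      path,
      param = Rsamtools::ScanBamParam(
        what = c("rname", "pos", "mapq"),
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
    keep <- !is.na(b$pos) & (is.na(b$mapq) | b$mapq >= mapq)
    chrom <- as.character(b$rname)[keep]
    start0 <- b$pos[keep] - 1          # BAM pos is 1-based
    key <- paste(chrom, floor(start0 / w) * w)
    counts <- table(key)
    gkey <- paste(genome$chrom, genome$start)
    n <- as.integer(counts[gkey])
    n[is.na(n)] <- 0L
    tibble::tibble(
      line_id = lid,
      chrom = genome$chrom, start = genome$start, end = genome$end,
      width = genome$width, partial = genome$partial, count = n
    )
  })
  new_skim_depth(out, state = "raw", genome = genome, line_ids = ids)
}

#' Coerce a long data frame of window counts to a depth table
#'
#' For counts assembled outside the package readers: `df` needs columns
#' `line_id`, `chrom`, `start`, `end`, and `count` (raw state) or `depth`
#' (normalized state), with every line covering the full grid of `genome`.
#'
#' @param df A data frame of per-line window counts.
#' @param genome The `genome_windows` grid the rows lie on.
#' @param state `"raw"` or `"normalized"`.
#' @return A `skim_depth` tibble.
#' @export
as_skim_depth <- function(df, genome, state = c("raw", "normalized")) {
  state <- match.arg(state)
  value <- if (state == "raw") "count" else "depth"
  need <- c("line_id", "chrom", "start", "end", value)
  if (!all(need %in% names(df))) {
    stop("need columns: ", paste(need, collapse = ", "))
  }
  key <- paste(genome$chrom, genome$start, genome$end)
  out <- purrr::map_dfr(split(tibble::as_tibble(df), df$line_id), function(d) {
    idx <- match(key, paste(d$chrom, d$start, d$end))
    if (anyNA(idx)) {
      miss <- which(is.na(idx))[1]
      stop("line ", d$line_id[1], " is missing window ", genome$chrom[miss],
           ":", genome$start[miss], "-", genome$end[miss])
    }
    tibble::tibble(
      line_id = d$line_id[1],
      chrom = genome$chrom, start = genome$start, end = genome$end,
      width = genome$width, partial = genome$partial
    ) |>
      dplyr::mutate(!!value := d[[value]][idx])
  })
  new_skim_depth(out, state = state, genome = genome,
                 line_ids = unique(df$line_id))
}

#' Normalize depth per line
#'
#' Divides each line's window counts by that line's median count over
#' non-partial windows, so a line's typical window has depth 1 regardless of
#' how many reads it received. The median (not the mean) is used so that a
#' line's own large deletions or duplications do not shift its normalizer.
#'
#' @param depth A `skim_depth` table (raw counts, or already normalized, in
#'   which case re-normalizing is a no-op up to floating point).
#' @param mask Optional logical vector (one entry per grid window, in grid
#'   order) of windows to exclude from the median.
#' @return A `skim_depth` tibble in `normalized` state with column `depth`.
#' @export
normalize_depth <- function(depth, mask = NULL) {
  stopifnot(inherits(depth, "skim_depth"))
  val <- if (attr(depth, "state") == "normalized") depth$depth else depth$count
  usable <- !depth$partial
  if (!is.null(mask)) {
    usable <- usable & !mask[grid_index(depth)]
  }
  med <- tapply(val[usable], depth$line_id[usable], stats::median)
  if (any(med <= 0 | is.na(med))) {
    bad <- names(med)[which(med <= 0 | is.na(med))[1]]
    stop("line ", bad, " has non-positive median count; sample failed")
  }
  out <- dplyr::mutate(depth, depth = val / unname(med[.data$line_id]))
  new_skim_depth(out, state = "normalized",
                 window_size = attr(depth, "window_size"),
                 chrom_lengths = attr(depth, "chrom_lengths"),
                 line_ids = attr(depth, "line_ids"))
}

# Index of each depth row into the (chrom, start)-ordered window grid.
grid_index <- function(depth) {
  key <- paste(depth$chrom, depth$start)
  ukey <- unique(key[depth$line_id == depth$line_id[1]])
  match(key, ukey)
}

#' Per-window depth statistics across lines
#'
#' For every window computes the cross-line mean and standard deviation of
#' normalized depth (the n-1 convention of [stats::sd()]; with hundreds of
#' lines the distinction is immaterial), the inputs to the three-class CNV
#' flagging rules. Windows are masked — excluded from calling
#' in every line — when their mean depth falls below `min_mean` (systematically
#' unmappable sequence) or, by default, when they are partial terminal windows
#' (their reduced width mimics low depth).
#'
#' @param depth A normalized `skim_depth` table with at least 3 lines.
#' @param min_mean Mask windows whose cross-line mean depth is below this
#'   floor (default 0.1).
#' @param mask_partial Mask partial terminal windows (default `TRUE`).
#' @return A tibble of class `window_stats`: `chrom`, `start`, `end`,
#'   `partial`, `mu`, `sigma`, `masked`.
#' @export
window_stats <- function(depth, min_mean = 0.1, mask_partial = TRUE) {
  stopifnot(inherits(depth, "skim_depth"))
  if (attr(depth, "state") != "normalized") {
    stop("window_stats needs normalized depth; run normalize_depth() first")
  }
  n_lines <- length(unique(depth$line_id))
  if (n_lines < 3) {
    stop("window_stats needs at least 3 lines; got ", n_lines)
  }
  out <- depth |>
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$partial) |>
    dplyr::summarise(
      mu = mean(.data$depth),
      sigma = stats::sd(.data$depth),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$chrom, unique(depth$chrom)), .data$start)
  out <- dplyr::mutate(out,
    masked = .data$mu < min_mean | (mask_partial & .data$partial))
  structure(out,
            class = unique(c("window_stats", class(out))),
            window_size = attr(depth, "window_size"),
            chrom_lengths = attr(depth, "chrom_lengths"))
}

#' Write depth tracks to disk
#'
#' Writes one bedGraph per line plus a combined wide TSV matrix
#' (chrom, start, end, one column per line).
#'
#' @param depth A `skim_depth` table.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_depth_tracks <- function(depth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  value <- if (attr(depth, "state") == "normalized") "depth" else "count"
  paths <- character(0)
  for (lid in unique(depth$line_id)) {
    d <- depth[depth$line_id == lid, c("chrom", "start", "end", value)]
    p <- file.path(dir, paste0(lid, ".bedgraph"))
    readr::write_tsv(d, p, col_names = FALSE)
    paths <- c(paths, p)
  }
  wide <- tidyr::pivot_wider(
    depth[, c("chrom", "start", "end", "line_id", value)],
    names_from = "line_id", values_from = dplyr::all_of(value))
  mp <- file.path(dir, "depth_matrix.tsv")
  readr::write_tsv(wide, mp)
  invisible(c(paths, mp))
}

#' Write window statistics as TSV
#' @param stats A `window_stats` table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_window_stats <- function(stats, path) {
  readr::write_tsv(tibble::as_tibble(stats), path)
  invisible(path)
}
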