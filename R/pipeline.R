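#' Resolve deletion zygosity across the two flagging modes
#'
#' The homozygous rule (`x < mu - 3*sigma`) also captures half-depth windows
#' when the cross-line spread is small, and the hemizygous rule captures
#' zero-depth windows, so one implanted event typically yields overlapping
#' calls in both modes. Same-line overlapping deletion calls are clustered
#' (transitively, any overlap). The hemizygous rule's threshold (`x < 3mu/4`)
#' does not depend on the cross-line spread, so the hemizygous-mode flag set
#' is the union deletion track and delimits the event most completely: the
#' cluster's span is taken from its strongest (minimum `E`) hemizygous-mode
#' call, falling back to the strongest call of any mode, using the call's
#' trimmed core extremes (see [find_runs()]) as breakpoints. The final zygosity
#' comes from the median normalized depth over that span: below `hom_cutoff`
#' (default 0.25, the midpoint of the expected depths 0 and 0.5) the deletion
#' is homozygous, otherwise hemizygous. The cluster's `E` is the minimum over
#' all member calls — the strongest component carries the evidence.
#'
#' @param calls A `cnv_calls` tibble containing `hom_del` and/or `hemi_del`
#'   calls (typically merged).
#' @param depth The normalized `skim_depth` table the calls came from.
#' @param hom_cutoff Median-depth cutoff separating homozygous from
#'   hemizygous.
#' @return A tibble of resolved deletions: `line_id`, `chrom`, `start`, `end`,
#'   `size`, `kind`, `median_depth`, `n_windows`, `n_interruptions`, `E`,
#'   `sig_tags`, `n_modes`.
#' @export
resolve_deletions <- function(calls, depth, hom_cutoff = 0.25) {
  calls <- tibble::as_tibble(calls)
  calls <- calls[calls$mode %in% c("hom_del", "hemi_del"), , drop = FALSE]
  if (nrow(calls) == 0) {
    return(tibble::tibble(line_id = character(), chrom = character(),
                          start = double(), end = double(), size = double(),
                          kind = character(), median_depth = double(),
                          n_windows = integer(), n_interruptions = integer(),
                          E = double(), sig_tags = list(), n_modes = integer()))
  }
  depth_split <- split(tibble::as_tibble(depth)[, c("start", "end", "depth")],
                       paste(depth$line_id, depth$chrom))
  calls |>
    dplyr::group_by(.data$line_id, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      dloc <- depth_split[[paste(key$line_id, key$chrom)]]
      ir <- IRanges::IRanges(start = d$start + 1, end = d$end)
      hits <- IRanges::findOverlaps(ir, ir)
      comp <- union_find(nrow(d), S4Vectors::queryHits(hits),
                         S4Vectors::subjectHits(hits))
      if (!"core_start" %in% names(d)) {
        d$core_start <- d$start
        d$core_end <- d$end
      }
      purrr::map_dfr(split(seq_len(nrow(d)), comp), function(idx) {
        dd <- d[idx, , drop = FALSE]
        hemi <- dd[dd$mode == "hemi_del", , drop = FALSE]
        rep_call <- if (nrow(hemi) > 0) {
          hemi[which.min(hemi$E), , drop = FALSE]
        } else {
          dd[which.min(dd$E), , drop = FALSE]
        }
        tibble::tibble(
          start = rep_call$core_start, end = rep_call$core_end,
          n_windows = rep_call$n_windows,
          n_interruptions = rep_call$n_interruptions,
          E = min(dd$E),
          sig_tags = dd$sig_tags[which.min(dd$E)],
          n_modes = dplyr::n_distinct(dd$mode)
        )
      }) |>
        dplyr::mutate(median_depth = purrr::map2_dbl(.data$start, .data$end,
          function(s, e) {
            val <- dloc$depth[dloc$start < e & dloc$end > s]
            if (length(val) == 0) return(NA_real_)
            stats::median(val)
          }))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      size = .data$end - .data$start,
      kind = ifelse(.data$median_depth < hom_cutoff, "hom_del", "hemi_del")
    ) |>
    dplyr::select("line_id", "chrom", "start", "end", "size", "kind",
                  "median_depth", "n_windows", "n_interruptions", "E",
                  "sig_tags", "n_modes")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full discovery pipeline
#'
#' Executes normalize -> window statistics -> three-mode flagging -> run
#' assembly -> calling -> merging -> zygosity resolution -> population
#' summaries, and optionally the array null-call screen and a saturation
#' projection, from either simulated inputs or files on disk. Any stage error
#' aborts with the stage name and cause. Given the same configuration and
#' seed, the result is identical.
#'
#' @param config A named list, or the path to a YAML file with the same
#'   structure (requires the yaml package):
#' \describe{
#'   \item{genome}{Either a `genome_windows` object or a list with
#'     `chrom_lengths`, and optionally `window_size`, `mappability_sd`.}
#'   \item{simulate}{Optional list for synthetic input: `n_lines`,
#'     `events_per_line`, `min_size`, `max_size`, `zygosity_mix`,
#'     `size_exponent`, `mean_depth`, and optionally `markers` (a list with
#'     `n_markers`, `null_rate`, `het_rate`, `fixed_het_fraction`).}
#'   \item{inputs}{Alternative to `simulate`: list with `depth_paths`
#'     (named character vector) and optionally `marker_path`.}
#'   \item{calling}{Optional overrides: `alpha_levels`, `gap_tolerance`,
#'     `merge_gap_bp`, `min_mean`, `mask_partial`, `hom_cutoff`.}
#'   \item{axiom}{Optional overrides: `min_run`, `interruption_tolerance`,
#'     `merge_gap_markers`.}
#'   \item{saturation}{Optional list: `n_population` (and optionally
#'     `genome_bp`, `n_families`).}
#'   \item{seed}{Integer; drives all randomness. Stage sub-seeds are derived
#'     deterministically from it.}
#'   \item{out_dir}{Optional output directory; see [write_scan()].}
#' }
#' @return An object of class `cnv_scan`: a list with the genome, normalized
#'   depth, window stats, per-mode merged calls, resolved `deletions`,
#'   `duplications`, the deletion `spectrum`, duplication `spacing`, the
#'   `axiom` screen results (or `NULL`), the `saturation` model (or `NULL`),
#'   the truth set when simulated, and a `params` record.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the yaml package")
    }
    config <- yaml::read_yaml(config)
    if (!is.null(config$genome$chrom_lengths)) {
      config$genome$chrom_lengths <- unlist(config$genome$chrom_lengths)
    }
    if (!is.null(config$simulate$zygosity_mix)) {
      config$simulate$zygosity_mix <- unlist(config$simulate$zygosity_mix)
    }
  }
  seed <- config$seed %||% 1L
  cal <- config$calling %||% list()
  alpha_levels <- cal$alpha_levels %||% c(0.05, 0.01)
  gap_tolerance <- cal$gap_tolerance %||% 1
  merge_gap_bp <- cal$merge_gap_bp %||% 2e5
  min_mean <- cal$min_mean %||% 0.1
  mask_partial <- cal$mask_partial %||% TRUE
  hom_cutoff <- cal$hom_cutoff %||% 0.25
  ax <- config$axiom %||% list()

  genome <- stage("genome", {
    if (inherits(config$genome, "genome_windows")) config$genome
    else make_genome(config$genome$chrom_lengths,
                     window_size = config$genome$window_size %||% 1e4,
                     mappability_sd = config$genome$mappability_sd %||% 0,
                     seed = seed)
  })

  truth <- NULL
  markers <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    truth <- stage("implant_events", implant_events(
      genome, n_lines = sim$n_lines,
      events_per_line = sim$events_per_line %||% 3,
      min_size = sim$min_size %||% 3e4,
      max_size = sim$max_size %||% max(attr(genome, "chrom_lengths")),
      zygosity_mix = sim$zygosity_mix %||% c(hom_del = 0.4, hemi_del = 0.4,
                                             dup = 0.2),
      size_exponent = sim$size_exponent %||% 1,
      seed = seed + 1L))
    depth_raw <- stage("simulate_depth", simulate_depth(
      genome, truth, mean_depth = sim$mean_depth %||% 67, seed = seed + 2L))
    if (!is.null(sim$markers)) {
      mk <- sim$markers
      markers <- stage("simulate_marker_calls", simulate_marker_calls(
        genome, truth, n_markers = mk$n_markers %||% 2000,
        null_rate = mk$null_rate %||% 0.005,
        het_rate = mk$het_rate %||% 0.005,
        fixed_het_fraction = mk$fixed_het_fraction %||% 0.02,
        seed = seed + 3L))
    }
  } else if (!is.null(config$inputs)) {
    depth_raw <- stage("read_window_counts",
                       read_window_counts(config$inputs$depth_paths, genome))
    if (!is.null(config$inputs$marker_path)) {
      markers <- stage("read_genotype_matrix",
                       read_genotype_matrix(config$inputs$marker_path))
    }
  } else {
    stop("config must provide either $simulate or $inputs")
  }

  depth <- stage("normalize", normalize_depth(depth_raw))
  stats <- stage("window_stats",
                 window_stats(depth, min_mean = min_mean,
                              mask_partial = mask_partial))

  calls <- list()
  for (mode in c("hom_del", "hemi_del", "dup")) {
    raw <- stage(paste0("call_", mode),
                 call_cnv(depth, stats, mode, alpha_levels = alpha_levels,
                          gap_tolerance = gap_tolerance))
    calls[[mode]] <- stage(paste0("merge_", mode),
                           merge_nearby(raw, max_gap_bp = merge_gap_bp,
                                        min_sig = max(alpha_levels)))
  }

  deletions <- stage("resolve_deletions", resolve_deletions(
    dplyr::bind_rows(tibble::as_tibble(calls$hom_del),
                     tibble::as_tibble(calls$hemi_del)),
    depth, hom_cutoff = hom_cutoff))
  sig_deletions <- deletions[deletions$E <= max(alpha_levels), , drop = FALSE]

  spectrum <- stage("unique_deletions", unique_deletions(
    preserve_call_attrs(sig_deletions, calls$hom_del),
    genome_bp = genome_total_bp(genome)))
  spacing <- stage("duplication_spacing", duplication_spacing(calls$dup))

  axiom <- NULL
  if (!is.null(markers)) {
    axiom <- stage("axiom_screen", call_axiom(
      markers, min_run = ax$min_run %||% 3,
      interruption_tolerance = ax$interruption_tolerance %||% 1,
      merge_gap_markers = ax$merge_gap_markers %||% 5,
      alpha_levels = alpha_levels))
  }

  saturation <- NULL
  if (!is.null(config$saturation)) {
    sat <- config$saturation
    saturation <- stage("saturation", saturation_model(
      deleted_bp = spectrum$unique_deleted_bp,
      genome_bp = sat$genome_bp %||% genome_total_bp(genome),
      n_families = sat$n_families %||% length(unique(depth$line_id)),
      n_population = sat$n_population))
  }

  p_estimates <- dplyr::bind_rows(purrr::map(calls, function(cc) {
    dplyr::distinct(tibble::as_tibble(cc)[, c("line_id", "mode", "p_hat")])
  }))

  scan <- structure(list(
    genome = genome,
    truth = truth,
    markers = markers,
    depth = depth,
    stats = stats,
    calls = calls,
    deletions = deletions,
    duplications = calls$dup,
    spectrum = spectrum,
    spacing = spacing,
    axiom = axiom,
    saturation = saturation,
    p_estimates = p_estimates,
    params = list(seed = seed, alpha_levels = alpha_levels,
                  gap_tolerance = gap_tolerance, merge_gap_bp = merge_gap_bp,
                  min_mean = min_mean, mask_partial = mask_partial,
                  hom_cutoff = hom_cutoff,
                  window_size = genome_window_size(genome))
  ), class = "cnv_scan")

  if (!is.null(config$out_dir)) write_scan(scan, config$out_dir)
  scan
}

#' @export
print.cnv_scan <- function(x, ...) {
  cat("CNV scan of", length(unique(x$depth$line_id)), "lines over",
      sprintf("%.1f Mb\n", genome_total_bp(x$genome) / 1e6))
  cat(sprintf("  deletions: %d resolved (%d hom, %d hemi); duplications: %d\n",
              nrow(x$deletions), sum(x$deletions$kind == "hom_del"),
              sum(x$deletions$kind == "hemi_del"), nrow(x$duplications)))
  print(x$spectrum)
  if (!is.null(x$saturation)) print(x$saturation)
  invisible(x)
}

#' Write a scan's outputs to a run directory
#'
#' Writes the calls as BED6+ (score = capped `-log10(E)`), the resolved
#' deletions and window statistics as TSV, the truth set as BED when
#' simulated, and a machine-readable JSON run log (parameters, per-line/mode
#' noise-rate estimates, seed, file manifest).
#'
#' @param scan A `cnv_scan` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_scan <- function(scan, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing a run log requires the jsonlite package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (mode in names(scan$calls)) {
    p <- file.path(dir, paste0("calls_", mode, ".bed"))
    write_calls_bed(scan$calls[[mode]], p)
    files <- c(files, p)
  }
  p <- file.path(dir, "deletions.tsv")
  readr::write_tsv(dplyr::mutate(scan$deletions,
                                 sig_tags = tags_chr(scan$deletions$sig_tags)), p)
  files <- c(files, p)
  files <- c(files, write_window_stats(scan$stats, file.path(dir, "window_stats.tsv")))
  if (!is.null(scan$truth)) {
    p <- file.path(dir, "truth.bed")
    write_truth_bed(scan$truth, p)
    files <- c(files, p)
  }
  if (!is.null(scan$axiom)) {
    ax <- scan$axiom$calls
    p <- file.path(dir, "axiom_calls.tsv")
    readr::write_tsv(dplyr::select(
      dplyr::mutate(tibble::as_tibble(ax), sig_tags = tags_chr(ax$sig_tags)),
      -dplyr::any_of("interruptions")), p)
    files <- c(files, p)
    p <- file.path(dir, "axiom_calls.bed")
    readr::write_tsv(tibble::tibble(
      chrom = ax$chrom,
      start = format(ax$start, scientific = FALSE, trim = TRUE),
      end = format(ax$end, scientific = FALSE, trim = TRUE),
      name = paste0(ax$line_id, ":null_run"),
      score = round(pmin(-log10(pmax(ax$E, 1e-300)), 1000), 2),
      strand = "."
    ), p, col_names = FALSE)
    files <- c(files, p)
    if ("interruptions" %in% names(ax)) {
      p <- file.path(dir, "axiom_interruptions.tsv")
      intr <- dplyr::bind_rows(purrr::map2(
        ax$interruptions, seq_len(nrow(ax)),
        function(tb, i) dplyr::mutate(tb, line_id = ax$line_id[i],
                                      chrom = ax$chrom[i], .before = 1)))
      readr::write_tsv(intr, p)
      files <- c(files, p)
    }
  }
  manifest <- file.path(dir, "run_log.json")
  jsonlite::write_json(list(
    params = scan$params,
    p_estimates = scan$p_estimates,
    summary = list(
      n_deletions = nrow(scan$deletions),
      n_duplications = nrow(scan$duplications),
      n_unique = scan$spectrum$n_unique,
      unique_deleted_bp = scan$spectrum$unique_deleted_bp,
      genome_fraction = scan$spectrum$genome_fraction
    ),
    files = basename(files)
  ), manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

tags_chr <- function(tags) {
  vapply(tags, function(t) paste(t, collapse = ";"), character(1))
}

#' Write calls as BED6+
#'
#' Columns: chrom, start, end, name (`line:mode`), score (`-log10(E)` capped
#' at 1000), strand (`.`), then `n_windows`, `n_interruptions`, `sig_tags`
#' and, when present, component spans.
#'
#' @param calls A `cnv_calls` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calls_bed <- function(calls, path) {
  d <- tibble::as_tibble(calls)
  bed <- tibble::tibble(
    chrom = d$chrom,
    start = format(d$start, scientific = FALSE, trim = TRUE),
    end = format(d$end, scientific = FALSE, trim = TRUE),
    name = paste0(d$line_id, ":", d$mode),
    score = round(pmin(-log10(pmax(d$E, 1e-300)), 1000), 2),
    strand = ".",
    n_windows = d$n_windows,
    n_interruptions = d$n_interruptions,
    sig_tags = tags_chr(d$sig_tags)
  )
  if ("components" %in% names(d)) {
    bed$components <- vapply(d$components, function(cm) {
      paste(sprintf("%.0f-%.0f", cm$start, cm$end), collapse = ",")
    }, character(1))
  }
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write a truth set as BED (kind in the name column)
#' @param truth Truth table from [implant_events()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- tibble::tibble(
    chrom = truth$chrom,
    start = format(truth$start, scientific = FALSE, trim = TRUE),
    end = format(truth$end, scientific = FALSE, trim = TRUE),
    name = paste0(truth$line_id, ":", truth$kind)
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
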