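#' Analysis configuration
#'
#' Collects every option of the end-to-end driver with its default:
#' 2 Mb windows, all plots, internal ploidy estimation, full-resolution
#' histograms with a cn-LOH line, absolute copy numbers for clustering.
#' `window_size` and `window_percent` are mutually exclusive.
#'
#' @param input path of the segment file/directory, or a [segment_set()]
#' @param target_dir output directory
#' @param file_type `"ascat"` or `"sequenza"`
#' @param ref_build `"hg18"`, `"hg19"` or a chrom-sizes file path
#' @param centromere_file centromere file for a custom build
#' @param window_size window length in bp (default 2e6)
#' @param window_percent window length in percent of chromosome length
#' @param ploidy_file ploidy TSV path, or a single number for all samples
#' @param use_custom_ploidies run the internal ploidy estimator for
#'   samples not covered by `ploidy_file` (default TRUE)
#' @param run_gistic write a GISTIC segmentation input file
#' @param small_mem pass-through flag for an external GISTIC run; no
#'   internal effect
#' @param r_color_file colour-configuration file (see [read_color_file()])
#' @param output_format format string, e.g.
#'   `"hist:png(width=4000,height=1800,res=300);heat:pdf(width=10,height=12)"`
#' @param loh_to_plot `"cn-LOH"`, `"LOH"`, `"both"` or `"none"`
#' @param use_full_resolution histograms at base resolution (default
#'   TRUE) rather than windowed
#' @param use_relative_for_clustering cluster on ploidy-relative values
#'   (default FALSE)
#' @param keep_genomic_pos keep heatmap columns in genomic order
#'   (default TRUE; FALSE clusters the windows)
#' @param sample_file sample-annotation TSV (see [read_sample_table()])
#' @param feature single feature to decorate plots with; default all
#' @param plot_all render every plot (default TRUE)
#' @param samples_to_exclude,samples_to_process optional sample filters
#' @return a `RunConfig` list
#' @export
run_config <- function(input, target_dir,
                       file_type = "ascat", ref_build = "hg19",
                       centromere_file = NULL,
                       window_size = 2e6, window_percent = NULL,
                       ploidy_file = NULL, use_custom_ploidies = TRUE,
                       run_gistic = FALSE, small_mem = FALSE,
                       r_color_file = NULL, output_format = NULL,
                       loh_to_plot = "cn-LOH",
                       use_full_resolution = TRUE,
                       use_relative_for_clustering = FALSE,
                       keep_genomic_pos = TRUE,
                       sample_file = NULL, feature = NULL,
                       plot_all = TRUE,
                       samples_to_exclude = NULL,
                       samples_to_process = NULL) {
  if (!is.null(window_percent) && !missing(window_size))
    stop("window_size and window_percent are mutually exclusive")
  structure(as.list(environment()), class = "RunConfig")
}

#' Run the full cohort analysis
#'
#' Wires the modules end to end: parse segments, resolve ploidies, build
#' the windowed matrices, the base-resolution segment matrix and its
#' classification, the frequency tracks, the clusterings, and every text
#' export (plus plots when requested).  All outputs land in
#' `config$target_dir`; a `run.log` records each stage with its row
#' counts.  Re-running with identical inputs produces byte-identical
#' text outputs.
#'
#' @param config a [run_config()]
#' @return invisibly, a list of the main in-memory results
#' @export
run_cohort_analysis <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$target_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$target_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  build <- if (inherits(config$ref_build, "GenomeBuild")) config$ref_build
           else load_build(config$ref_build, config$centromere_file)
  say("stage=build name=", build$build_name,
      " chromosomes=", nrow(build$chromosomes))

  segs <- if (inherits(config$input, "SegmentSet")) config$input
          else parse_segments(config$input, config$file_type, build)
  if (!is.null(config$samples_to_exclude) ||
      !is.null(config$samples_to_process)) {
    keep <- segs$samples
    if (!is.null(config$samples_to_process))
      keep <- intersect(keep, config$samples_to_process)
    if (!is.null(config$samples_to_exclude))
      keep <- setdiff(keep, config$samples_to_exclude)
    if (length(keep) == 0L) stop("sample filters removed every sample")
    segs <- segment_set(
      segs$segments[segs$segments$sample %in% keep, , drop = FALSE])
  }
  n <- length(segs$samples)
  say("stage=parse segments=", nrow(segs$segments), " samples=", n)

  custom <- if (is.null(config$ploidy_file)) NULL
            else read_ploidy_table(config$ploidy_file, segs$samples)
  ploidies <- resolve_ploidies(segs, build, custom,
                               use_estimator = config$use_custom_ploidies)
  write_tsv_file(data.frame(sample = names(ploidies), ploidy = ploidies),
                 file.path(config$target_dir, "ploidies.tsv"))
  say("stage=ploidy estimated=", sum(!names(ploidies) %in% names(custom)))

  windows <- if (is.null(config$window_percent))
    make_windows(build, size = config$window_size)
  else make_windows(build, size = NULL, percent = config$window_percent)
  m_abs <- build_cnv_matrix(segs, windows, ploidies, fill = "ploidy")
  m_rel <- to_relative(m_abs, ploidies)
  export_cnv_matrix(m_abs, file.path(config$target_dir, "cnv_matrix.tsv"))
  export_cnv_matrix(m_rel,
                    file.path(config$target_dir, "cnv_matrix_relative.tsv"))
  say("stage=matrix windows=", nrow(windows))

  ms <- classify_cells(build_segment_matrix(segs), ploidies)
  export_segment_matrix(ms,
                        file.path(config$target_dir, "segment_matrix.tsv"))
  say("stage=segments pieces=", nrow(ms$segments),
      " cells=", nrow(ms$cells))

  hist_table <- if (config$use_full_resolution)
    compute_stacked_frequencies(ms, n, "full")
  else compute_stacked_frequencies(m_rel, n, "windowed")
  export_event_text(hist_table,
                    file.path(config$target_dir, "cnv_events.tsv"))
  loh <- compute_loh_tracks(ms, config$loh_to_plot, n)
  write_tsv_file(loh, file.path(config$target_dir, "loh_tracks.tsv"))
  hethom <- compute_hethom_frequencies(ms, n)
  write_tsv_file(hethom[, setdiff(names(hethom), "samples")],
                 file.path(config$target_dir, "hethom_events.tsv"))
  say("stage=histogram rows=", nrow(hist_table), " loh_rows=", nrow(loh))

  m_clust <- if (config$use_relative_for_clustering) m_rel else m_abs
  hc <- ward_linkage(m_clust, on = "rows")
  export_newick(hc, file.path(config$target_dir, "dendrogram.nwk"))
  sample_table <- if (is.null(config$sample_file)) NULL
                  else read_sample_table(config$sample_file)
  layouts <- build_heatmap(m_clust, sample_table, config$feature,
                           cluster_windows = !config$keep_genomic_pos)
  say("stage=clustering leaves=", length(hc$order),
      " heatmaps=", length(layouts))

  if (config$run_gistic) {
    export_gistic_segments(segs,
                           file.path(config$target_dir, "gistic_input.seg"))
    say("stage=gistic wrote gistic_input.seg; ",
        "the external GISTIC tool is not bundled and must be run separately")
  }

  if (config$plot_all) {
    colors <- read_color_file(config$r_color_file)
    fmts <- parse_output_format(config$output_format)
    render <- function(key, fname, expr) {
      f <- fmts[[key]]
      path <- file.path(config$target_dir, paste0(fname, ".", f$format))
      open_device(path, f$format, f$width, f$height, f$res)
      on.exit(grDevices::dev.off(), add = TRUE)
      force(expr)
    }
    render("hist", "stacked_histogram",
           plot_stacked_histogram(hist_table, build, loh, colors))
    render("hetHom", "hethom_histogram",
           plot_hethom_histogram(hethom, build, colors))
    render("dend", "dendrogram",
           plot_sample_dendrogram(hc, layouts[[1]]$labels))
    for (i in seq_along(layouts)) {
      nm <- if (is.null(layouts[[i]]$feature)) "heatmap"
            else paste0("heatmap_", layouts[[i]]$feature)
      render("heat", nm, plot_heatmap_layout(layouts[[i]]))
    }
    say("stage=plots formats=",
        paste(vapply(fmts, `[[`, character(1), "format"), collapse = ","))
  }

  writeLines(log_lines, log_path)
  invisible(list(build = build, segments = segs, ploidies = ploidies,
                 windows = windows, matrix = m_abs,
                 matrix_relative = m_rel, segment_matrix = ms,
                 histogram = hist_table, loh = loh, hethom = hethom,
                 dendrogram = hc, heatmaps = layouts))
}

## default device settings per plot kind, overridable by a format string
## "hist:png(width=4000,height=1800,res=300);heat:pdf(width=10,height=12)"
parse_output_format <- function(spec = NULL) {
  defaults <- list(
    hist = list(format = "png", width = 4000, height = 1800, res = 300),
    hetHom = list(format = "png", width = 4000, height = 1800, res = 300),
    dend = list(format = "png", width = 4000, height = 2200, res = 300),
    heat = list(format = "pdf", width = 10, height = 12, res = NA))
  if (is.null(spec) || !nzchar(spec)) return(defaults)
  for (part in strsplit(spec, ";", fixed = TRUE)[[1]]) {
    m <- regmatches(part,
                    regexec("^\\s*(\\w+):(\\w+)\\(([^)]*)\\)\\s*$", part))[[1]]
    if (length(m) != 4L) {
      warning("cannot parse output-format entry '", part, "'; using default")
      next
    }
    key <- m[2]
    if (!key %in% names(defaults)) {
      warning("unknown plot key '", key, "' in output format; ignored")
      next
    }
    f <- defaults[[key]]
    f$format <- m[3]
    for (kv in strsplit(m[4], ",", fixed = TRUE)[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(p) == 2L && trimws(p[1]) %in% c("width", "height", "res"))
        f[[trimws(p[1])]] <- as.numeric(p[2])
    }
    defaults[[key]] <- f
  }
  defaults
}
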