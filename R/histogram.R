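#' Stacked copy-number frequency table
#'
#' For every segment of a classified [build_segment_matrix()] (full
#' resolution, the default) or every window of a relative [CNVMatrix]
#' computes, per relative copy-number category c in -4..+6 (c != 0), the
#' percentage of cohort samples carrying that category there, together
#' with the explicit sample list.  The denominator is always the full
#' cohort size N; samples without a call at a segment count in no
#' category.  Neutral (c = 0) rows are computed too and flagged, so
#' callers may drop them from the stacked plot.
#'
#' @param ms a classified `SegmentMatrix`, or a relative `CNVMatrix` when
#'   `resolution = "windowed"`
#' @param n_samples cohort size N (defaults to the number of samples in
#'   `ms`)
#' @param resolution `"full"` (base-resolution segments) or `"windowed"`
#' @param drop_empty drop zero-count rows (default TRUE)
#' @return a `HistogramTable`: data.frame `chrom`, `start`, `end`,
#'   `category` (integer -4..+6), `count`, `pct`, `samples`
#'   (comma-joined)
#' @export
compute_stacked_frequencies <- function(ms, n_samples = NULL,
                                        resolution = c("full", "windowed"),
                                        drop_empty = TRUE) {
  resolution <- match.arg(resolution)
  if (resolution == "full") {
    stopifnot(inherits(ms, "SegmentMatrix"))
    if (is.null(ms$cells$rel))
      stop("segment matrix must be classified first (classify_cells)")
    if (is.null(n_samples)) n_samples <- length(ms$samples)
    long <- data.frame(segment = ms$cells$segment,
                       sample = ms$cells$sample,
                       category = ms$cells$rel)
    coords <- ms$segments
  } else {
    stopifnot(inherits(ms, "CNVMatrix"))
    if (ms$flavor != "relative")
      stop("windowed histograms need a relative CNVMatrix")
    if (is.null(n_samples)) n_samples <- nrow(ms$values)
    long <- data.frame(
      segment = rep(seq_len(ncol(ms$values)), each = nrow(ms$values)),
      sample = rep(rownames(ms$values), times = ncol(ms$values)),
      category = as.vector(ms$values))
    coords <- data.frame(chrom = ms$windows$chrom,
                         start = ms$windows$start, end = ms$windows$end,
                         segment = seq_len(nrow(ms$windows)))
  }
  if (n_samples < 1L) stop("empty cohort")
  tally_categories(long, coords, n_samples, drop_empty)
}

tally_categories <- function(long, coords, n_samples, drop_empty) {
  grp <- interaction(long$segment, long$category, drop = TRUE)
  agg <- data.frame(
    segment = as.integer(tapply(long$segment, grp, `[`, 1)),
    category = as.integer(tapply(long$category, grp, `[`, 1)),
    count = as.integer(tapply(long$sample, grp, length)),
    samples = vapply(split(long$sample, grp),
                     function(s) paste(sort(s), collapse = ","),
                     character(1)))
  agg$pct <- 100 * agg$count / n_samples
  i <- match(agg$segment, coords$segment)
  out <- data.frame(chrom = coords$chrom[i], start = coords$start[i],
                    end = coords$end[i], category = agg$category,
                    count = agg$count, pct = agg$pct,
                    samples = agg$samples)
  if (drop_empty) out <- out[out$count > 0L, , drop = FALSE]
  lev <- chrom_order(out$chrom)
  out <- out[order(factor(out$chrom, levels = lev), out$start,
                   out$category), ]
  rownames(out) <- NULL
  attr(out, "n_samples") <- n_samples
  class(out) <- c("HistogramTable", "data.frame")
  out
}

#' Display binning of gain categories
#'
#' Collapses relative gains of +4..+6 into a single `">=+4"` bin for
#' plotting and region comparison, keeping losses -1..-4 and gains
#' +1..+3 as-is.
#'
#' @param category integer vector of relative categories
#' @return character vector of display bins (`"0"` for neutral)
#' @export
display_bin <- function(category) {
  ifelse(category >= 4, ">=+4",
  ifelse(category > 0, paste0("+", category),
         as.character(category)))
}

#' Cohort LOH / cn-LOH line tracks
#'
#' Per segment, the percentage of cohort samples flagged copy-neutral LOH
#' (drawn as a black line) and/or LOH (blue line).  Following the plot
#' convention these lines live in negative ordinates, so `value` is the
#' negated percentage.
#'
#' @param ms a classified `SegmentMatrix`
#' @param mode `"cn-LOH"`, `"LOH"`, `"both"` or `"none"`
#' @param n_samples cohort size N (defaults to samples in `ms`)
#' @return data.frame `chrom`, `start`, `end`, `track`, `count`, `pct`,
#'   `value` (= -pct); zero rows when `mode = "none"`
#' @export
compute_loh_tracks <- function(ms, mode = c("cn-LOH", "LOH", "both", "none"),
                               n_samples = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ms, "SegmentMatrix"))
  if (is.null(ms$cells$is_loh))
    stop("segment matrix must be classified first (classify_cells)")
  if (is.null(n_samples)) n_samples <- length(ms$samples)
  tracks <- switch(mode, `cn-LOH` = "cn-LOH", LOH = "LOH",
                   both = c("cn-LOH", "LOH"), none = character())
  out <- lapply(tracks, function(tr) {
    flag <- if (tr == "cn-LOH") ms$cells$is_cn_loh else ms$cells$is_loh
    cnt <- tapply(flag, factor(ms$cells$segment,
                               levels = ms$segments$segment), sum)
    cnt[is.na(cnt)] <- 0
    data.frame(chrom = ms$segments$chrom, start = ms$segments$start,
               end = ms$segments$end, track = tr,
               count = as.integer(cnt), pct = 100 * as.integer(cnt) / n_samples,
               value = -100 * as.integer(cnt) / n_samples)
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               track = character(), count = integer(), pct = numeric(),
               value = numeric())
  rownames(out) <- NULL
  out
}

#' Heterozygous/homozygous CNV frequency table
#'
#' Per segment, six stacked percentages crossing zygosity (heterozygous:
#' both alleles retained; homozygous: at least one allele null) with the
#' net state (gain / neutral / loss vs the sample ploidy).  Gains and
#' neutral events are drawn in positive ordinates, losses negative:
#' `value` carries that sign.
#'
#' @param ms a classified `SegmentMatrix`
#' @param n_samples cohort size N (defaults to samples in `ms`)
#' @param drop_empty drop zero-count rows (default TRUE)
#' @return data.frame `chrom`, `start`, `end`, `zygosity`, `state`,
#'   `count`, `pct`, `value`, `samples`
#' @export
compute_hethom_frequencies <- function(ms, n_samples = NULL,
                                       drop_empty = TRUE) {
  stopifnot(inherits(ms, "SegmentMatrix"))
  if (is.null(ms$cells$state))
    stop("segment matrix must be classified first (classify_cells)")
  if (is.null(n_samples)) n_samples <- length(ms$samples)
  zyg <- ifelse(ms$cells$is_heterozygous, "het", "hom")
  grp <- interaction(ms$cells$segment, zyg, ms$cells$state, drop = TRUE)
  agg <- data.frame(
    segment = as.integer(tapply(ms$cells$segment, grp, `[`, 1)),
    zygosity = as.character(tapply(zyg, grp, `[`, 1)),
    state = as.character(tapply(ms$cells$state, grp, `[`, 1)),
    count = as.integer(tapply(zyg, grp, length)),
    samples = vapply(split(ms$cells$sample, grp),
                     function(s) paste(sort(s), collapse = ","),
                     character(1)))
  agg$pct <- 100 * agg$count / n_samples
  agg$value <- ifelse(agg$state == "loss", -agg$pct, agg$pct)
  i <- match(agg$segment, ms$segments$segment)
  out <- data.frame(chrom = ms$segments$chrom[i],
                    start = ms$segments$start[i],
                    end = ms$segments$end[i],
                    zygosity = agg$zygosity, state = agg$state,
                    count = agg$count, pct = agg$pct, value = agg$value,
                    samples = agg$samples)
  if (drop_empty) out <- out[out$count > 0L, , drop = FALSE]
  lev <- chrom_order(out$chrom)
  out <- out[order(factor(out$chrom, levels = lev), out$start,
                   out$zygosity, out$state), ]
  rownames(out) <- NULL
  attr(out, "n_samples") <- n_samples
  out
}

#' Export a histogram table as tab-delimited text
#'
#' One row per (segment, category) with the percentage and the
#' comma-joined list of carrier samples, sorted genomically then by
#' category; zero-count rows are omitted.  [read_event_text()] parses
#' the export back.
#'
#' @param h a [compute_stacked_frequencies()] table
#' @param out output path
#' @return the path, invisibly
#' @export
export_event_text <- function(h, out) {
  stopifnot(inherits(h, "HistogramTable"))
  df <- as.data.frame(h[h$count > 0L,
                        c("chrom", "start", "end", "category", "count",
                          "pct", "samples")])
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  write_tsv_file(df, out)
}

#' @rdname export_event_text
#' @param path an [export_event_text()] file
#' @param n_samples cohort size N used to recompute percentages
#' @export
read_event_text <- function(path, n_samples) {
  df <- read_tsv_file(path)
  attr(df, "n_samples") <- n_samples
  class(df) <- c("HistogramTable", "data.frame")
  df
}
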