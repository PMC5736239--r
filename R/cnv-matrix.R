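#' Windowed copy-number matrices
#'
#' A `CNVMatrix` holds one integer copy-number value per (sample, window):
#' rows are samples, columns the windows of a [make_windows()] partition.
#' The `flavor` records whether values are absolute copy numbers or
#' relative to each sample's ploidy (see [to_relative()]).
#'
#' @name CNVMatrix
NULL

new_cnv_matrix <- function(values, windows, flavor) {
  structure(list(values = values, windows = windows, flavor = flavor),
            class = "CNVMatrix")
}

#' @export
print.CNVMatrix <- function(x, ...) {
  cat("CNVMatrix (", x$flavor, "): ", nrow(x$values), " samples x ",
      ncol(x$values), " windows\n", sep = "")
  invisible(x)
}

#' Build the windowed copy-number matrix
#'
#' For every sample and window, each base of the window gets a copy
#' number: the calling segment's total copy number where one exists,
#' otherwise the fill value (the sample's ploidy by default, or a fixed
#' value such as 2 for the ploidy-estimation matrix).  The window entry
#' is the length-weighted mean over the window's bases, rounded to the
#' nearest integer (half away from zero).
#'
#' @param segs a [segment_set()]
#' @param windows a [make_windows()] partition
#' @param ploidies named numeric vector of per-sample ploidies (required
#'   unless `fill` is numeric)
#' @param fill `"ploidy"` to fill uncovered bases with the sample's
#'   ploidy, or a single number used for every sample
#' @return a `CNVMatrix` with flavor `"absolute"`
#' @export
build_cnv_matrix <- function(segs, windows, ploidies = NULL,
                             fill = "ploidy") {
  stopifnot(inherits(segs, "SegmentSet"), inherits(windows, "WindowSet"))
  samples <- segs$samples
  if (identical(fill, "ploidy")) {
    if (is.null(ploidies)) stop("fill = \"ploidy\" needs a ploidy table")
    missing_p <- setdiff(samples, names(ploidies))
    if (length(missing_p) > 0L)
      stop("no ploidy for sample(s): ", paste(missing_p, collapse = ", "))
    fill_values <- ploidies[samples]
  } else {
    stopifnot(is.numeric(fill), length(fill) == 1L)
    fill_values <- stats::setNames(rep(fill, length(samples)), samples)
  }

  values <- matrix(NA_real_, nrow = length(samples), ncol = nrow(windows),
                   dimnames = list(samples, window_labels(windows)))
  seg_df <- segs$segments
  for (chrom in unique(windows$chrom)) {
    w <- windows[windows$chrom == chrom, , drop = FALSE]
    d <- seg_df[seg_df$chrom == chrom, , drop = FALSE]
    values[, w$index] <- window_means_chrom(w, d, samples, fill_values)
  }
  new_cnv_matrix(round_half_away(values), windows, "absolute")
}

## Length-weighted window means on one chromosome.  The chromosome is cut
## into "atoms" at every window or segment boundary, so no atom straddles
## a window or any sample's segment; per sample the atom value is the
## covering call's total copy number, else the fill, and window means are
## length-weighted sums over atoms.
window_means_chrom <- function(w, d, samples, fill_values) {
  bp <- sort(unique(c(w$start, w$end, d$start, d$end)))
  a_start <- bp[-length(bp)]
  a_end <- bp[-1]
  ## window containing each atom; NA outside all windows (centromere gap
  ## or beyond the tiled range)
  wi <- findInterval(a_start, w$start)
  ok <- wi >= 1 & a_start < w$end[pmax(wi, 1)]
  a_start <- a_start[ok]; a_end <- a_end[ok]; wi <- wi[ok]
  a_len <- a_end - a_start
  win_len <- as.vector(rowsum(a_len, wi))

  out <- matrix(NA_real_, nrow = length(samples), ncol = nrow(w))
  for (si in seq_along(samples)) {
    ds <- d[d$sample == samples[si], , drop = FALSE]
    val <- rep(fill_values[[samples[si]]], length(a_start))
    if (nrow(ds) > 0L) {
      j <- findInterval(a_start, ds$start)
      hit <- j >= 1 & a_start < ds$end[pmax(j, 1)]
      val[hit] <- ds$total_cn[j[hit]]
    }
    out[si, ] <- as.vector(rowsum(val * a_len, wi)) / win_len
  }
  out
}

#' Convert an absolute matrix to relative copy numbers
#'
#' Subtracts each sample's ploidy from its entries: a value of 0 means no
#' net change, negative values are losses (bounded below by -ploidy,
#' clamped at -4) and positive values gains (unbounded, clamped at +6 to
#' keep downstream categories readable).  Rounding is half away from
#' zero, which matters only for tie-averaged non-integer ploidies.
#'
#' @param m an absolute `CNVMatrix`
#' @param ploidies named numeric vector covering every sample of `m`
#' @return a `CNVMatrix` with flavor `"relative"`
#' @export
to_relative <- function(m, ploidies) {
  stopifnot(inherits(m, "CNVMatrix"))
  if (m$flavor != "absolute")
    stop("to_relative() expects an absolute matrix, got flavor '",
         m$flavor, "'")
  samples <- rownames(m$values)
  missing_p <- setdiff(samples, names(ploidies))
  if (length(missing_p) > 0L)
    stop("no ploidy for sample(s): ", paste(missing_p, collapse = ", "))
  rel <- clamp(round_half_away(m$values - ploidies[samples]), -4, 6)
  new_cnv_matrix(rel, m$windows, "relative")
}

#' Export a CNVMatrix as tab-delimited text
#'
#' One row per sample, one column per window labelled `chrom:start-end`.
#'
#' @param m a `CNVMatrix`
#' @param out output path
#' @return the path, invisibly
#' @export
export_cnv_matrix <- function(m, out) {
  stopifnot(inherits(m, "CNVMatrix"))
  df <- data.frame(sample = rownames(m$values), m$values,
                   check.names = FALSE)
  write_tsv_file(df, out)
}
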