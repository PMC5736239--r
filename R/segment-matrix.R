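#' Base-resolution segment matrix
#'
#' A `SegmentMatrix` partitions the genome at the union of all samples'
#' segment breakpoints: the resulting pieces are non-overlapping, sorted,
#' and their union equals the union of all input calls.  Each input call
#' is split across the pieces it covers, copying its allele-specific copy
#' numbers; a sample with no call over a piece is simply absent there (no
#' fill is applied at base resolution).
#'
#' @param segs a [segment_set()]
#' @param coalesce merge adjacent pieces whose full set of sample cells is
#'   identical (default TRUE; frequency-preserving)
#' @return an object of class `SegmentMatrix` with elements `segments`
#'   (data.frame `chrom`, `start`, `end`, `segment`), `cells` (data.frame
#'   `segment`, `sample`, `n_major`, `n_minor`, `total_cn`), `samples`
#' @export
build_segment_matrix <- function(segs, coalesce = TRUE) {
  stopifnot(inherits(segs, "SegmentSet"))
  df <- segs$segments
  check_no_overlap(df)
  lev <- chrom_order(df$chrom)

  per_chrom <- lapply(lev, function(chrom) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    bp <- sort(unique(c(d$start, d$end)))
    p_start <- bp[-length(bp)]
    p_end <- bp[-1]
    ## keep only pieces covered by at least one call
    cover <- vapply(seq_along(p_start), function(k)
      any(d$start <= p_start[k] & d$end >= p_end[k]), logical(1))
    pieces <- data.frame(chrom = chrom, start = p_start[cover],
                         end = p_end[cover])
    ## split each call across the pieces it covers
    cells <- lapply(seq_len(nrow(d)), function(r) {
      k <- which(pieces$start >= d$start[r] & pieces$end <= d$end[r])
      if (length(k) == 0L) return(NULL)
      data.frame(chrom = chrom, start = pieces$start[k],
                 sample = d$sample[r], n_major = d$n_major[r],
                 n_minor = d$n_minor[r], total_cn = d$total_cn[r])
    })
    list(pieces = pieces, cells = do.call(rbind, cells))
  })

  segments <- do.call(rbind, lapply(per_chrom, `[[`, "pieces"))
  cells <- do.call(rbind, lapply(per_chrom, `[[`, "cells"))
  segments$segment <- seq_len(nrow(segments))
  key <- paste(segments$chrom, segments$start)
  cells$segment <- segments$segment[match(paste(cells$chrom, cells$start),
                                          key)]
  cells <- cells[order(cells$segment, cells$sample),
                 c("segment", "sample", "n_major", "n_minor", "total_cn")]
  rownames(segments) <- rownames(cells) <- NULL
  ms <- structure(list(segments = segments[, c("chrom", "start", "end",
                                               "segment")],
                       cells = cells, samples = segs$samples),
                  class = "SegmentMatrix")
  if (coalesce) coalesce_segments(ms) else ms
}

## Merge runs of adjacent pieces whose per-sample cells are identical.
## Adjacency requires same chromosome and end == next start, so merging
## never bridges an uncovered gap; every cohort frequency is unchanged.
coalesce_segments <- function(ms) {
  seg <- ms$segments
  sig <- vapply(split(ms$cells[, c("sample", "n_major", "n_minor")],
                      factor(ms$cells$segment, levels = seg$segment)),
                function(d) paste(d$sample, d$n_major, d$n_minor,
                                  collapse = ";"),
                character(1))
  adjacent <- c(FALSE, seg$chrom[-1] == seg$chrom[-nrow(seg)] &
                  seg$start[-1] == seg$end[-nrow(seg)])
  same <- c(FALSE, sig[-1] == sig[-length(sig)])
  group <- cumsum(!(adjacent & same))
  new_seg <- data.frame(
    chrom = tapply(seg$chrom, group, `[`, 1),
    start = as.numeric(tapply(seg$start, group, `[`, 1)),
    end = as.numeric(tapply(seg$end, group, function(e) e[length(e)])),
    segment = seq_len(max(group)))
  first_old <- tapply(seg$segment, group, `[`, 1)
  keep <- ms$cells$segment %in% first_old
  cells <- ms$cells[keep, , drop = FALSE]
  cells$segment <- match(cells$segment, first_old)
  rownames(new_seg) <- rownames(cells) <- NULL
  structure(list(segments = new_seg, cells = cells, samples = ms$samples),
            class = "SegmentMatrix")
}

#' @export
print.SegmentMatrix <- function(x, ...) {
  cat("SegmentMatrix: ", nrow(x$segments), " segments x ",
      length(x$samples), " samples (", nrow(x$cells), " cells)\n", sep = "")
  invisible(x)
}

#' Classify every cell of a segment matrix
#'
#' Adds event annotations to each (sample, segment) cell, relative to the
#' sample's ploidy p:
#' \itemize{
#'   \item `rel`: total copy number minus p, rounded half away from zero
#'     and clamped to \[-4, +6\];
#'   \item `state`: `"gain"` / `"neutral"` / `"loss"` comparing the total
#'     to round(p) (no net change means the total equals the ploidy);
#'   \item `is_cn_loh`: one allele has no copies and the other exactly
#'     round(p) copies — copy-neutral LOH;
#'   \item `is_loh`: the minor allele has no copies while at least one
#'     copy is retained (cn-LOH implies LOH);
#'   \item `is_homozygous` / `is_heterozygous`: whether at least one
#'     allele has zero copies, or both are non-null.
#' }
#' A homozygous total deletion (0,0) is a homozygous loss but not LOH:
#' no allele is retained.  With a non-integer (tie-averaged) ploidy, the
#' integer comparisons use round(p).
#'
#' @param ms a [build_segment_matrix()] result
#' @param ploidies named numeric vector covering every sample
#' @return the `SegmentMatrix` with annotated `cells`
#' @export
classify_cells <- function(ms, ploidies) {
  stopifnot(inherits(ms, "SegmentMatrix"))
  missing_p <- setdiff(ms$samples, names(ploidies))
  if (length(missing_p) > 0L)
    stop("no ploidy for sample(s): ", paste(missing_p, collapse = ", "))
  cells <- ms$cells
  p <- ploidies[cells$sample]
  rp <- round_half_away(p)
  cells$rel <- clamp(round_half_away(cells$total_cn - p), -4, 6)
  cells$state <- c("loss", "neutral", "gain")[
    sign(cells$total_cn - rp) + 2]
  cells$is_loh <- cells$n_minor == 0 & cells$n_major >= 1
  cells$is_cn_loh <- cells$is_loh & cells$n_major == rp
  cells$is_homozygous <- pmin(cells$n_major, cells$n_minor) == 0
  cells$is_heterozygous <- !cells$is_homozygous
  ms$cells <- cells
  ms$ploidies <- ploidies[ms$samples]
  ms
}

#' Export a segment matrix as tab-delimited text
#'
#' One row per (segment, sample) cell with coordinates, copy numbers and,
#' when present, the classification flags.
#'
#' @param ms a `SegmentMatrix`
#' @param out output path
#' @return the path, invisibly
#' @export
export_segment_matrix <- function(ms, out) {
  stopifnot(inherits(ms, "SegmentMatrix"))
  seg <- ms$segments[match(ms$cells$segment, ms$segments$segment), ]
  df <- cbind(seg[, c("chrom", "start", "end")],
              ms$cells[, setdiff(names(ms$cells), "segment")])
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  write_tsv_file(df, out)
}
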