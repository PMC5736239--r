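#' Partition a genome build into non-overlapping windows
#'
#' Each chromosome is tiled from position 0 with windows of length `size`
#' bp (or, in percent mode, `percent`% of that chromosome's length, rounded
#' down to an integer bp).  Windows never overlap the chromosome's
#' centromere: a window straddling the centromere is replaced by its arm
#' pieces, and any piece shorter than half the window length — including
#' the chromosome-terminal remainder — is merged into its nearest
#' contiguous window on the same arm (the upstream neighbour when both
#' exist), so that all windows are of comparable size.  An entire arm
#' shorter than half a window still yields one window.
#'
#' @param build a [genome_build()]
#' @param size window length L in bp (default 2 Mb)
#' @param percent window length as a percentage of each chromosome's
#'   length; mutually exclusive with `size`
#' @return a `WindowSet`: data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and genome-wide ordinal `index`
#' @examples
#' b <- genome_build(data.frame(chrom = "c1", length = 1e7),
#'                   data.frame(chrom = "c1", start = 4.5e6, end = 5.5e6))
#' make_windows(b, size = 2e6)
#' @export
make_windows <- function(build, size = 2e6, percent = NULL) {
  stopifnot(inherits(build, "GenomeBuild"))
  if (nrow(build$chromosomes) == 0L) stop("empty genome build")
  if (!is.null(percent)) {
    if (!missing(size) && !is.null(size))
      stop("give either `size` or `percent`, not both")
    if (percent <= 0 || percent > 100)
      stop("`percent` must be in (0, 100]")
  } else {
    if (is.null(size) || size <= 0) stop("window size must be positive")
    if (all(size > build$chromosomes$length))
      stop("window size exceeds the length of every chromosome")
  }

  pieces <- lapply(seq_len(nrow(build$chromosomes)), function(i) {
    chrom <- build$chromosomes$chrom[i]
    len <- build$chromosomes$length[i]
    L <- if (is.null(percent)) size else max(1, floor(percent / 100 * len))
    tile_chromosome(chrom, len, L, centromere_of(build, chrom))
  })
  out <- do.call(rbind, pieces)
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("WindowSet", "data.frame")
  attr(out, "build_name") <- build$build_name
  out
}

## Tile one chromosome: regular L tiling, centromere trim, then the
## < L/2 merge rule applied independently on each arm.
tile_chromosome <- function(chrom, len, L, cent) {
  starts <- seq(0, len - 1, by = L)
  ends <- pmin(starts + L, len)
  w <- data.frame(start = starts, end = ends)

  if (!is.null(cent)) {
    keep <- list()
    for (k in seq_len(nrow(w))) {
      s <- w$start[k]; e <- w$end[k]
      if (e <= cent["start"] || s >= cent["end"]) {        # no overlap
        keep[[length(keep) + 1L]] <- c(s, e)
      } else {                                              # trim W - E
        if (s < cent["start"])
          keep[[length(keep) + 1L]] <- c(s, cent[["start"]])
        if (e > cent["end"])
          keep[[length(keep) + 1L]] <- c(cent[["end"]], e)
      }
    }
    if (length(keep) == 0L)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric()))
    w <- as.data.frame(do.call(rbind, keep))
    names(w) <- c("start", "end")
  }

  ## split into arms: pieces are contiguous unless separated by a gap
  ## (the centromere); merge undersized pieces within each arm only
  arm_id <- cumsum(c(1, as.integer(w$start[-1] != w$end[-nrow(w)])))
  merged <- lapply(split(w, arm_id), merge_small_pieces, min_len = L / 2)
  w <- do.call(rbind, merged)
  w <- w[order(w$start), , drop = FALSE]
  data.frame(chrom = chrom, start = w$start, end = w$end)
}

## Merge every piece shorter than min_len into its upstream contiguous
## neighbour (downstream when it is the first piece of the arm).  A
## single-piece arm is kept whatever its length.
merge_small_pieces <- function(arm, min_len) {
  repeat {
    if (nrow(arm) <= 1L) return(arm)
    short <- which(arm$end - arm$start < min_len)
    if (length(short) == 0L) return(arm)
    k <- short[1]
    if (k > 1L) {                       # upstream neighbour preferred
      arm$end[k - 1L] <- arm$end[k]
      arm <- arm[-k, , drop = FALSE]
    } else {
      arm$start[2L] <- arm$start[1L]
      arm <- arm[-1L, , drop = FALSE]
    }
  }
}

#' @export
print.WindowSet <- function(x, ...) {
  cat("WindowSet: ", nrow(x), " windows over ",
      length(unique(x$chrom)), " chromosomes\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

window_labels <- function(windows) {
  sprintf("%s:%d-%d", windows$chrom, as.integer(windows$start),
          as.integer(windows$end))
}
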