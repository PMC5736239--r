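#' Tabulate gain categories of two genomic regions
#'
#' For each region and each sample, the sample's region-level category is
#' the length-weighted modal display category over the region: every
#' classified cell overlapping the region contributes its overlap length
#' to its category (losses and neutral pool into `"no gain"`, gains into
#' `"+1"`, `"+2"`, `"+3"`, `">=+4"`); bases of the region where the
#' sample has no call count as `"no gain"` (no call means baseline).
#' Ties in the weighted mode resolve to the higher gain category.  The
#' result is a categories x 2 contingency table of sample counts, ready
#' for [fisher_exact()].
#'
#' @param ms a classified [build_segment_matrix()]
#' @param region_a,region_b region strings `"chrom:start-end"` (0-based
#'   half-open) or [parse_region()] lists
#' @param include_no_gain keep the `"no gain"` row (default TRUE);
#'   with FALSE, samples whose modal category is not a gain are dropped
#'   from that region's column
#' @param aggregate how a sample's per-cell categories collapse to one
#'   region category: `"mode"` (length-weighted mode, the default) or
#'   `"max"` (highest gain category touched anywhere in the region)
#' @return a `ContingencyTable`: integer matrix with gain-category rows
#'   and one column per region
#' @export
gain_category_table <- function(ms, region_a, region_b,
                                include_no_gain = TRUE,
                                aggregate = c("mode", "max")) {
  stopifnot(inherits(ms, "SegmentMatrix"))
  aggregate <- match.arg(aggregate)
  if (is.null(ms$cells$rel))
    stop("segment matrix must be classified first (classify_cells)")
  regions <- list(a = as_region(region_a), b = as_region(region_b))
  bins <- c("no gain", "+1", "+2", "+3", ">=+4")
  counts <- vapply(regions, function(rg) {
    cat_per_sample <- region_sample_category(ms, rg, bins, aggregate)
    tab <- table(factor(cat_per_sample, levels = bins))
    as.integer(tab)
  }, integer(length(bins)))
  rownames(counts) <- bins
  colnames(counts) <- vapply(regions, function(rg)
    sprintf("%s:%d-%d", rg$chrom, as.integer(rg$start),
            as.integer(rg$end)), character(1))
  if (!include_no_gain) counts <- counts[-1, , drop = FALSE]
  structure(counts, class = c("ContingencyTable", class(counts)))
}

as_region <- function(x) if (is.character(x)) parse_region(x) else x

#' @export
print.ContingencyTable <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

## per-sample region category: length-weighted mode (or maximum) of the
## display bins over the region
region_sample_category <- function(ms, rg, bins, aggregate = "mode") {
  seg <- ms$segments
  ov_len <- pmin(seg$end, rg$end) - pmax(seg$start, rg$start)
  hit <- seg$chrom == rg$chrom & ov_len > 0
  if (!any(hit)) stop("region overlaps no segment: ", rg$chrom, ":",
                      rg$start, "-", rg$end)
  seg_w <- stats::setNames(ov_len[hit], seg$segment[hit])
  cells <- ms$cells[ms$cells$segment %in% seg$segment[hit], , drop = FALSE]
  cells$bin <- ifelse(cells$rel <= 0, "no gain", display_bin(cells$rel))
  cells$w <- seg_w[as.character(cells$segment)]
  region_len <- rg$end - rg$start

  vapply(ms$samples, function(s) {
    d <- cells[cells$sample == s, , drop = FALSE]
    if (aggregate == "max") {
      gains <- d$bin[d$bin != "no gain"]
      return(if (length(gains) == 0L) "no gain"
             else bins[max(match(gains, bins))])
    }
    w <- tapply(d$w, factor(d$bin, levels = bins), sum)
    w[is.na(w)] <- 0
    ## uncovered bases of the region mean no call, hence baseline
    w["no gain"] <- w["no gain"] + (region_len - sum(d$w))
    best <- which(w == max(w))
    bins[best[length(best)]]         # tie -> highest gain category
  }, character(1))
}

#' Fisher exact test on a contingency table
#'
#' Two-sided exact test.  For 2x2 tables the p-value sums the
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one; for r x 2 tables the exact
#' conditional test enumerates the same-margin tables as long as the
#' grand total is at most `exact_limit`, beyond which a Monte-Carlo
#' estimate with `replicates` samples is used (fix the RNG seed upstream
#' for reproducibility).  Computation is delegated to
#' [stats::fisher.test()]; a degenerate table (a zero row/column margin)
#' returns p = 1 with a warning.
#'
#' @param tab a [gain_category_table()] result or any non-negative
#'   integer matrix with at least 2 rows and 2 columns
#' @param exact_limit largest grand total for the exact test
#'   (default 200)
#' @param replicates Monte-Carlo replicates above `exact_limit`
#' @return the p-value, with attributes `method` and (for Monte-Carlo)
#'   `replicates`
#' @export
fisher_exact <- function(tab, exact_limit = 200, replicates = 1e5) {
  x <- unclass(as.matrix(tab))
  storage.mode(x) <- "integer"
  if (any(x < 0)) stop("negative counts")
  keep_r <- rowSums(x) > 0; keep_c <- colSums(x) > 0
  if (!all(keep_r) || !all(keep_c)) {
    if (sum(keep_r) < 2L || sum(keep_c) < 2L) {
      warning("degenerate margins; p = 1")
      return(structure(1, method = "degenerate"))
    }
    x <- x[keep_r, keep_c, drop = FALSE]
  }
  if ((nrow(x) == 2L && ncol(x) == 2L) || sum(x) <= exact_limit) {
    ## 2x2 tables are always exact: the hypergeometric sum costs nothing
    p <- stats::fisher.test(x, hybrid = FALSE,
                            workspace = 2e7)$p.value
    structure(min(p, 1), method = "exact")
  } else {
    p <- stats::fisher.test(x, simulate.p.value = TRUE,
                            B = replicates)$p.value
    structure(p, method = "monte-carlo", replicates = replicates)
  }
}

#' Compare the gain categories of two regions
#'
#' Convenience wrapper chaining [gain_category_table()] and
#' [fisher_exact()], mirroring a comparison such as 1q vs 8q gains.
#'
#' @inheritParams gain_category_table
#' @inheritParams fisher_exact
#' @return list with elements `table` and `p.value`
#' @export
compare_regions <- function(ms, region_a, region_b, include_no_gain = TRUE,
                            exact_limit = 200, replicates = 1e5) {
  tab <- gain_category_table(ms, region_a, region_b, include_no_gain)
  list(table = tab,
       p.value = fisher_exact(tab, exact_limit, replicates))
}
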