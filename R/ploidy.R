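#' Estimate sample ploidies from windowed copy numbers
#'
#' Each sample's ploidy is the modal value of its windowed copy numbers,
#' computed on a coarse matrix with windows of 10% of each chromosome's
#' length and uncovered bases filled with a default copy number of 2
#' (at this window size the fill has little influence on the window
#' values).  Windows of all chromosomes are pooled.  When several values
#' tie for the highest frequency the ploidy is their arithmetic mean,
#' which can be non-integer (e.g. 2.5 for an exact diploid/triploid
#' split); downstream relative values round it half away from zero.
#'
#' @param segs a [segment_set()]
#' @param build the [genome_build()] the calls refer to
#' @param window_percent window length as percent of chromosome length
#'   (default 10)
#' @param default_fill copy number assumed for uncovered bases (default 2)
#' @return named numeric vector: one ploidy per sample
#' @export
estimate_ploidies <- function(segs, build, window_percent = 10,
                              default_fill = 2) {
  stopifnot(inherits(segs, "SegmentSet"), inherits(build, "GenomeBuild"))
  windows <- make_windows(build, size = NULL, percent = window_percent)
  if (nrow(windows) == 0L) stop("build produced no windows")
  mp <- build_cnv_matrix(segs, windows, fill = default_fill)
  apply(mp$values, 1, modal_value)
}

## mode of a vector; ties averaged
modal_value <- function(x) {
  tab <- table(x)
  tied <- as.numeric(names(tab)[tab == max(tab)])
  mean(tied)
}

#' Resolve the ploidies used by an analysis
#'
#' Combines the internal estimator with user-supplied values: entries of
#' `custom` override the estimate for their sample; remaining samples use
#' [estimate_ploidies()].  With `use_estimator = FALSE` every sample must
#' be covered by `custom`.
#'
#' @param segs a [segment_set()]
#' @param build a [genome_build()]
#' @param custom optional named numeric vector of user ploidies
#' @param use_estimator run the internal estimator for samples not in
#'   `custom` (default TRUE)
#' @return named numeric vector covering every sample of `segs`
#' @export
resolve_ploidies <- function(segs, build, custom = NULL,
                             use_estimator = TRUE) {
  samples <- segs$samples
  out <- stats::setNames(rep(NA_real_, length(samples)), samples)
  if (!is.null(custom)) {
    hit <- intersect(names(custom), samples)
    out[hit] <- custom[hit]
  }
  if (anyNA(out)) {
    if (!use_estimator)
      stop("no ploidy for sample(s): ",
           paste(names(out)[is.na(out)], collapse = ", "),
           " and the internal estimator is disabled")
    est <- estimate_ploidies(segs, build)
    out[is.na(out)] <- est[names(out)[is.na(out)]]
  }
  if (any(out <= 0)) stop("ploidies must be positive")
  out
}
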