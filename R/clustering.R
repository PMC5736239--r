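#' Ward-linkage hierarchical clustering of a copy-number matrix
#'
#' Clusters the samples (rows) or windows (columns) of a [CNVMatrix]
#' agglomeratively.  The default follows the historical "ward.D"
#' behaviour: Euclidean (unsquared) distances fed to Ward's
#' Lance-Williams update, via `stats::hclust`.  Both the distance and the
#' agglomeration method can be changed.
#'
#' @param m a `CNVMatrix`, or a plain numeric matrix
#' @param on `"rows"` (samples) or `"columns"` (windows)
#' @param dist_method distance passed to [stats::dist()] (default
#'   `"euclidean"`)
#' @param method agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D"`)
#' @return an object of class `hclust`
#' @export
ward_linkage <- function(m, on = c("rows", "columns"),
                         dist_method = "euclidean", method = "ward.D") {
  on <- match.arg(on)
  values <- if (inherits(m, "CNVMatrix")) m$values else as.matrix(m)
  if (on == "columns") values <- t(values)
  if (nrow(values) < 2L) stop("clustering needs at least 2 items")
  if (anyNA(values)) stop("matrix has missing values")
  stats::hclust(stats::dist(values, method = dist_method), method = method)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths derive from the merge heights, for downstream
#' inspection with standard tree tools.
#'
#' @param hc an `hclust` object
#' @param out output path
#' @return the path, invisibly
#' @export
export_newick <- function(hc, out) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = out)
  invisible(out)
}

#' Lay out one or more heatmaps of a copy-number matrix
#'
#' Rows (samples) are always clustered with [ward_linkage()]; columns
#' (windows) are clustered only when `cluster_windows` is TRUE, otherwise
#' they stay in genomic order.  When a `sample_table` is given and
#' `feature` is omitted, one layout per feature column is produced, each
#' decorated with that feature's per-sample labels.
#'
#' @param m a `CNVMatrix` (absolute, relative-to-estimated-ploidy, or
#'   relative-to-2, per the caller's construction)
#' @param sample_table optional [read_sample_table()] annotation
#' @param feature optional single feature name from `sample_table`
#' @param cluster_windows cluster the columns too (default FALSE)
#' @return a list of `HeatmapLayout` objects: `values` (render order),
#'   `row_hclust`, `col_hclust` (or NULL), `row_order`, `col_order`,
#'   `feature`, `labels`, `flavor`
#' @export
build_heatmap <- function(m, sample_table = NULL, feature = NULL,
                          cluster_windows = FALSE) {
  stopifnot(inherits(m, "CNVMatrix"))
  features <- if (!is.null(feature)) {
    if (is.null(sample_table) || !feature %in% names(sample_table))
      stop("unknown feature: ", feature)
    feature
  } else if (!is.null(sample_table)) {
    setdiff(names(sample_table), "Sample")
  } else NA_character_

  row_hc <- ward_linkage(m, on = "rows")
  col_hc <- if (cluster_windows) ward_linkage(m, on = "columns") else NULL
  row_order <- row_hc$order
  col_order <- if (cluster_windows) col_hc$order else seq_len(ncol(m$values))

  lapply(features, function(f) {
    labels <- if (!is.na(f)) {
      idx <- match(rownames(m$values), sample_table$Sample)
      as.character(sample_table[[f]])[idx]
    } else NULL
    structure(list(values = m$values[row_order, col_order, drop = FALSE],
                   row_hclust = row_hc, col_hclust = col_hc,
                   row_order = row_order, col_order = col_order,
                   feature = if (is.na(f)) NULL else f,
                   labels = if (is.null(labels)) NULL else labels[row_order],
                   flavor = m$flavor),
              class = "HeatmapLayout")
  })
}
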