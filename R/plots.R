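## Rendering of the three figure types.  All quantitative content lives
## in the exported tables; these renderers only draw them, so acceptance
## of results never depends on pixels.

default_category_colors <- function() {
  c("-4" = "#08306b", "-3" = "#2171b5", "-2" = "#6baed6", "-1" = "#c6dbef",
    "+1" = "#fcbba1", "+2" = "#fb6a4a", "+3" = "#cb181d", ">=+4" = "#67000d",
    "cn-LOH" = "black", "LOH" = "blue",
    "het" = "#74c476", "hom" = "#756bb1")
}

#' Read a colour-configuration file
#'
#' Two tab-delimited columns, category and colour, overriding the
#' default palette for histogram categories and LOH lines.
#'
#' @param path file path, or NULL for the defaults
#' @return named character vector of colours
#' @export
read_color_file <- function(path = NULL) {
  colors <- default_category_colors()
  if (is.null(path)) return(colors)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  colors[as.character(df[[1]])] <- as.character(df[[2]])
  colors
}

## cumulative genome x-offsets for a build
genome_offsets <- function(build) {
  len <- build$chromosomes$length
  stats::setNames(c(0, cumsum(len))[seq_along(len)],
                  build$chromosomes$chrom)
}

open_device <- function(path, format, width, height, res) {
  switch(format,
         png = grDevices::png(path, width = width, height = height, res = res),
         pdf = grDevices::pdf(path, width = width, height = height),
         tiff = grDevices::tiff(path, width = width, height = height, res = res),
         bmp = grDevices::bmp(path, width = width, height = height, res = res),
         jpg = ,
         jpeg = grDevices::jpeg(path, width = width, height = height, res = res),
         stop("unsupported output format: ", format))
}

#' Plot the stacked copy-number frequency histogram
#'
#' Gains stack upward and losses downward per segment along the genome;
#' LOH/cn-LOH percentage lines are drawn in negative ordinates.
#'
#' @param hist_table a [compute_stacked_frequencies()] table
#' @param build the [genome_build()] giving the x layout
#' @param loh_tracks optional [compute_loh_tracks()] table
#' @param colors palette from [read_color_file()]
#' @param main plot title
#' @return invisibly, NULL
#' @export
plot_stacked_histogram <- function(hist_table, build, loh_tracks = NULL,
                                   colors = read_color_file(),
                                   main = "Cohort CNV frequencies") {
  off <- genome_offsets(build)
  h <- hist_table[hist_table$category != 0, , drop = FALSE]
  h$bin <- display_bin(h$category)
  x0 <- off[as.character(h$chrom)] + h$start
  x1 <- off[as.character(h$chrom)] + h$end
  ## stack order: small |category| first
  gains <- h[h$category > 0, ][order(h$category[h$category > 0]), ]
  losses <- h[h$category < 0, ][order(-h$category[h$category < 0]), ]
  ylim <- c(-100, 100)
  graphics::plot(NA, xlim = c(0, sum(build$chromosomes$length)),
                 ylim = ylim, xlab = "", ylab = "% of samples",
                 xaxt = "n", main = main)
  graphics::abline(h = 0)
  draw_stack <- function(d, sgn) {
    if (nrow(d) == 0L) return()
    base <- stats::setNames(rep(0, length(unique(paste(d$chrom, d$start)))),
                            unique(paste(d$chrom, d$start)))
    for (r in seq_len(nrow(d))) {
      key <- paste(d$chrom[r], d$start[r])
      y0 <- base[[key]]
      y1 <- y0 + sgn * d$pct[r]
      graphics::rect(off[as.character(d$chrom[r])] + d$start[r], y0,
                     off[as.character(d$chrom[r])] + d$end[r], y1,
                     col = colors[[d$bin[r]]], border = NA)
      base[[key]] <- y1
    }
  }
  draw_stack(gains, +1)
  draw_stack(losses, -1)
  if (!is.null(loh_tracks) && nrow(loh_tracks) > 0) {
    for (tr in unique(loh_tracks$track)) {
      d <- loh_tracks[loh_tracks$track == tr, ]
      graphics::segments(off[as.character(d$chrom)] + d$start, d$value,
                         off[as.character(d$chrom)] + d$end, d$value,
                         col = colors[[tr]], lwd = 1.5)
    }
  }
  ticks <- off + build$chromosomes$length / 2
  graphics::axis(1, at = ticks, labels = build$chromosomes$chrom,
                 las = 2, cex.axis = 0.6, tick = FALSE)
  graphics::abline(v = off[-1], col = "grey85")
  invisible(NULL)
}

#' Plot the heterozygous/homozygous CNV histogram
#'
#' Gains and copy-neutral events stack upward, losses downward, coloured
#' by zygosity.
#'
#' @param hethom a [compute_hethom_frequencies()] table
#' @param build the [genome_build()]
#' @param colors palette from [read_color_file()]
#' @return invisibly, NULL
#' @export
plot_hethom_histogram <- function(hethom, build,
                                  colors = read_color_file()) {
  off <- genome_offsets(build)
  graphics::plot(NA, xlim = c(0, sum(build$chromosomes$length)),
                 ylim = c(-100, 100), xlab = "", ylab = "% of samples",
                 xaxt = "n", main = "Heterozygous/homozygous CNVs")
  graphics::abline(h = 0)
  key <- paste(hethom$chrom, hethom$start, hethom$value >= 0)
  base <- stats::setNames(rep(0, length(unique(key))), unique(key))
  for (r in seq_len(nrow(hethom))) {
    y0 <- base[[key[r]]]
    y1 <- y0 + hethom$value[r]
    graphics::rect(off[[as.character(hethom$chrom[r])]] + hethom$start[r],
                   y0,
                   off[[as.character(hethom$chrom[r])]] + hethom$end[r],
                   y1, col = colors[[hethom$zygosity[r]]],
                   border = NA)
    base[[key[r]]] <- y1
  }
  graphics::abline(v = off[-1], col = "grey85")
  invisible(NULL)
}

#' Plot a dendrogram with feature-coloured leaves
#'
#' @param hc an `hclust` from [ward_linkage()]
#' @param labels optional per-leaf feature values used for colouring
#' @param main title
#' @return invisibly, NULL
#' @export
plot_sample_dendrogram <- function(hc, labels = NULL, main = "Samples") {
  graphics::plot(hc, hang = -1, main = main, xlab = "", sub = "",
                 cex = 0.5)
  if (!is.null(labels)) {
    lv <- unique(labels)
    pal <- grDevices::hcl.colors(max(3, length(lv)), "Dark 3")
    graphics::points(seq_along(hc$order), rep(0, length(hc$order)),
                     pch = 15, col = pal[match(labels[hc$order], lv)])
    graphics::legend("topright", legend = lv, fill = pal[seq_along(lv)],
                     cex = 0.6, bty = "n")
  }
  invisible(NULL)
}

#' Render a heatmap layout
#'
#' @param layout a [build_heatmap()] layout
#' @return invisibly, NULL
#' @export
plot_heatmap_layout <- function(layout) {
  v <- layout$values
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(t(v)[, rev(seq_len(nrow(v))), drop = FALSE], col = pal,
                  axes = FALSE,
                  main = paste0("CNV heatmap (", layout$flavor, ")",
                                if (!is.null(layout$feature))
                                  paste0(" - ", layout$feature)))
  invisible(NULL)
}
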