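#' Genome build: chromosome lengths and centromere intervals
#'
#' A `GenomeBuild` holds the ordered chromosome lengths and the centromere
#' interval of each chromosome.  All coordinates are 0-based half-open.
#' Builds drive window construction ([make_windows()]) and input validation.
#'
#' @param chromosomes data.frame with columns `chrom`, `length`
#' @param centromeres data.frame with columns `chrom`, `start`, `end`, or
#'   `NULL` for a build without centromere annotation
#' @param build_name identifier for the build
#' @return an object of class `GenomeBuild`
#' @export
genome_build <- function(chromosomes, centromeres = NULL,
                         build_name = "custom") {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicate chromosome names in build")
  if (any(!is.finite(chromosomes$length)) || any(chromosomes$length <= 0))
    stop("chromosome lengths must be positive")
  if (is.null(centromeres)) {
    centromeres <- data.frame(chrom = character(), start = numeric(),
                              end = numeric())
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(centromeres)))
  centromeres$chrom <- as.character(centromeres$chrom)
  if (anyDuplicated(centromeres$chrom))
    stop("more than one centromere interval for a chromosome")
  idx <- match(centromeres$chrom, chromosomes$chrom)
  if (anyNA(idx))
    stop("centromere refers to unknown chromosome: ",
         paste(centromeres$chrom[is.na(idx)], collapse = ", "))
  len <- chromosomes$length[idx]
  bad <- centromeres$start < 0 | centromeres$end > len |
    centromeres$end <= centromeres$start |
    (centromeres$start == 0 & centromeres$end == len)
  if (any(bad))
    stop("centromere interval outside (or covering all of) chromosome: ",
         paste(centromeres$chrom[bad], collapse = ", "))
  structure(list(build_name = build_name,
                 chromosomes = chromosomes[, c("chrom", "length")],
                 centromeres = centromeres[, c("chrom", "start", "end")]),
            class = "GenomeBuild")
}

#' Load a genome build
#'
#' Loads one of the bundled builds (`"hg18"`, `"hg19"`) or a custom build
#' from a pair of tab-delimited files: a chromosome-sizes file
#' (`chrom<TAB>length`, no header) and an optional centromere file
#' (`chrom<TAB>start<TAB>end`, no header, 0-based half-open).
#'
#' @param source `"hg18"`, `"hg19"`, or the path of a chromosome-sizes file
#' @param centromeres path of a centromere file (ignored for bundled builds)
#' @return a [genome_build()] object
#' @examples
#' hg19 <- load_build("hg19")
#' nrow(hg19$chromosomes)  # 24 (1..22, X, Y)
#' @export
load_build <- function(source, centromeres = NULL) {
  if (source %in% c("hg18", "hg19")) {
    sizes_path <- system.file("extdata", paste0(source, "_chrom_sizes.tsv"),
                              package = "cnvcohort", mustWork = TRUE)
    cent_path <- system.file("extdata", paste0(source, "_centromeres.tsv"),
                             package = "cnvcohort", mustWork = TRUE)
    return(load_build_files(sizes_path, cent_path, source))
  }
  if (!file.exists(source))
    stop("unknown build '", source,
         "': expected \"hg18\", \"hg19\" or a readable chrom-sizes file")
  load_build_files(source, centromeres,
                   build_name = tools::file_path_sans_ext(basename(source)))
}

load_build_files <- function(sizes_path, cent_path, build_name) {
  sizes <- utils::read.delim(sizes_path, header = FALSE,
                             stringsAsFactors = FALSE)
  if (ncol(sizes) < 2) stop("malformed chrom-sizes file: ", sizes_path)
  names(sizes)[1:2] <- c("chrom", "length")
  cents <- NULL
  if (!is.null(cent_path)) {
    cents <- utils::read.delim(cent_path, header = FALSE,
                               stringsAsFactors = FALSE)
    if (ncol(cents) < 3) stop("malformed centromere file: ", cent_path)
    names(cents)[1:3] <- c("chrom", "start", "end")
  }
  genome_build(sizes, cents, build_name)
}

#' @export
print.GenomeBuild <- function(x, ...) {
  cat("GenomeBuild '", x$build_name, "': ", nrow(x$chromosomes),
      " chromosomes, ", nrow(x$centromeres), " centromeres, ",
      format(sum(x$chromosomes$length), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

## centromere interval of one chromosome, or NULL
centromere_of <- function(build, chrom) {
  i <- match(chrom, build$centromeres$chrom)
  if (is.na(i)) NULL else
    c(start = build$centromeres$start[i], end = build$centromeres$end[i])
}

chrom_length <- function(build, chrom) {
  i <- match(chrom, build$chromosomes$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  build$chromosomes$length[i]
}
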