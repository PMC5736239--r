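#' Round half away from zero
#'
#' Rounding used throughout the package when averaging copy numbers:
#' ties at .5 move away from zero, so gains and losses are treated
#' symmetrically (2.5 -> 3, -2.5 -> -3).  This differs from base R's
#' banker's rounding.
#'
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## canonical chromosome ordering: numeric first, then alphabetic (X, Y, MT)
chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(u))
  u[order(is.na(num), num, u)]
}

## sort factor levels for a set of chromosomes, honoring a build's order
## when one is given
chrom_factor <- function(chroms, build = NULL) {
  levels <- if (!is.null(build)) build$chromosomes$chrom else chrom_order(chroms)
  factor(as.character(chroms), levels = levels)
}

## strip/match an optional "chr" prefix against a build's naming
normalize_chroms <- function(chroms, build) {
  chroms <- as.character(chroms)
  target <- build$chromosomes$chrom
  stripped <- sub("^chr", "", chroms)
  out <- ifelse(chroms %in% target, chroms,
         ifelse(stripped %in% target, stripped,
         ifelse(paste0("chr", chroms) %in% target, paste0("chr", chroms), NA)))
  if (anyNA(out)) {
    bad <- unique(chroms[is.na(out)])
    stop("unknown chromosome(s) for build '", build$build_name, "': ",
         paste(bad, collapse = ", "))
  }
  out
}

#' Parse a genomic region string
#'
#' Accepts `"chrom:start-end"` with 0-based half-open coordinates (the
#' package's internal convention), e.g. `"1:125000000-249250621"`.
#' Thousands separators (commas) are tolerated.
#'
#' @param x character scalar
#' @return list with elements `chrom`, `start`, `end`
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub(",", "", x)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L)
    stop("malformed region '", x, "'; expected chrom:start-end")
  out <- list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
  if (out$end <= out$start) stop("region end must exceed start: ", x)
  out
}

## tab-delimited reader used for all plain-text inputs
read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
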