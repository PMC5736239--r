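#' Allele-specific copy-number segment sets
#'
#' A `SegmentSet` is the internal representation of a cohort of
#' allele-specific copy-number calls: one row per segment with the sample
#' identifier, 0-based half-open genomic interval, major-allele copies
#' `n_major`, minor-allele copies `n_minor` and their sum `total_cn`.
#' Within one sample segments never overlap, matching what any segment
#' caller emits.
#'
#' @param segments data.frame with columns `sample`, `chrom`, `start`,
#'   `end`, `n_major`, `n_minor`
#' @return an object of class `SegmentSet`
#' @export
segment_set <- function(segments) {
  req <- c("sample", "chrom", "start", "end", "n_major", "n_minor")
  stopifnot(is.data.frame(segments), all(req %in% names(segments)))
  segments <- segments[, req]
  segments$sample <- as.character(segments$sample)
  segments$chrom <- as.character(segments$chrom)
  for (col in c("start", "end", "n_major", "n_minor"))
    segments[[col]] <- as.numeric(segments[[col]])
  if (any(segments$end <= segments$start))
    stop("segment with end <= start")
  if (any(segments$n_minor < 0) || any(segments$n_major < 0))
    stop("negative allele copy numbers")
  if (any(segments$n_major < segments$n_minor))
    stop("n_major < n_minor; allele columns are (major, minor)")
  segments$total_cn <- segments$n_major + segments$n_minor
  ## canonical order: sample, chromosome, start
  lev <- chrom_order(segments$chrom)
  o <- order(segments$sample, factor(segments$chrom, levels = lev),
             segments$start)
  segments <- segments[o, , drop = FALSE]
  rownames(segments) <- NULL
  check_no_overlap(segments)
  structure(list(segments = segments,
                 samples = sort(unique(segments$sample))),
            class = "SegmentSet")
}

check_no_overlap <- function(segments) {
  key <- paste(segments$sample, segments$chrom)
  prev_end <- ave(segments$end, key,
                  FUN = function(e) c(-Inf, e[-length(e)]))
  bad <- segments$start < prev_end
  if (any(bad)) {
    b <- segments[which(bad)[1], ]
    stop("overlapping segments within sample ", b$sample, " on ", b$chrom,
         " near position ", format(b$start, scientific = FALSE))
  }
  invisible(TRUE)
}

#' @export
print.SegmentSet <- function(x, ...) {
  cat("SegmentSet: ", nrow(x$segments), " segments, ",
      length(x$samples), " samples\n", sep = "")
  print.data.frame(utils::head(x$segments, 8))
  if (nrow(x$segments) > 8) cat("...\n")
  invisible(x)
}

## header synonyms for the ASCAT segment table
.ascat_cols <- list(
  sample = c("sample", "sampleid", "sample_id", "name"),
  chrom = c("chr", "chrom", "chromosome"),
  start = c("startpos", "start.pos", "start", "start_pos"),
  end = c("endpos", "end.pos", "end", "end_pos"),
  n_major = c("nmajor", "n_major", "major", "na"),
  n_minor = c("nminor", "n_minor", "minor", "nb"))

match_col <- function(header, synonyms, what, path) {
  hit <- which(tolower(header) %in% synonyms)
  if (length(hit) == 0L)
    stop("missing column '", what, "' in ", path,
         " (accepted: ", paste(synonyms, collapse = "/"), ")")
  hit[1]
}

#' Parse allele-specific segment calls
#'
#' Reads segment calls in either of two dialects.  `"ascat"` expects one
#' tab-delimited file with a header naming the sample, chromosome,
#' 1-based inclusive start/end, and major/minor allele copy numbers
#' (header spellings such as `startpos`/`start.pos`/`start` are all
#' accepted, case-insensitively).  `"sequenza"` expects a directory of
#' per-sample `*_segments.txt` tables with columns `chromosome`,
#' `start.pos`, `end.pos`, `A` and `B`; the sample name is taken from the
#' file name.  Coordinates are converted to the package's 0-based
#' half-open convention, chromosome names are normalised against `build`
#' (a `chr` prefix is accepted either way), and per-sample non-overlap is
#' validated.
#'
#' @param path file (ascat) or directory (sequenza)
#' @param dialect `"ascat"` or `"sequenza"`
#' @param build optional [genome_build()] used to normalise and validate
#'   chromosome names
#' @return a [segment_set()]
#' @export
parse_segments <- function(path, dialect = c("ascat", "sequenza"),
                           build = NULL) {
  dialect <- match.arg(dialect)
  df <- switch(dialect,
               ascat = parse_ascat_file(path),
               sequenza = parse_sequenza_dir(path))
  if (!is.null(build)) df$chrom <- normalize_chroms(df$chrom, build)
  segment_set(df)
}

parse_ascat_file <- function(path) {
  if (!file.exists(path)) stop("cannot read segment file: ", path)
  raw <- read_tsv_file(path)
  header <- names(raw)
  idx <- vapply(names(.ascat_cols), function(f)
    match_col(header, .ascat_cols[[f]], f, path), integer(1))
  df <- raw[, idx]
  names(df) <- names(.ascat_cols)
  ## ASCAT coordinates are 1-based inclusive
  df$start <- as.numeric(df$start) - 1
  df$end <- as.numeric(df$end)
  df
}

parse_sequenza_dir <- function(path) {
  if (!dir.exists(path)) stop("expected a directory of Sequenza results: ",
                              path)
  files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0L) stop("no *.txt segment tables under ", path)
  per_sample <- lapply(files, function(f) {
    raw <- read_tsv_file(f)
    need <- c("chromosome", "start.pos", "end.pos", "A")
    if (!all(need %in% names(raw)))
      stop("missing Sequenza columns in ", f, ": ",
           paste(setdiff(need, names(raw)), collapse = ", "))
    b <- if ("B" %in% names(raw)) raw$B else rep(NA_real_, nrow(raw))
    if (anyNA(b)) {
      warning("missing minor-allele counts (column B) in ", basename(f),
              "; treating as 0")
      b[is.na(b)] <- 0
    }
    data.frame(sample = sub("_segments\\.txt$|\\.txt$", "", basename(f)),
               chrom = raw$chromosome,
               start = as.numeric(raw$`start.pos`) - 1,
               end = as.numeric(raw$`end.pos`),
               n_major = as.numeric(raw$A), n_minor = as.numeric(b))
  })
  do.call(rbind, per_sample)
}

#' Read a sample-annotation table
#'
#' Tab-delimited file with a `Sample` column plus one column per
#' phenotypic/clinical feature.  When an `Alias` column is present the
#' alias becomes the official sample identifier.
#'
#' @param path file path
#' @return data.frame of class `SampleTable` with a `Sample` column
#' @export
read_sample_table <- function(path) {
  df <- read_tsv_file(path)
  if (!"Sample" %in% names(df))
    stop("sample file must contain a column named 'Sample': ", path)
  alias_col <- grep("^alias$", names(df), ignore.case = TRUE, value = TRUE)
  if (length(alias_col) == 1L) {
    has_alias <- !is.na(df[[alias_col]]) & nzchar(df[[alias_col]])
    df$Sample[has_alias] <- df[[alias_col]][has_alias]
    df[[alias_col]] <- NULL
  }
  if (anyDuplicated(df$Sample)) stop("duplicate sample ids in ", path)
  class(df) <- c("SampleTable", "data.frame")
  df
}

#' Read (or synthesise) a ploidy table
#'
#' `source` is either a tab-delimited file with columns `sample` and
#' `ploidy`, or a single number, which assigns that ploidy to every
#' sample in `samples`.
#'
#' @param source file path or a single numeric value
#' @param samples character vector of sample ids (required when `source`
#'   is a single number)
#' @return named numeric vector, one positive ploidy per sample
#' @export
read_ploidy_table <- function(source, samples = NULL) {
  if (is.numeric(source) ||
      (is.character(source) && !file.exists(source) &&
       !is.na(suppressWarnings(as.numeric(source))))) {
    p <- as.numeric(source)
    if (!is.finite(p) || p <= 0) stop("ploidy must be positive")
    if (is.null(samples)) stop("a constant ploidy needs the sample list")
    return(stats::setNames(rep(p, length(samples)), samples))
  }
  df <- read_tsv_file(source)
  names(df) <- tolower(names(df))
  if (!all(c("sample", "ploidy") %in% names(df)))
    stop("ploidy file needs columns 'sample' and 'ploidy': ", source)
  p <- suppressWarnings(as.numeric(df$ploidy))
  if (anyNA(p) || any(p <= 0)) stop("non-numeric or non-positive ploidy in ",
                                    source)
  stats::setNames(p, as.character(df$sample))
}

#' Write a SegmentSet in ASCAT or Sequenza dialect
#'
#' Inverse of [parse_segments()]; used by the synthetic-cohort generator
#' to materialise fixtures, and round-trip tested against the parser.
#'
#' @param segs a [segment_set()]
#' @param path output file (ascat) or directory (sequenza)
#' @param dialect `"ascat"` or `"sequenza"`
#' @return the path, invisibly
#' @export
write_segments <- function(segs, path, dialect = c("ascat", "sequenza")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(segs, "SegmentSet"))
  df <- segs$segments
  if (dialect == "ascat") {
    out <- data.frame(sample = df$sample, chr = df$chrom,
                      startpos = as.integer(df$start + 1),
                      endpos = as.integer(df$end),
                      nMajor = as.integer(df$n_major),
                      nMinor = as.integer(df$n_minor))
    write_tsv_file(out, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (s in segs$samples) {
      d <- df[df$sample == s, , drop = FALSE]
      out <- data.frame(chromosome = d$chrom,
                        start.pos = as.integer(d$start + 1),
                        end.pos = as.integer(d$end),
                        CNt = as.integer(d$total_cn),
                        A = as.integer(d$n_major), B = as.integer(d$n_minor),
                        check.names = FALSE)
      write_tsv_file(out, file.path(path, paste0(s, "_segments.txt")))
    }
  }
  invisible(path)
}

#' Export a GISTIC segmentation file
#'
#' Writes the six-column GISTIC input (sample, chromosome, 1-based
#' inclusive start/end, marker count, seg.mean) where seg.mean is
#' `log2(total_cn / 2)`.  Homozygous deletions (total 0) are floored at
#' `cn_floor` before the log.  The marker count is a surrogate
#' (segment length / 10 kb, minimum 5) since segment tables carry no
#' probe information.
#'
#' @param segs a [segment_set()]
#' @param out output path
#' @param cn_floor positive floor applied to a total copy number of 0
#' @return the path, invisibly
#' @export
export_gistic_segments <- function(segs, out, cn_floor = 0.1) {
  stopifnot(inherits(segs, "SegmentSet"), cn_floor > 0)
  df <- segs$segments
  if (nrow(df) == 0L) stop("empty SegmentSet")
  seg_cn <- log2(pmax(df$total_cn, cn_floor) / 2)
  gistic <- data.frame(Sample = df$sample,
                       Chromosome = df$chrom,
                       Start = as.integer(df$start + 1),
                       End = as.integer(df$end),
                       Num_Probes = pmax(5L, as.integer((df$end - df$start) %/% 1e4)),
                       Segment_Mean = seg_cn)
  write_tsv_file(gistic, out)
}
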