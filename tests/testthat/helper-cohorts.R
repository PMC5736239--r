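## Random small fixtures built in code, independent of the package's own
## cohort generator so the two can check each other.

## a toy build with small chromosomes (and optional centromeres)
toy_build <- function(lengths = c(c1 = 2e5, c2 = 1.5e5),
                      centromere_frac = NULL) {
  chroms <- data.frame(chrom = names(lengths), length = as.numeric(lengths))
  cents <- NULL
  if (!is.null(centromere_frac)) {
    cents <- data.frame(chrom = chroms$chrom,
                        start = round(chroms$length * centromere_frac[1]),
                        end = round(chroms$length * centromere_frac[2]))
  }
  genome_build(chroms, cents, "toy")
}

## random non-overlapping allele-specific calls on a build
random_segments <- function(build, n_samples = 4, max_calls = 12,
                            seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in paste0("R", seq_len(n_samples))) {
    for (ci in seq_len(nrow(build$chromosomes))) {
      chrom <- build$chromosomes$chrom[ci]
      len <- build$chromosomes$length[ci]
      n_bp <- sample(2:max(3, max_calls), 1)
      bp <- sort(unique(c(0, len, sample(seq_len(len - 1), n_bp))))
      for (k in seq_len(length(bp) - 1)) {
        if (stats::runif(1) < 0.25) next      # leave uncovered gaps
        n_min <- sample(0:2, 1)
        n_maj <- n_min + sample(0:3, 1)
        if (n_maj == 0 && stats::runif(1) < 0.5) next
        rows[[length(rows) + 1]] <-
          data.frame(sample = s, chrom = chrom, start = bp[k],
                     end = bp[k + 1], n_major = n_maj, n_minor = n_min)
      }
    }
  }
  segment_set(do.call(rbind, rows))
}

## write an ASCAT-dialect file from explicit rows (1-based inclusive)
write_ascat_text <- function(rows, path) {
  writeLines(c("sample\tchr\tstartpos\tendpos\tnMajor\tnMinor", rows), path)
  path
}
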