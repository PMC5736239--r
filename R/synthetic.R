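#' Specify a synthetic cohort of allele-specific copy-number calls
#'
#' A `CohortSpec` describes a cohort with known ground truth: per-sample
#' baseline ploidies, planted recurrent events, a coverage gap rate and a
#' fragmentation rate.  [generate_cohort()] realises it deterministically
#' from the seed.
#'
#' Planted events are rows of `events`: `chrom`, `start`, `end` (0-based
#' half-open), `type` (`"gain"`, `"loss"` or `"cnloh"`), `delta` (copies
#' gained/lost relative to the carrier's ploidy; ignored for `"cnloh"`),
#' `fraction` (of samples carrying the event) and optional `group`.
#' Events sharing a `group` draw disjoint carrier blocks from one
#' shuffled sample order, so several gain categories can be planted on
#' the same interval with exact, non-overlapping carrier counts.
#'
#' @param n_samples cohort size
#' @param build a [genome_build()]
#' @param ploidies baseline ploidy, a single value or one per sample
#' @param events data.frame of planted events (see Details), or NULL
#' @param gap_rate fraction of each chromosome left uncovered per sample
#'   (one uniformly-placed gap per chromosome), in \[0, 1)
#' @param frag_rate expected extra breakpoints per Mb (value-preserving
#'   splits emulating caller fragmentation)
#' @param seed RNG seed; everything downstream is a pure function of it
#' @return an object of class `CohortSpec`
#' @export
cohort_spec <- function(n_samples, build, ploidies = 2, events = NULL,
                        gap_rate = 0, frag_rate = 0, seed = 1) {
  stopifnot(inherits(build, "GenomeBuild"), n_samples >= 1,
            gap_rate >= 0, gap_rate < 1, frag_rate >= 0)
  ploidies <- rep_len(as.numeric(ploidies), n_samples)
  if (any(ploidies <= 0)) stop("ploidies must be positive")
  if (!is.null(events)) {
    req <- c("chrom", "start", "end", "type", "delta", "fraction")
    stopifnot(is.data.frame(events), all(req %in% names(events)))
    if (!"group" %in% names(events))
      events$group <- paste0("g", seq_len(nrow(events)))
    if (any(events$fraction < 0 | events$fraction > 1))
      stop("event fractions must lie in [0, 1]")
    bad <- !events$chrom %in% build$chromosomes$chrom
    if (any(bad)) stop("event on unknown chromosome: ",
                       paste(unique(events$chrom[bad]), collapse = ", "))
    len <- build$chromosomes$length[match(events$chrom,
                                          build$chromosomes$chrom)]
    if (any(events$start < 0 | events$end > len |
            events$end <= events$start))
      stop("event interval outside its chromosome")
  }
  structure(list(n_samples = n_samples, build = build, ploidies = ploidies,
                 events = events, gap_rate = gap_rate,
                 frag_rate = frag_rate, seed = seed),
            class = "CohortSpec")
}

#' Generate a synthetic cohort with ground truth
#'
#' Realises a [cohort_spec()]: every sample starts from whole-chromosome
#' baseline segments at its ploidy p with allele split
#' (ceiling(p/2), floor(p/2)); planted events overwrite the baseline on
#' their carriers (gains add copies to the major allele, losses remove
#' from the minor allele first, cn-LOH sets (round(p), 0)); one coverage
#' gap per chromosome removes `gap_rate` of its length; fragmentation
#' splits segments at random points without changing values.  Carriers
#' of each event are the next `round(fraction * n)` samples of the
#' group's seeded shuffle, so planted frequencies are exact.
#'
#' @param spec a [cohort_spec()]
#' @return list with elements `segments` (a [segment_set()]) and `truth`
#'   (list: `ploidy` named vector, `events` data.frame with a `carriers`
#'   list-column)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  samples <- sprintf("S%0*d", max(2L, nchar(n)), seq_len(n))
  ploidy <- stats::setNames(spec$ploidies, samples)

  truth_events <- assign_carriers(spec$events, samples)
  check_event_conflicts(truth_events)

  chroms <- spec$build$chromosomes
  per_sample <- lapply(seq_len(n), function(si) {
    s <- samples[si]; p <- ploidy[[s]]
    base_min <- floor(p / 2); base_maj <- ceiling(p / 2)
    rows <- lapply(seq_len(nrow(chroms)), function(ci) {
      chrom <- chroms$chrom[ci]; len <- chroms$length[ci]
      seg <- data.frame(start = 0, end = len,
                        n_major = base_maj, n_minor = base_min)
      ## planted events carried by this sample on this chromosome
      if (!is.null(truth_events)) {
        ev <- truth_events[truth_events$chrom == chrom, , drop = FALSE]
        for (k in seq_len(nrow(ev))) {
          if (!s %in% ev$carriers[[k]]) next
          al <- event_alleles(ev$type[k], ev$delta[k], p)
          seg <- set_interval(seg, ev$start[k], ev$end[k],
                              al["maj"], al["min"])
        }
      }
      ## coverage gap: one uniformly placed interval per chromosome
      if (spec$gap_rate > 0) {
        glen <- round(spec$gap_rate * len)
        gs <- floor(stats::runif(1, 0, len - glen))
        seg <- drop_interval(seg, gs, gs + glen)
      }
      ## fragmentation: value-preserving splits
      if (spec$frag_rate > 0) {
        npts <- stats::rpois(1, spec$frag_rate * len / 1e6)
        if (npts > 0) {
          pts <- sort(unique(floor(stats::runif(npts, 1, len - 1))))
          seg <- split_at(seg, pts)
        }
      }
      if (nrow(seg) == 0L) return(NULL)
      data.frame(sample = s, chrom = chrom, seg)
    })
    do.call(rbind, rows)
  })
  segs <- segment_set(do.call(rbind, per_sample))
  list(segments = segs,
       truth = list(ploidy = ploidy, events = truth_events))
}

## carriers per event: disjoint blocks of one shuffled order per group
assign_carriers <- function(events, samples) {
  if (is.null(events) || nrow(events) == 0L) return(NULL)
  n <- length(samples)
  events$carriers <- vector("list", nrow(events))
  for (g in unique(events$group)) {
    idx <- which(events$group == g)
    order_g <- sample(samples)
    used <- 0L
    for (k in idx) {
      m <- round(events$fraction[k] * n)
      if (used + m > n)
        stop("carrier fractions of group '", g, "' exceed the cohort")
      events$carriers[[k]] <- sort(order_g[seq_len(m) + used])
      used <- used + m
    }
  }
  events
}

## planted events must not overlap on a shared carrier
check_event_conflicts <- function(events) {
  if (is.null(events) || nrow(events) < 2L) return(invisible(TRUE))
  for (i in seq_len(nrow(events) - 1L)) for (j in (i + 1L):nrow(events)) {
    if (events$chrom[i] != events$chrom[j]) next
    if (events$start[j] >= events$end[i] ||
        events$start[i] >= events$end[j]) next
    shared <- intersect(events$carriers[[i]], events$carriers[[j]])
    if (length(shared) > 0L)
      stop("contradictory overlapping events for sample(s): ",
           paste(utils::head(shared, 3), collapse = ", "))
  }
  invisible(TRUE)
}

## allele counts produced by an event on a carrier of ploidy p
event_alleles <- function(type, delta, p) {
  base_min <- floor(p / 2); base_maj <- ceiling(p / 2)
  switch(type,
    gain = c(maj = base_maj + abs(delta), min = base_min),
    loss = {
      k <- abs(delta)
      total <- base_maj + base_min - k
      if (total < 0) stop("loss below zero copies (delta ", delta,
                          " at ploidy ", p, ")")
      mn <- max(0, base_min - k)
      c(maj = total - mn, min = mn)
    },
    cnloh = c(maj = round_half_away(p), min = 0),
    stop("unknown event type: ", type))
}

## overwrite [s, e) of a per-chromosome segment table with new alleles
set_interval <- function(seg, s, e, maj, mn) {
  out <- drop_interval(seg, s, e)
  out <- rbind(out, data.frame(start = s, end = e,
                               n_major = maj, n_minor = mn))
  out[order(out$start), , drop = FALSE]
}

## remove coverage of [s, e)
drop_interval <- function(seg, s, e) {
  pieces <- lapply(seq_len(nrow(seg)), function(r) {
    rs <- seg$start[r]; re <- seg$end[r]
    keep <- list()
    if (rs < s) keep[[1]] <- c(rs, min(re, s))
    if (re > e) keep[[length(keep) + 1L]] <- c(max(rs, e), re)
    if (re <= s || rs >= e) keep <- list(c(rs, re))
    if (length(keep) == 0L) return(NULL)
    data.frame(start = vapply(keep, `[`, numeric(1), 1),
               end = vapply(keep, `[`, numeric(1), 2),
               n_major = seg$n_major[r], n_minor = seg$n_minor[r])
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- seg[0, , drop = FALSE]
  out[out$end > out$start, , drop = FALSE]
}

## split segments at internal points, preserving values
split_at <- function(seg, points) {
  pieces <- lapply(seq_len(nrow(seg)), function(r) {
    rs <- seg$start[r]; re <- seg$end[r]
    inner <- points[points > rs & points < re]
    b <- c(rs, inner, re)
    data.frame(start = b[-length(b)], end = b[-1],
               n_major = seg$n_major[r], n_minor = seg$n_minor[r])
  })
  do.call(rbind, pieces)
}

#' Write fixture files for a cohort
#'
#' Materialises a generated cohort in either input dialect so the parser
#' round-trip can be exercised; thin wrapper over [write_segments()].
#'
#' @param segs a [segment_set()]
#' @param dialect `"ascat"` or `"sequenza"`
#' @param out_dir output directory; the ascat dialect writes
#'   `segments.tsv` inside it
#' @return path of the written file or directory, invisibly
#' @export
write_fixture_files <- function(segs, dialect = c("ascat", "sequenza"),
                                out_dir) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (dialect == "ascat") {
    write_segments(segs, file.path(out_dir, "segments.tsv"), "ascat")
    invisible(file.path(out_dir, "segments.tsv"))
  } else {
    write_segments(segs, out_dir, "sequenza")
    invisible(out_dir)
  }
}

#' Bundled HCC-like cohort preset
#'
#' A 96-sample liver-cancer-like cohort on hg19 with recurrent gains on
#' the 1q and 8q arms whose category mix differs while the total gain
#' frequency matches: both arms are gained in 54/96 samples, but the
#' strong ">= +4" category is carried by exactly 7/96 samples on 1q
#' versus 24/96 on 8q.  An 8p loss and a 17p copy-neutral LOH region are
#' planted as well.  A third of the cohort is tetraploid; the generator
#' is noise-free (no gaps, no fragmentation) so every planted frequency
#' is recovered exactly.
#'
#' @param seed RNG seed for carrier assignment (default 20)
#' @return a [cohort_spec()]
#' @export
hcc_like_spec <- function(seed = 20) {
  build <- load_build("hg19")
  q1 <- c(125000000, 249250621)     # 1q arm (distal to the centromere)
  q8 <- c(47000000, 146364022)      # 8q arm
  p8 <- c(0, 43838887)              # 8p arm
  p17 <- c(0, 22263006)             # 17p arm
  events <- rbind(
    data.frame(chrom = "1", start = q1[1], end = q1[2], type = "gain",
               delta = 1:4, fraction = c(30, 12, 5, 7) / 96, group = "1q"),
    data.frame(chrom = "8", start = q8[1], end = q8[2], type = "gain",
               delta = 1:4, fraction = c(18, 8, 4, 24) / 96, group = "8q"),
    data.frame(chrom = "8", start = p8[1], end = p8[2], type = "loss",
               delta = 1, fraction = 24 / 96, group = "8p"),
    data.frame(chrom = "17", start = p17[1], end = p17[2], type = "cnloh",
               delta = 0, fraction = 14 / 96, group = "17p"))
  cohort_spec(n_samples = 96, build = build,
              ploidies = rep(c(2, 2, 4), length.out = 96),
              events = events, gap_rate = 0, frag_rate = 0, seed = seed)
}
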