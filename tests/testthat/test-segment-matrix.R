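two_sample_set <- function() {
  segment_set(data.frame(
    sample = c("A", "B"), chrom = "c1", start = c(100, 150),
    end = c(200, 250), n_major = c(2, 1), n_minor = c(1, 0)))
}

test_that("breakpoint partition splits overlapping calls across pieces", {
  ms <- build_segment_matrix(two_sample_set(), coalesce = FALSE)
  expect_equal(ms$segments$start, c(100, 150, 200))
  expect_equal(ms$segments$end, c(150, 200, 250))
  a <- ms$cells[ms$cells$sample == "A", ]
  b <- ms$cells[ms$cells$sample == "B", ]
  expect_equal(a$segment, 1:2)
  expect_equal(unique(a$total_cn), 3)
  expect_equal(b$segment, 2:3)
  expect_equal(unique(b$total_cn), 1)
})

test_that("a single call maps to a single identical piece", {
  segs <- segment_set(data.frame(sample = "A", chrom = "c1", start = 5,
                                 end = 50, n_major = 3, n_minor = 2))
  ms <- build_segment_matrix(segs)
  expect_equal(nrow(ms$segments), 1)
  expect_equal(c(ms$segments$start, ms$segments$end), c(5, 50))
  expect_equal(ms$cells$total_cn, 5)
})

test_that("segment matrix preserves every base of every call", {
  for (seed in 1:8) {
    b <- toy_build(c(c1 = sample(3e4:8e4, 1), c2 = sample(3e4:8e4, 1)))
    segs <- random_segments(b, n_samples = 4, seed = 300 + seed)
    ms <- build_segment_matrix(segs)
    expect_true(oracle_check_segment_matrix(ms, segs, b),
                info = paste("seed", seed))
    ## covered length per sample conserved
    seg_len <- ms$segments$end - ms$segments$start
    for (s in segs$samples) {
      before <- sum(with(segs$segments[segs$segments$sample == s, ],
                         end - start))
      after <- sum(seg_len[match(ms$cells$segment[ms$cells$sample == s],
                                 ms$segments$segment)])
      expect_equal(after, before)
    }
  }
})

test_that("partitioning an already-partitioned set is idempotent", {
  segs <- random_segments(toy_build(), n_samples = 3, seed = 9)
  ms1 <- build_segment_matrix(segs, coalesce = FALSE)
  ## rebuild a SegmentSet from the partition cells and re-partition
  seg <- ms1$segments[match(ms1$cells$segment, ms1$segments$segment), ]
  flat <- segment_set(data.frame(
    sample = ms1$cells$sample, chrom = seg$chrom, start = seg$start,
    end = seg$end, n_major = ms1$cells$n_major,
    n_minor = ms1$cells$n_minor))
  ms2 <- build_segment_matrix(flat, coalesce = FALSE)
  expect_equal(ms2$segments, ms1$segments)
  expect_equal(ms2$cells, ms1$cells)
})

test_that("coalescing merges identical adjacent columns and keeps counts", {
  ## one sample split into two equal-value pieces collapses back
  segs <- segment_set(data.frame(
    sample = "A", chrom = "c1", start = c(0, 100), end = c(100, 300),
    n_major = 2, n_minor = 1))
  ms <- build_segment_matrix(segs)
  expect_equal(nrow(ms$segments), 1)
  expect_equal(c(ms$segments$start, ms$segments$end), c(0, 300))
  ## but a gap prevents merging even with equal values
  gap <- segment_set(data.frame(
    sample = "A", chrom = "c1", start = c(0, 200), end = c(100, 300),
    n_major = 2, n_minor = 1))
  expect_equal(nrow(build_segment_matrix(gap)$segments), 2)
})

test_that("fragmenting input calls changes no classification or frequency", {
  b <- toy_build(c(c1 = 1e5))
  base <- segment_set(data.frame(
    sample = c("A", "B"), chrom = "c1", start = 0, end = 1e5,
    n_major = c(3, 2), n_minor = c(0, 1)))
  frag <- segment_set(do.call(rbind, lapply(c("A", "B"), function(s) {
    d <- base$segments[base$segments$sample == s, ]
    cuts <- c(0, 2e4, 33333, 9e4, 1e5)
    data.frame(sample = s, chrom = "c1", start = cuts[-5], end = cuts[-1],
               n_major = d$n_major, n_minor = d$n_minor)
  })))
  p <- c(A = 3, B = 2)
  h1 <- compute_stacked_frequencies(classify_cells(build_segment_matrix(base), p))
  h2 <- compute_stacked_frequencies(classify_cells(build_segment_matrix(frag), p))
  expect_equal(h2, h1)
})

test_that("cells are classified per the cn-LOH/LOH/zygosity definitions", {
  segs <- segment_set(data.frame(
    sample = c("A", "B", "C"), chrom = "c1", start = 0, end = 100,
    n_major = c(2, 1, 2), n_minor = c(0, 0, 1)))
  p <- c(A = 2, B = 2, C = 2)
  ms <- classify_cells(build_segment_matrix(segs), p)
  cells <- ms$cells[order(ms$cells$sample), ]
  ## (2,0) p2: cn-LOH, LOH, homozygous, neutral
  expect_equal(cells$is_cn_loh, c(TRUE, FALSE, FALSE))
  expect_equal(cells$is_loh, c(TRUE, TRUE, FALSE))
  expect_equal(cells$is_homozygous, c(TRUE, TRUE, FALSE))
  expect_equal(cells$state, c("neutral", "loss", "gain"))
  expect_equal(cells$rel, c(0, -1, 1))
  ## cn-LOH implies LOH; zygosity is exclusive
  expect_true(all(!cells$is_cn_loh | cells$is_loh))
  expect_true(all(xor(cells$is_homozygous, cells$is_heterozygous)))
})

test_that("classification handles total deletion and non-integer ploidy", {
  segs <- segment_set(data.frame(
    sample = c("A", "B", "B"), chrom = "c1", start = c(0, 0, 100),
    end = c(100, 100, 200), n_major = c(0, 3, 2), n_minor = c(0, 0, 1)))
  ms <- classify_cells(build_segment_matrix(segs), c(A = 2, B = 2.5))
  a <- ms$cells[ms$cells$sample == "A", ]
  expect_false(a$is_loh)              # nothing retained: not LOH
  expect_true(a$is_homozygous)
  expect_equal(a$state, "loss")
  b <- ms$cells[ms$cells$sample == "B", ]
  ## tie-averaged ploidy 2.5 rounds to 3 for the integer comparisons
  expect_equal(b$is_cn_loh, c(TRUE, FALSE))
  expect_equal(b$state, c("neutral", "neutral"))
})

test_that("segment matrix export includes flags", {
  segs <- two_sample_set()
  ms <- classify_cells(build_segment_matrix(segs), c(A = 2, B = 2))
  f <- tempfile()
  export_segment_matrix(ms, f)
  df <- read.delim(f)
  expect_true(all(c("chrom", "start", "end", "sample", "rel", "state",
                    "is_cn_loh") %in% names(df)))
  expect_equal(nrow(df), nrow(ms$cells))
})
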