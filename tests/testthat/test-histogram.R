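make_classified <- function(df, ploidies) {
  classify_cells(build_segment_matrix(segment_set(df)), ploidies)
}

test_that("stacked percentages count carriers over the whole cohort", {
  ms <- make_classified(data.frame(
    sample = c("S1", "S2", "S3", "S4"), chrom = "c1", start = 0, end = 100,
    n_major = c(2, 2, 1, 1), n_minor = c(1, 1, 0, 1)),
    c(S1 = 2, S2 = 2, S3 = 2, S4 = 2))
  h <- compute_stacked_frequencies(ms)
  expect_equal(h$pct[h$category == 1], 50)
  expect_equal(h$pct[h$category == -1], 25)
  expect_equal(h$pct[h$category == 0], 25)
  expect_equal(h$samples[h$category == 1], "S1,S2")

  ## a single fully neutral sample yields no gain/loss rows
  one <- make_classified(data.frame(sample = "S1", chrom = "c1", start = 0,
                                    end = 100, n_major = 1, n_minor = 1),
                         c(S1 = 2))
  h1 <- compute_stacked_frequencies(one)
  expect_equal(h1$category, 0L)
  expect_equal(h1$pct, 100)
  expect_error(compute_stacked_frequencies(one, n_samples = 0), "empty")
})

test_that("absent samples count in no category", {
  ms <- make_classified(data.frame(
    sample = c("S1", "S2"), chrom = "c1", start = c(0, 50),
    end = c(100, 100), n_major = c(3, 1), n_minor = c(1, 1)),
    c(S1 = 2, S2 = 2))
  h <- compute_stacked_frequencies(ms, n_samples = 2)
  first <- h[h$start == 0, ]
  expect_equal(sum(first$count), 1)     # S2 has no call on [0,50)
  expect_equal(first$pct[first$category == 2], 50)
})

test_that("planted events are recovered at their exact frequency", {
  b <- toy_build(c(c1 = 1e5, c2 = 1e5))
  spec <- cohort_spec(10, b, ploidies = 2,
                      events = data.frame(chrom = "c1", start = 1e4,
                                          end = 2e4, type = "gain",
                                          delta = 2, fraction = 0.3),
                      seed = 5)
  co <- generate_cohort(spec)
  ms <- classify_cells(build_segment_matrix(co$segments),
                       co$truth$ploidy)
  h <- compute_stacked_frequencies(ms)
  gained <- h[h$category == 2, ]
  expect_equal(nrow(gained), 1)
  expect_equal(gained$chrom, "c1")
  expect_equal(c(gained$start, gained$end), c(1e4, 2e4))
  expect_equal(gained$pct, 30)
  expect_equal(strsplit(gained$samples, ",")[[1]],
               co$truth$events$carriers[[1]])
  expect_equal(sum(h$category > 0 & h$chrom == "c2"), 0)
})

test_that("windowed histograms agree with full resolution on whole-window events", {
  b <- toy_build(c(c1 = 1e5))
  w <- make_windows(b, size = 2e4)
  spec <- cohort_spec(5, b, ploidies = 2,
                      events = data.frame(chrom = "c1", start = 2e4,
                                          end = 6e4, type = "gain",
                                          delta = 1, fraction = 0.4),
                      seed = 2)
  co <- generate_cohort(spec)
  p <- co$truth$ploidy
  ms <- classify_cells(build_segment_matrix(co$segments), p)
  rel <- to_relative(build_cnv_matrix(co$segments, w, p), p)
  full <- compute_stacked_frequencies(ms)
  wind <- compute_stacked_frequencies(rel, resolution = "windowed")
  ## same planted gain, same percentage, over the same total extent
  expect_equal(sum(wind$pct[wind$category == 1] *
                     (wind$end[wind$category == 1] -
                        wind$start[wind$category == 1])),
               sum(full$pct[full$category == 1] *
                     (full$end[full$category == 1] -
                        full$start[full$category == 1])))
})

test_that("LOH tracks report negated percentages by mode", {
  ms <- make_classified(data.frame(
    sample = paste0("S", 1:8), chrom = "c1", start = 0, end = 100,
    n_major = c(2, 2, 1, rep(1, 5)), n_minor = c(0, 0, 0, rep(1, 5))),
    setNames(rep(2, 8), paste0("S", 1:8)))
  cn <- compute_loh_tracks(ms, "cn-LOH")
  expect_equal(cn$value, -25)           # 2 of 8 samples are cn-LOH
  loh <- compute_loh_tracks(ms, "LOH")
  expect_equal(loh$value, -37.5)        # the (1,0) loss joins LOH only
  both <- compute_loh_tracks(ms, "both")
  expect_setequal(both$track, c("cn-LOH", "LOH"))
  expect_equal(nrow(compute_loh_tracks(ms, "none")), 0)
  expect_error(compute_loh_tracks(ms, "blue"), "arg")
})

test_that("het/hom tables cross zygosity with net state", {
  ms <- make_classified(data.frame(
    sample = c("S1", "S2", "S3"), chrom = "c1", start = 0, end = 100,
    n_major = c(2, 2, 2), n_minor = c(0, 2, 1)),
    c(S1 = 2, S2 = 2, S3 = 2))
  hh <- compute_hethom_frequencies(ms)
  expect_equal(hh$count[hh$zygosity == "hom" & hh$state == "neutral"], 1)
  expect_equal(hh$count[hh$zygosity == "het" & hh$state == "gain"], 2)
  ## gains/neutral positive ordinates, losses negative
  all_loss <- make_classified(data.frame(
    sample = c("S1", "S2"), chrom = "c1", start = 0, end = 100,
    n_major = 1, n_minor = 0), c(S1 = 2, S2 = 2))
  hl <- compute_hethom_frequencies(all_loss)
  expect_equal(hl$value, -100)
  all_het <- make_classified(data.frame(
    sample = c("S1", "S2"), chrom = "c1", start = 0, end = 100,
    n_major = 1, n_minor = 1), c(S1 = 2, S2 = 2))
  expect_equal(compute_hethom_frequencies(all_het)$value, 100)
})

test_that("event text export round-trips and omits empty categories", {
  ms <- make_classified(data.frame(
    sample = c("S1", "S3", "S7", "S2"), chrom = "c1", start = 0, end = 100,
    n_major = c(3, 3, 3, 1), n_minor = c(1, 1, 1, 1)),
    setNames(rep(2, 4), c("S1", "S2", "S3", "S7")))
  h <- compute_stacked_frequencies(ms, n_samples = 10)
  f <- tempfile()
  export_event_text(h, f)
  back <- read_event_text(f, n_samples = 10)
  expect_equal(back$pct, h$pct)
  expect_equal(back$category, h$category)
  expect_equal(back$samples[back$category == 2], "S1,S3,S7")
  expect_false(any(back$count == 0))
})
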