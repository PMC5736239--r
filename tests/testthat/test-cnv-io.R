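test_that("ASCAT rows parse with coordinate conversion and validation", {
  f <- write_ascat_text("S1\t1\t1\t1000000\t2\t1", tempfile())
  segs <- parse_segments(f, "ascat")
  expect_equal(segs$segments$start, 0)
  expect_equal(segs$segments$end, 1e6)
  expect_equal(segs$segments$n_major, 2)
  expect_equal(segs$segments$total_cn, 3)

  f2 <- write_ascat_text(c("S1\t1\t1\t500\t2\t1",
                           "S1\t1\t401\t900\t3\t1"), tempfile())
  expect_error(parse_segments(f2, "ascat"), "overlap")
  f3 <- write_ascat_text("S1\t1\t1\t500\t-1\t0", tempfile())
  expect_error(parse_segments(f3, "ascat"), "negative|major")
})

test_that("header synonyms and chr prefixes are accepted", {
  f <- tempfile()
  writeLines(c("SampleID\tchromosome\tstart.pos\tend.pos\tmajor\tminor",
               "S1\tchr2\t101\t200\t2\t0"), f)
  b <- toy_build(c(`2` = 1e5))
  segs <- parse_segments(f, "ascat", build = b)
  expect_equal(segs$segments$chrom, "2")
  expect_equal(segs$segments$start, 100)
  writeLines(c("SampleID\tchromosome\tstart.pos\tend.pos\tmajor\tminor",
               "S1\tchr7\t101\t200\t2\t0"), f)
  expect_error(parse_segments(f, "ascat", build = b), "unknown chromosome")
})

test_that("Sequenza directories parse, with missing B treated as 0", {
  d <- tempfile(); dir.create(d)
  writeLines(c("chromosome\tstart.pos\tend.pos\tCNt\tA\tB",
               "chr8\t101\t200\t4\t4\t0"),
             file.path(d, "T1_segments.txt"))
  writeLines(c("chromosome\tstart.pos\tend.pos\tCNt\tA",
               "chr8\t201\t400\t2\t2"),
             file.path(d, "T2_segments.txt"))
  expect_warning(segs <- parse_segments(d, "sequenza"), "treating as 0")
  expect_setequal(segs$samples, c("T1", "T2"))
  t1 <- segs$segments[segs$segments$sample == "T1", ]
  expect_equal(c(t1$start, t1$end, t1$n_major, t1$n_minor),
               c(100, 200, 4, 0))
})

test_that("write/parse round-trips are exact in both dialects", {
  spec <- cohort_spec(4, toy_build(), ploidies = c(2, 3, 4, 2),
                      events = data.frame(chrom = "c1", start = 5e4,
                                          end = 1e5, type = "gain",
                                          delta = 2, fraction = 0.5),
                      gap_rate = 0.1, frag_rate = 10, seed = 3)
  segs <- generate_cohort(spec)$segments
  f <- tempfile(fileext = ".tsv")
  write_segments(segs, f, "ascat")
  expect_equal(parse_segments(f, "ascat")$segments, segs$segments)
  d <- tempfile()
  write_segments(segs, d, "sequenza")
  expect_length(list.files(d), 4)
  expect_equal(parse_segments(d, "sequenza")$segments, segs$segments)
})

test_that("parsing is order-independent", {
  segs <- random_segments(toy_build(), n_samples = 3, seed = 11)
  f <- tempfile(); write_segments(segs, f, "ascat")
  lines <- readLines(f)
  set.seed(1)
  shuffled <- c(lines[1], sample(lines[-1]))
  f2 <- tempfile(); writeLines(shuffled, f2)
  expect_equal(parse_segments(f2, "ascat")$segments,
               parse_segments(f, "ascat")$segments)
})

test_that("sample and ploidy tables read per contract", {
  pf <- tempfile()
  writeLines(c("sample\tploidy", "S1\t4"), pf)
  expect_equal(read_ploidy_table(pf), c(S1 = 4))
  expect_equal(read_ploidy_table(2, samples = c("a", "b")),
               c(a = 2, b = 2))
  expect_equal(read_ploidy_table("2", samples = "a"), c(a = 2))
  writeLines(c("sample\tploidy", "S1\tx"), pf)
  expect_error(read_ploidy_table(pf), "non-numeric")

  sf <- tempfile()
  writeLines(c("Sample\tBCLC\tAlias", "S1\tB\t", "S2\tC\tTumor2"), sf)
  st <- read_sample_table(sf)
  expect_true("BCLC" %in% names(st))
  expect_setequal(st$Sample, c("S1", "Tumor2"))
  writeLines(c("name\tBCLC", "S1\tB"), sf)
  expect_error(read_sample_table(sf), "Sample")
})

test_that("GISTIC export writes log2-ratio segment means", {
  segs <- segment_set(data.frame(
    sample = "S1", chrom = "c1", start = c(0, 1e5, 2e5),
    end = c(1e5, 2e5, 3e5), n_major = c(1, 2, 0), n_minor = c(1, 2, 0)))
  out <- tempfile(fileext = ".seg")
  export_gistic_segments(segs, out)
  g <- read.delim(out)
  expect_equal(g$Start, c(1, 100001, 200001))
  expect_equal(g$Segment_Mean, c(log2(2 / 2), log2(4 / 2), log2(0.1 / 2)))
  expect_true(all(g$Num_Probes >= 5))
})
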