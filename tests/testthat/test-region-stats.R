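region_fixture <- function() {
  ## 4 samples on a 1kb chromosome; region [0,1000)
  ## S1: +1 everywhere; S2: 60% at +4, 40% at +1; S3: neutral; S4: loss
  segment_set(data.frame(
    sample = c("S1", "S2", "S2", "S3", "S4"),
    chrom = "c1",
    start = c(0, 0, 600, 0, 0),
    end = c(1000, 600, 1000, 1000, 1000),
    n_major = c(2, 5, 2, 1, 1),
    n_minor = c(1, 1, 1, 1, 0)))
}

test_that("gain categories aggregate by length-weighted mode", {
  p <- setNames(rep(2, 4), paste0("S", 1:4))
  ms <- classify_cells(build_segment_matrix(region_fixture()), p)
  tab <- gain_category_table(ms, "c1:0-1000", "c1:0-500")
  expect_equal(unname(tab["+1", 1]), 1)       # S1
  expect_equal(unname(tab[">=+4", 1]), 1)     # S2: 600 of 1000 bases at +4
  expect_equal(unname(tab["no gain", 1]), 2)  # S3 neutral, S4 loss
  expect_equal(sum(tab[, 1]), 4)
  no_gain_dropped <- gain_category_table(ms, "c1:0-1000", "c1:0-500",
                                         include_no_gain = FALSE)
  expect_equal(sum(no_gain_dropped[, 1]), 2)
  ## max aggregation promotes any touched gain
  mx <- gain_category_table(ms, "c1:600-1000", "c1:0-500",
                            aggregate = "max")
  expect_equal(unname(mx[">=+4", 2]), 1)      # S2's +4 piece lies in [0,500)
  expect_equal(unname(mx["+1", 2]), 1)        # S1
  expect_error(gain_category_table(ms, "c2:0-100", "c1:0-100"),
               "no segment")
})

test_that("uncovered samples fall in the no-gain row", {
  segs <- segment_set(data.frame(
    sample = c("S1", "S2"), chrom = "c1", start = c(0, 900),
    end = c(1000, 1000), n_major = c(3, 4), n_minor = c(1, 1)))
  ms <- classify_cells(build_segment_matrix(segs), c(S1 = 2, S2 = 2))
  tab <- gain_category_table(ms, "c1:0-1000", "c1:900-1000")
  ## S2 covers 10% of region a: mostly uncovered -> no gain there
  expect_equal(unname(tab["no gain", 1]), 1)
  expect_equal(unname(tab["+2", 1]), 1)
  ## in region b both are fully categorical
  expect_equal(unname(tab["+3", 2]), 1)
  expect_equal(unname(tab["+2", 2]), 1)
})

test_that("fisher p matches the worked 2x2 example and edge cases", {
  expect_equal(as.numeric(fisher_exact(matrix(c(3, 1, 1, 3), 2))), 34 / 70,
               tolerance = 1e-12)
  expect_equal(as.numeric(fisher_exact(matrix(c(1, 1, 1, 1), 2))), 1)
  expect_warning(p <- fisher_exact(matrix(c(0, 0, 3, 4), nrow = 2)),
                 "degenerate")
  expect_equal(as.numeric(p), 1)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "negative")
})

test_that("fisher p equals same-margin enumeration on random tables", {
  set.seed(42)
  for (i in 1:60) {
    r <- sample(2:4, 1)
    tab <- matrix(rpois(2 * r, 3), nrow = r)
    if (sum(tab) < 2 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    p <- as.numeric(fisher_exact(tab))
    oracle <- if (r == 2) oracle_fisher_2x2(tab) else oracle_fisher_rx2(tab)
    expect_equal(p, oracle, tolerance = 1e-7, info = paste("table", i))
    ## invariance to row and column swaps
    expect_equal(as.numeric(fisher_exact(tab[rev(seq_len(r)), ])), p,
                 tolerance = 1e-12)
    expect_equal(as.numeric(fisher_exact(tab[, 2:1])), p,
                 tolerance = 1e-12)
  }
})

test_that("monte-carlo mode engages on large r x 2 tables and converges", {
  tab <- matrix(c(60, 50, 40, 30, 70, 60), nrow = 3)  # total 310 > limit
  exact <- oracle_fisher_rx2(tab)
  set.seed(7)
  p <- fisher_exact(tab, exact_limit = 200, replicates = 20000)
  expect_equal(attr(p, "method"), "monte-carlo")
  expect_equal(attr(p, "replicates"), 20000)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(as.numeric(p) - exact), 3 * se + 1e-4)
  ## 2x2 tables stay exact whatever the total
  big <- matrix(c(600, 900, 1400, 1100), nrow = 2)
  expect_equal(attr(fisher_exact(big), "method"), "exact")
  expect_equal(as.numeric(fisher_exact(big)), oracle_fisher_2x2(big),
               tolerance = 1e-9)
})

test_that("compare_regions chains the table and the test", {
  p <- setNames(rep(2, 4), paste0("S", 1:4))
  ms <- classify_cells(build_segment_matrix(region_fixture()), p)
  res <- compare_regions(ms, "c1:0-1000", "c1:0-500")
  expect_s3_class(res$table, "ContingencyTable")
  expect_true(res$p.value >= 0 && res$p.value <= 1)
})
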