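## Independent brute-force oracles.  Each works per base / per table /
## per agglomeration step from first principles and shares no code with
## the implementation it checks.

## per-base copy-number vector of one sample on one chromosome:
## fill everywhere, then overwrite called bases (0-based half-open)
oracle_base_vector <- function(seg_rows, chrom_len, fill) {
  v <- rep(fill, chrom_len)
  for (r in seq_len(nrow(seg_rows))) {
    s <- seg_rows$start[r]; e <- seg_rows$end[r]
    v[(s + 1):e] <- seg_rows$total_cn[r]
  }
  v
}

## expected CNVMatrix values: per-base mean over each window, rounded
## half away from zero
oracle_window_matrix <- function(segs, windows, build, fill_values) {
  samples <- segs$samples
  out <- matrix(NA_real_, length(samples), nrow(windows))
  for (si in seq_along(samples)) {
    for (chrom in unique(windows$chrom)) {
      len <- build$chromosomes$length[build$chromosomes$chrom == chrom]
      d <- segs$segments[segs$segments$sample == samples[si] &
                           segs$segments$chrom == chrom, , drop = FALSE]
      v <- oracle_base_vector(d, len, fill_values[[samples[si]]])
      w <- windows[windows$chrom == chrom, , drop = FALSE]
      for (k in seq_len(nrow(w))) {
        m <- mean(v[(w$start[k] + 1):w$end[k]])
        out[si, w$index[k]] <- sign(m) * floor(abs(m) + 0.5)
      }
    }
  }
  rownames(out) <- samples
  out
}

## per-base check of a segment matrix: for every base of every input
## call, the cell covering it must carry the call's copy numbers, and
## bases outside any call of that sample must have no cell
oracle_check_segment_matrix <- function(ms, segs, build) {
  seg <- ms$segments
  for (s in segs$samples) {
    cells_s <- ms$cells[ms$cells$sample == s, , drop = FALSE]
    for (chrom in unique(seg$chrom)) {
      len <- build$chromosomes$length[build$chromosomes$chrom == chrom]
      d <- segs$segments[segs$segments$sample == s &
                           segs$segments$chrom == chrom, , drop = FALSE]
      truth <- rep(NA_real_, len)
      for (r in seq_len(nrow(d)))
        truth[(d$start[r] + 1):d$end[r]] <- d$total_cn[r]
      got <- rep(NA_real_, len)
      pc <- seg[seg$chrom == chrom, , drop = FALSE]
      cc <- cells_s[cells_s$segment %in% pc$segment, , drop = FALSE]
      for (r in seq_len(nrow(cc))) {
        p <- pc[pc$segment == cc$segment[r], ]
        got[(p$start + 1):p$end] <- cc$total_cn[r]
      }
      if (!identical(is.na(truth), is.na(got)) ||
          !isTRUE(all.equal(truth[!is.na(truth)], got[!is.na(got)])))
        return(FALSE)
    }
  }
  TRUE
}

## brute-force Ward agglomeration ("ward.D": Lance-Williams update on
## unsquared Euclidean distances); returns merge heights and the full
## cophenetic matrix for topology comparison
oracle_ward <- function(x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  size <- rep(1, n)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      a <- active[ii]; b <- active[jj]
      if (d[a, b] < best_d) { best_d <- d[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    heights[step] <- best_d
    for (ma in members[[a]]) for (mb in members[[b]])
      coph[ma, mb] <- coph[mb, ma] <- best_d
    for (k in active) {
      if (k == a || k == b) next
      d[a, k] <- d[k, a] <-
        ((size[a] + size[k]) * d[a, k] + (size[b] + size[k]) * d[b, k] -
           size[k] * d[a, b]) / (size[a] + size[b] + size[k])
    }
    members[[a]] <- c(members[[a]], members[[b]])
    size[a] <- size[a] + size[b]
    active <- setdiff(active, b)
  }
  list(heights = sort(heights), cophenetic = coph)
}

## exact two-sided Fisher p for a 2x2 table: enumerate all tables with
## the observed margins, sum hypergeometric probabilities not exceeding
## the observed one (standard 1e-7 relative tolerance on the comparison)
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## exact conditional Fisher p for an r x 2 table: enumerate every table
## with the observed margins (first column determines the table)
oracle_fisher_rx2 <- function(tab) {
  r <- rowSums(tab); c1 <- sum(tab[, 1]); n <- sum(tab)
  nr <- length(r)
  grids <- lapply(r[-nr], function(ri) 0:min(ri, c1))
  combos <- as.matrix(expand.grid(grids))
  last <- c1 - rowSums(combos)
  ok <- last >= 0 & last <= r[nr]
  combos <- cbind(combos[ok, , drop = FALSE], last[ok])
  logp <- rep(-lchoose(n, c1), nrow(combos))
  for (i in seq_len(nr))
    logp <- logp + lchoose(r[i], combos[, i])
  p_obs_log <- -lchoose(n, c1) + sum(lchoose(r, tab[, 1]))
  sum(exp(logp)[logp <= p_obs_log + log(1 + 1e-7)])
}

## brute-force per-base tiler for window construction: returns the
## per-base window id (NA inside the centromere / outside all windows)
oracle_window_coverage <- function(windows, chrom, chrom_len) {
  w <- windows[windows$chrom == chrom, , drop = FALSE]
  v <- rep(NA_integer_, chrom_len)
  for (k in seq_len(nrow(w))) v[(w$start[k] + 1):w$end[k]] <- w$index[k]
  v
}
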