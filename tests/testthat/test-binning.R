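make_track <- function(fwd, rev = NULL, chrom = "chr1") {
  cl <- setNames(length(fwd), chrom)
  coverage_track("t", cl,
                 forward = setNames(list(fwd), chrom),
                 reverse = setNames(list(rev %||% numeric(length(fwd))), chrom))
}

test_that("constant and zero coverage bin to their exact means", {
  tr <- make_track(rep(3, 1000))
  b <- bin_coverage(tr, 500)
  expect_equal(nrow(b), 4)  # 2 bins x 2 strands
  expect_equal(b$mean[b$strand == "+"], c(3, 3))
  expect_equal(b$mean[b$strand == "-"], c(0, 0))
  expect_true(all(bin_coverage(make_track(numeric(800)), 500)$mean == 0))
})

test_that("bin means match a per-position oracle, trailing partial bin included", {
  x <- withr::with_seed(21, round(runif(1234, 0, 50), 2))
  tr <- make_track(x, rev = rev(x))
  b <- bin_coverage(tr, 500)
  fwd <- b[b$strand == "+", ]
  expect_equal(fwd$mean, oracle_bin_means(x, 500))
  expect_equal(fwd$end - fwd$start, c(500L, 500L, 234L))
  expect_equal(b$mean[b$strand == "-"], oracle_bin_means(rev(x), 500))
  # conservation: sum(bin mean * span) recovers the array total per strand
  expect_equal(sum(fwd$mean * (fwd$end - fwd$start)), sum(x),
               tolerance = 1e-9)
  expect_error(bin_coverage(tr, 5000), "longest")
})

test_that("percentile threshold interpolates linearly between closest ranks", {
  means <- c(numeric(30), 1:100)  # zeros must be ignored
  tr <- make_track(rep(means, each = 10), rev = rep(rev(means), each = 10))
  b <- bin_coverage(tr, 10)
  thr <- compute_strand_threshold(b, 85)
  expect_equal(unname(thr[["+"]]), 85.15)
  expect_equal(unname(thr[["-"]]), 85.15)
  expect_equal(unname(thr[["+"]]), oracle_percentile(1:100, 85))
  # degenerate: all expressed bins equal v -> threshold v, nothing above
  tr2 <- make_track(rep(c(0, 7), each = 500), rev = rep(7, 1000))
  b2 <- bin_coverage(tr2, 100)
  thr2 <- compute_strand_threshold(b2, 85)
  expect_equal(unname(thr2), c(7, 7))
  expect_equal(nrow(call_bidirectional_bins(b2, thr2)), 0)
})

test_that("threshold errors without expressed bins and honors pooling", {
  tr <- make_track(rep(2, 1000))  # minus strand all zero
  b <- bin_coverage(tr, 500)
  expect_error(compute_strand_threshold(b, 85), "no expressed bins")
  tr2 <- make_track(c(rep(2, 500), rep(8, 500)), rev = rep(c(4, 0), each = 500))
  b2 <- bin_coverage(tr2, 500)
  pooled <- compute_strand_threshold(b2, 50, pooled = TRUE)
  expect_equal(unname(pooled[["+"]]), unname(pooled[["-"]]))
  expect_equal(unname(pooled[["+"]]), median(c(2, 8, 4)))
  expect_error(compute_strand_threshold(b2, 0), "between")
  expect_error(compute_strand_threshold(b2, 100), "between")
})

test_that("percentile calibration: fraction strictly above q-th percentile", {
  for (seed in 1:20) {
    x <- withr::with_seed(seed, runif(150, 0.01, 100))  # distinct nonzero means
    thr <- oracle_percentile(x, 85)
    frac <- mean(x > thr)
    # interpolation between closest ranks pins the pass fraction to within
    # one rank of the nominal top share
    expect_lte(frac, 0.15 + 1 / length(x))
    expect_gte(frac, 0.15 - 1 / length(x))
  }
})

test_that("dual-strand calling equals the intersection of per-strand filters", {
  for (seed in 1:5) {
    n <- 200
    fwd <- withr::with_seed(seed, rexp(n, 1 / 5))
    rev <- withr::with_seed(seed + 100, rexp(n, 1 / 5))
    tr <- make_track(rep(fwd, each = 10), rev = rep(rev, each = 10))
    b <- bin_coverage(tr, 10)
    thr <- compute_strand_threshold(b, 85)
    called <- call_bidirectional_bins(b, thr)
    mf <- b$mean[b$strand == "+"]
    mr <- b$mean[b$strand == "-"]
    pass_f <- which(mf > thr[["+"]])
    pass_r <- which(mr > thr[["-"]])
    expect_equal(called$bin, intersect(pass_f, pass_r) - 1L)
    expect_equal(called$fwd_mean, mf[called$bin + 1L])
  }
})

test_that("forward-only expression yields no bidirectional bins", {
  fwd <- withr::with_seed(9, rexp(100, 1))
  rev <- rep(0.01, 100)  # expressed but uniform: nothing strictly above
  tr <- make_track(rep(fwd, each = 10), rev = rep(rev, each = 10))
  b <- bin_coverage(tr, 10)
  called <- call_bidirectional_bins(b, compute_strand_threshold(b, 85))
  expect_equal(nrow(called), 0)
})

test_that("calling is monotone in coverage at fixed thresholds", {
  fwd <- withr::with_seed(13, rexp(100, 1 / 5))
  rev <- withr::with_seed(14, rexp(100, 1 / 5))
  tr <- make_track(rep(fwd, each = 10), rep(rev, each = 10))
  b <- bin_coverage(tr, 10)
  thr <- compute_strand_threshold(b, 85)
  base_called <- call_bidirectional_bins(b, thr)$bin
  # raising any bin's coverage never removes a called bin
  b_up <- b
  b_up$mean <- b_up$mean * ifelse(b_up$bin %% 3 == 0, 2, 1)
  up_called <- call_bidirectional_bins(b_up, thr)$bin
  expect_true(all(base_called %in% up_called))
})

test_that("adjacent bins merge into maximal runs with correct spans", {
  bins <- tibble::tibble(
    chrom = "chr1", bin = c(0L, 1L, 4L),
    start = c(0L, 500L, 2000L), end = c(500L, 1000L, 2500L),
    fwd_mean = c(2, 4, 6), rev_mean = c(1, 3, 5)
  )
  iv <- merge_adjacent_bins(bins)
  expect_equal(iv$start, c(0L, 2000L))
  expect_equal(iv$end, c(1000L, 2500L))
  expect_equal(iv$n_bins, c(2L, 1L))
  expect_equal(iv$fwd_mean, c(3, 6))
  # max_gap_bins = 1 bridges the single-bin gap chain
  iv2 <- merge_adjacent_bins(dplyr::mutate(bins, bin = c(0L, 2L, 4L),
                                           start = bin * 500L, end = start + 500L),
                             max_gap_bins = 1)
  expect_equal(nrow(iv2), 1)
  expect_equal(iv2$n_bins, 3L)
  expect_equal(nrow(merge_adjacent_bins(bins[0, ])), 0)
})

test_that("merging preserves the base union and counts connected components", {
  for (seed in 1:5) {
    picks <- withr::with_seed(seed, sort(sample(0:999, 300)))
    bins <- tibble::tibble(
      chrom = rep("chr1", 300), bin = as.integer(picks),
      start = as.integer(picks * 500), end = as.integer(picks * 500 + 500),
      fwd_mean = 1, rev_mean = 1
    )
    iv <- merge_adjacent_bins(bins)
    # component count: runs of consecutive indices
    expect_equal(nrow(iv), sum(diff(picks) > 1) + 1)
    expect_equal(sum(iv$end - iv$start), 300 * 500)
    expect_equal(sum(iv$n_bins), 300)
    # idempotence on the interval level: re-merging changes nothing
    again <- merge_adjacent_bins(
      dplyr::mutate(iv, bin = as.integer(start %/% 500),
                    fwd_mean = 1, rev_mean = 1))
    expect_equal(again$start, iv$start)
    expect_equal(again$end, iv$end)
  }
})
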