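#' Mean coverage per fixed-width genomic bin, per strand
#'
#' Partitions every chromosome into consecutive `bin_size`-bp bins anchored
#' at position 0 and computes the arithmetic mean of per-base coverage over
#' each bin's actual span, separately for the two strands. A trailing
#' partial bin at a chromosome end uses its true (shorter) span. Every bin
#' is represented, zeros included.
#'
#' @param track A [coverage_track()].
#' @param bin_size Bin width in bp (default 500).
#'
#' @return A tibble of class `bin_table` with columns `chrom`, `bin`
#'   (0-based index), `start`, `end` (0-based half-open), `strand`
#'   (`"+"`/`"-"`) and `mean`. Bin width and chromosome lengths are carried
#'   as attributes `bin_size` and `chrom_lengths`.
#' @export
bin_coverage <- function(track, bin_size = 500) {
  stopifnot(inherits(track, "coverage_track"))
  bin_size <- as.integer(bin_size)
  if (bin_size < 1) abort("`bin_size` must be >= 1")
  if (bin_size > max(track$chrom_lengths)) {
    abort("`bin_size` exceeds the longest chromosome")
  }
  one_chrom <- function(chrom, strand) {
    x <- if (strand == "+") track$forward[[chrom]] else track$reverse[[chrom]]
    len <- track$chrom_lengths[[chrom]]
    n_bins <- ceiling(len / bin_size)
    starts <- (seq_len(n_bins) - 1L) * bin_size
    ends <- pmin(starts + bin_size, len)
    spans <- ends - starts
    # per-bin summation (not a running sum), so identical bins give
    # bit-identical means and strict threshold comparisons behave
    sums <- rowsum(x, rep.int(seq_len(n_bins), spans), reorder = FALSE)
    tibble(
      chrom = chrom, bin = seq_len(n_bins) - 1L,
      start = starts, end = ends, strand = strand,
      mean = as.vector(sums) / spans
    )
  }
  out <- bind_rows(lapply(names(track$chrom_lengths), function(chrom) {
    bind_rows(one_chrom(chrom, "+"), one_chrom(chrom, "-"))
  }))
  structure(
    arrange(out, .data$chrom, .data$bin, .data$strand),
    class = c("bin_table", class(out)),
    bin_size = bin_size,
    chrom_lengths = track$chrom_lengths,
    sample_id = track$sample_id
  )
}

#' Per-strand expression thresholds over expressed bins
#'
#' A bin counts as expressed on a strand when its mean coverage is greater
#' than zero. The calling threshold for each strand is the `percentile`-th
#' percentile (linear interpolation between closest ranks) of the multiset
#' of expressed-bin means on that strand — by default the 85th percentile,
#' i.e. the top 15% of expressed bins pass. With `pooled = TRUE` a single
#' threshold is computed over both strands' expressed bins and used for
#' both.
#'
#' @param bins A `bin_table` from [bin_coverage()].
#' @param percentile Percentile in (0, 100); default 85.
#' @param pooled Compute one threshold over both strands (default `FALSE`:
#'   per-strand thresholds, robust to strand-specific library depth
#'   asymmetry).
#'
#' @return Named numeric vector `c("+" = ..., "-" = ...)`.
#' @export
compute_strand_threshold <- function(bins, percentile = 85, pooled = FALSE) {
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100) {
    abort("`percentile` must lie strictly between 0 and 100")
  }
  thr_of <- function(x, strand) {
    x <- x[x > 0]
    if (length(x) == 0) {
      abort(sprintf("no expressed bins on strand %s", strand))
    }
    unname(quantile(x, percentile / 100, type = 7, names = FALSE))
  }
  if (pooled) {
    t <- thr_of(bins$mean, "either")
    return(c("+" = t, "-" = t))
  }
  c(
    "+" = thr_of(bins$mean[bins$strand == "+"], "+"),
    "-" = thr_of(bins$mean[bins$strand == "-"], "-")
  )
}

#' Call bins transcribed from both strands
#'
#' A bin is bidirectionally transcribed when its mean coverage is strictly
#' above the threshold on the plus strand AND strictly above the threshold
#' on the minus strand. Ties at a threshold fail.
#'
#' @param bins A `bin_table` from [bin_coverage()].
#' @param thresholds Named vector `c("+" = ..., "-" = ...)` from
#'   [compute_strand_threshold()].
#'
#' @return Tibble with columns `chrom`, `bin`, `start`, `end`, `fwd_mean`,
#'   `rev_mean`, sorted by position; attributes of `bins` are carried over.
#' @export
call_bidirectional_bins <- function(bins, thresholds) {
  if (!all(c("+", "-") %in% names(thresholds))) {
    abort('`thresholds` must be named "+" and "-"')
  }
  wide <- tidyr::pivot_wider(
    as_tibble(bins),
    names_from = "strand", values_from = "mean"
  )
  out <- wide |>
    rename(fwd_mean = "+", rev_mean = "-") |>
    filter(.data$fwd_mean > thresholds[["+"]], .data$rev_mean > thresholds[["-"]]) |>
    arrange(.data$chrom, .data$bin)
  structure(out,
    bin_size = attr(bins, "bin_size"),
    chrom_lengths = attr(bins, "chrom_lengths")
  )
}

#' Merge adjacent bidirectional bins into intervals
#'
#' Maximal runs of consecutive bin indices on a chromosome become one
#' unstranded interval (book-ended merge; `max_gap_bins` generalizes the
#' gap allowed between runs, default 0). Per-strand means are the means of
#' the constituent bin means.
#'
#' @param bidir_bins Output of [call_bidirectional_bins()].
#' @param max_gap_bins Merge runs separated by at most this many
#'   non-qualifying bins (default 0: strict adjacency).
#'
#' @return Tibble with `chrom`, `start`, `end`, `n_bins`, `fwd_mean`,
#'   `rev_mean`, sorted and non-overlapping.
#' @export
merge_adjacent_bins <- function(bidir_bins, max_gap_bins = 0) {
  stopifnot(max_gap_bins >= 0)
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    n_bins = integer(), fwd_mean = numeric(), rev_mean = numeric()
  )
  if (nrow(bidir_bins) == 0) return(empty)
  bidir_bins |>
    arrange(.data$chrom, .data$bin) |>
    group_by(.data$chrom) |>
    mutate(run = cumsum(c(1L, diff(.data$bin) > max_gap_bins + 1L))) |>
    group_by(.data$chrom, .data$run) |>
    summarise(
      start = min(.data$start), end = max(.data$end), n_bins = n(),
      fwd_mean = mean(.data$fwd_mean), rev_mean = mean(.data$rev_mean),
      .groups = "drop"
    ) |>
    select(-"run") |>
    arrange(.data$chrom, .data$start)
}

#' Identify bidirectionally transcribed intervals in one call
#'
#' Convenience wrapper chaining [bin_coverage()],
#' [compute_strand_threshold()], [call_bidirectional_bins()] and
#' [merge_adjacent_bins()].
#'
#' @inheritParams bin_coverage
#' @inheritParams compute_strand_threshold
#' @inheritParams merge_adjacent_bins
#'
#' @return As [merge_adjacent_bins()], with the thresholds used attached as
#'   attribute `thresholds`.
#' @export
find_bidirectional_intervals <- function(track, bin_size = 500, percentile = 85,
                                         pooled = FALSE, max_gap_bins = 0) {
  bins <- bin_coverage(track, bin_size)
  thr <- compute_strand_threshold(bins, percentile, pooled)
  out <- merge_adjacent_bins(call_bidirectional_bins(bins, thr), max_gap_bins)
  attr(out, "thresholds") <- thr
  out
}
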