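# Independent brute-force oracles. Each recomputes a quantity by direct
# position-by-position or all-pairs enumeration, deliberately ignoring the
# package's implementation path.

oracle_expand_bedgraph <- function(records, chrom_lengths) {
  arrays <- lapply(chrom_lengths, numeric)
  for (i in seq_len(nrow(records))) {
    for (pos in (records$start[i] + 1):records$end[i]) {
      arrays[[records$chrom[i]]][pos] <- records$value[i]
    }
  }
  arrays
}

oracle_bin_means <- function(x, bin_size) {
  n_bins <- ceiling(length(x) / bin_size)
  vapply(seq_len(n_bins), function(k) {
    a <- (k - 1) * bin_size + 1
    b <- min(k * bin_size, length(x))
    mean(x[a:b])
  }, numeric(1))
}

oracle_percentile <- function(x, q) {
  # linear interpolation between closest ranks on the sorted values
  x <- sort(x)
  h <- (length(x) - 1) * q / 100 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

oracle_interval_overlaps <- function(intervals, te) {
  rows <- list()
  for (i in seq_len(nrow(te))) {
    for (j in seq_len(nrow(intervals))) {
      if (te$chrom[i] != intervals$chrom[j]) next
      ov <- min(te$end[i], intervals$end[j]) - max(te$start[i], intervals$start[j])
      if (ov >= 1) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = te$chrom[i], start = te$start[i], end = te$end[i],
          subfamily = te$subfamily[i],
          interval_start = intervals$start[j], interval_end = intervals$end[j],
          overlap_bp = ov
        )
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$interval_start), ]
}

oracle_nearest_tss_distance <- function(loci, genes) {
  vapply(seq_len(nrow(loci)), function(i) {
    d <- Inf
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != loci$chrom[i]) next
      t <- genes$tss[j]
      d <- min(d, max(0, loci$start[i] - t, t - (loci$end[i] - 1)))
    }
    d
  }, numeric(1))
}

oracle_pileup <- function(starts, widths, len) {
  vapply(seq_len(len) - 1L, function(pos) {
    sum(starts <= pos & pos < starts + widths)
  }, numeric(1))
}

# exact upper tail by exhaustive enumeration of all C(N, n) draws
oracle_hyper_enum <- function(k, N, K, n) {
  draws <- utils::combn(N, n)
  in_ref <- seq_len(N) <= K
  mean(apply(draws, 2, function(d) sum(in_ref[d]) >= k))
}

# exact upper tail by direct term summation with factorial cancellation
oracle_hyper_terms <- function(k, N, K, n) {
  sum(vapply(k:min(K, n), function(i) {
    exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  }, numeric(1)))
}

random_track <- function(chrom_lengths, seed, density = 0.3, max_val = 20) {
  withr::with_seed(seed, {
    arrays <- lapply(chrom_lengths, function(L) {
      x <- numeric(L)
      nz <- sample.int(L, round(density * L))
      x[nz] <- round(runif(length(nz), 0.1, max_val), 3)
      x
    })
    coverage_track("rnd", chrom_lengths,
                   forward = arrays,
                   reverse = lapply(arrays, function(x) rev(x)))
  })
}
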