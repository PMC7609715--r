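#' Read a RepeatMasker-style TE annotation (BED6)
#'
#' The interchange dialect is BED6 with the name field `"subfamily:class"`
#' (e.g. `L1PA1:LINE`). A name without a colon is taken as the subfamily
#' with class `"other"` (with a warning); classes outside
#' LINE/SINE/LTR/DNA are mapped to `"other"`. Coordinates are 0-based
#' half-open; the TE's genomic orientation is retained in `strand`.
#'
#' @param path Path to a BED6 file.
#' @return Tibble with columns `chrom`, `start`, `end`, `subfamily`,
#'   `te_class`, `strand`, sorted by (chrom, start).
#' @export
read_te_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) > 0 && any(GenomicRanges::width(gr) < 1)) {
    abort(sprintf("zero- or negative-length record in %s", path))
  }
  nm <- S4Vectors::mcols(gr)$name
  nm[is.na(nm)] <- ""
  no_colon <- !grepl(":", nm, fixed = TRUE)
  if (any(no_colon)) {
    warn(sprintf(
      "%d TE name(s) without a ':class' suffix; class set to 'other' (e.g. '%s')",
      sum(no_colon), nm[no_colon][1]
    ))
  }
  subfamily <- sub(":.*$", "", nm)
  te_class <- ifelse(no_colon, "other", sub("^[^:]*:", "", nm))
  te_class[!te_class %in% c("LINE", "SINE", "LTR", "DNA")] <- "other"
  if (any(!nzchar(subfamily))) abort(sprintf("empty TE subfamily name in %s", path))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    subfamily = subfamily,
    te_class = te_class,
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    arrange(.data$chrom, .data$start)
}

#' Write a TE annotation tibble as BED6
#'
#' @param te Tibble as returned by [read_te_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_bed <- function(te, path) {
  strand <- ifelse(te$strand %in% c("+", "-"), te$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = te$chrom,
    ranges = IRanges::IRanges(start = te$start + 1L, end = te$end),
    strand = strand,
    name = paste0(te$subfamily, ":", te$te_class),
    score = 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Intersect bidirectional intervals with a TE annotation
#'
#' Reports every (TE locus, bidirectional interval) pair overlapping by at
#' least 1 bp, the unit the family ranking and length summaries are built
#' from. A TE locus overlapped by several intervals yields one row per
#' interval; family tallies count each locus once. Bidirectionality is
#' defined on genome strands, so TE orientation plays no role in the
#' intersection and is retained for reporting only.
#'
#' @param intervals Tibble of unstranded intervals (`chrom`, `start`, `end`,
#'   plus any carried columns), e.g. from [merge_adjacent_bins()].
#' @param te TE annotation tibble (see [read_te_bed()]).
#'
#' @return Tibble with one row per overlapping pair: the TE columns, the
#'   interval coordinates (`interval_start`, `interval_end`, and `n_bins`,
#'   `fwd_mean`, `rev_mean` when present) and `overlap_bp`.
#' @export
intersect_with_te <- function(intervals, te) {
  carried <- intersect(c("n_bins", "fwd_mean", "rev_mean"), names(intervals))
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    subfamily = character(), te_class = character(), strand = character(),
    interval_start = integer(), interval_end = integer()
  )
  for (col in carried) empty[[col]] <- numeric()
  empty$overlap_bp <- integer()
  if (nrow(intervals) == 0 || nrow(te) == 0) return(empty)
  gr_te <- GenomicRanges::GRanges(te$chrom, IRanges::IRanges(te$start + 1L, te$end))
  gr_iv <- GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start + 1L, intervals$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_te, gr_iv, minoverlap = 1L)
  if (length(hits) == 0) return(empty)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(gr_te[i], gr_iv[j])
  out <- te[i, c("chrom", "start", "end", "subfamily", "te_class", "strand")]
  out$interval_start <- intervals$start[j]
  out$interval_end <- intervals$end[j]
  for (col in carried) out[[col]] <- intervals[[col]][j]
  out$overlap_bp <- GenomicRanges::width(ov)
  arrange(out, .data$chrom, .data$start, .data$interval_start)
}

#' Rank TE subfamilies by number of distinct bidirectional loci
#'
#' Counts distinct TE loci per subfamily among the intersection calls and
#' sorts descending; ties break alphabetically by subfamily. On coverage
#' with derepressed young LINE-1s the top hits are the hominid-specific
#' subfamilies (L1PA1, then L1PA2).
#'
#' @param calls Output of [intersect_with_te()].
#' @return Tibble `subfamily`, `te_class`, `n_loci`, sorted.
#' @export
rank_families <- function(calls) {
  calls |>
    distinct(.data$chrom, .data$start, .data$end, .data$subfamily, .data$te_class) |>
    dplyr::count(.data$subfamily, .data$te_class, name = "n_loci") |>
    arrange(desc(.data$n_loci), .data$subfamily)
}

#' Plot a TE family ranking
#'
#' Horizontal bar chart of distinct bidirectional loci per TE subfamily.
#'
#' @param ranking Output of [rank_families()].
#' @param top Show at most this many subfamilies (default 15).
#' @return A ggplot.
#' @export
plot_family_ranking <- function(ranking, top = 15) {
  df <- head(ranking, top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$n_loci,
    y = stats::reorder(.data$subfamily, .data$n_loci),
    fill = .data$te_class
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "distinct bidirectional loci", y = NULL,
                  fill = "class") +
    ggplot2::theme_minimal()
}

#' Full-length status and median length of bidirectional TE loci
#'
#' A TE copy is flagged full-length when its annotated genomic length is at
#' least `min_fraction` of its subfamily consensus length (the fraction is
#' a reporting convention, not part of the detection). Loci of subfamilies
#' without a known consensus length get `full_length = NA` and are excluded
#' from the full-length fraction but included in the median length. The
#' median is over the annotated lengths of the distinct TE loci in `calls`
#' (mean of the two central values for an even count). Full-length young
#' LINE-1 loci put this median near 6 kb.
#'
#' @param calls Output of [intersect_with_te()].
#' @param consensus_lengths Named numeric vector, subfamily -> consensus
#'   length (bp), or a tibble with columns `subfamily`, `consensus_length`.
#' @param min_fraction Fraction of the consensus length required to call a
#'   copy full-length; in (0, 1], default 0.9.
#'
#' @return List of class `full_length_summary` with elements `loci`
#'   (distinct loci with `length_bp`, `consensus_length`, `full_length`),
#'   `median_length_bp`, `n_loci`, `n_full_length`, `frac_full_length`
#'   (among loci with known consensus) and `min_fraction`.
#' @export
full_length_summary <- function(calls, consensus_lengths, min_fraction = 0.9) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    abort("`min_fraction` must lie in (0, 1]")
  }
  if (is_tibble(consensus_lengths) || is.data.frame(consensus_lengths)) {
    consensus_lengths <- setNames(
      consensus_lengths$consensus_length, consensus_lengths$subfamily
    )
  }
  loci <- calls |>
    distinct(.data$chrom, .data$start, .data$end, .data$subfamily, .data$te_class) |>
    mutate(
      length_bp = .data$end - .data$start,
      consensus_length = unname(consensus_lengths[.data$subfamily]),
      full_length = .data$length_bp >= min_fraction * .data$consensus_length
    )
  known <- !is.na(loci$full_length)
  structure(
    list(
      loci = loci,
      median_length_bp = if (nrow(loci)) median(loci$length_bp) else NA_real_,
      n_loci = nrow(loci),
      n_full_length = sum(loci$full_length[known]),
      frac_full_length = if (any(known)) mean(loci$full_length[known]) else NA_real_,
      min_fraction = min_fraction
    ),
    class = "full_length_summary"
  )
}

#' @export
print.full_length_summary <- function(x, ...) {
  cat(sprintf(
    "<full_length_summary> %d distinct loci; median length %.0f bp; %d full-length (%.1f%% of loci with known consensus, >= %.0f%% of consensus)\n",
    x$n_loci, x$median_length_bp, x$n_full_length,
    100 * x$frac_full_length, 100 * x$min_fraction
  ))
  invisible(x)
}
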