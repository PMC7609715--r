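#' Read primary alignments to TE consensus sequences from a SAM file
#'
#' Loads the primary alignments of reads mapped to a set of consensus
#' sequences (one `@SQ` header per consensus). Secondary and supplementary
#' alignments are excluded; unmapped reads are skipped and counted. The
#' 1-based SAM position is converted to a 0-based offset, the strand comes
#' from the reverse-complement flag, and the aligned length is the
#' reference-space CIGAR width (M/=/X and D count; insertions and clips do
#' not).
#'
#' @param path Path to a SAM file.
#' @return Tibble `read_id`, `consensus_id`, `strand` (`"+"`/`"-"`),
#'   `start` (0-based), `aligned_length` (bp), with attributes
#'   `consensus_lengths` (named vector from the header) and `n_unmapped`.
#' @export
read_consensus_alignments <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    Rsamtools::BamFile(bam),
    param = Rsamtools::ScanBamParam(flag = flag),
    use.names = TRUE
  )
  n_unmapped <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)
    )
  )$records
  si <- GenomeInfoDb::seqlengths(ga)
  out <- tibble(
    read_id = names(ga) %||% rep(NA_character_, length(ga)),
    consensus_id = as.character(GenomicAlignments::seqnames(ga)),
    strand = as.character(GenomicAlignments::strand(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    aligned_length = GenomicAlignments::width(ga)
  )
  attr(out, "consensus_lengths") <- si
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Per-sample size factors from a feature count table
#'
#' Two conventions for "size factors calculated for the entire library":
#' `total_count` scales by per-sample totals, normalized so the geometric
#' mean of the factors is 1; `median_of_ratios` is the count-based
#' median-of-ratios estimator (per-feature geometric means across samples,
#' factor = median ratio over features non-zero in every sample).
#'
#' @param counts Numeric matrix, features x samples (column names are
#'   sample ids), or a data frame with a `feature` column and one column
#'   per sample.
#' @param method `"total_count"` (default) or `"median_of_ratios"`.
#' @return Named numeric vector of size factors, one per sample.
#' @export
compute_size_factors <- function(counts, method = c("total_count", "median_of_ratios")) {
  method <- match.arg(method)
  if (is.data.frame(counts)) {
    feature_col <- intersect(c("feature", "consensus_id"), names(counts))[1]
    if (!is.na(feature_col)) counts <- counts[setdiff(names(counts), feature_col)]
    counts <- as.matrix(counts)
  }
  geo_mean <- function(x) exp(mean(log(x)))
  if (method == "total_count") {
    totals <- colSums(counts)
    if (any(totals <= 0)) abort("every sample must have a positive total count")
    return(totals / geo_mean(totals))
  }
  keep <- apply(counts, 1, function(r) all(r > 0))
  if (!any(keep)) abort("no feature with non-zero counts in every sample")
  ref <- apply(counts[keep, , drop = FALSE], 1, geo_mean)
  apply(counts[keep, , drop = FALSE], 2, function(col) median(col / ref))
}

#' Strand-split depth profile over consensus sequences
#'
#' Pileup of primary-alignment spans along each consensus, split by
#' alignment strand (read orientation on the consensus — bidirectionally
#' transcribed elements show depth on both). Depth is divided by the
#' sample's size factor; the per-strand read counts stay raw.
#'
#' @param alignments Alignment tibble from [read_consensus_alignments()]
#'   (or the synthetic generator).
#' @param consensus_lengths Named vector, consensus id -> length (bp);
#'   defaults to the lengths attached to `alignments`.
#' @param size_factor Positive scalar dividing the depth (default 1).
#' @param sample_id Sample label carried into the output.
#' @return Tibble of class `consensus_profile`: `consensus_id`, `position`
#'   (0-based), `depth_fwd`, `depth_rev` (normalized), with a per-strand
#'   raw read-count tibble in attribute `counts` and the `size_factor` and
#'   `sample_id` as attributes.
#' @export
profile_consensus <- function(alignments, consensus_lengths = NULL,
                              size_factor = 1, sample_id = "sample") {
  consensus_lengths <- consensus_lengths %||% attr(alignments, "consensus_lengths")
  if (is.null(consensus_lengths)) abort("`consensus_lengths` must be supplied")
  if (size_factor <= 0) abort("`size_factor` must be positive")
  unknown <- setdiff(unique(alignments$consensus_id), names(consensus_lengths))
  if (length(unknown) > 0) {
    abort(sprintf("alignments reference unknown consensus: %s",
                  paste(unknown, collapse = ", ")))
  }
  pile <- function(starts, widths, len) {
    d <- numeric(len + 1L)
    if (length(starts) > 0) {
      ends <- pmin(starts + widths, len)
      agg <- tapply(rep(1L, length(starts)), starts, sum)
      d[as.integer(names(agg)) + 1L] <- agg
      agg2 <- tapply(rep(1L, length(ends)), ends, sum)
      d[as.integer(names(agg2)) + 1L] <- d[as.integer(names(agg2)) + 1L] - agg2
    }
    cumsum(d)[seq_len(len)]
  }
  profs <- lapply(names(consensus_lengths), function(id) {
    len <- consensus_lengths[[id]]
    a <- alignments[alignments$consensus_id == id, ]
    fwd <- a[a$strand == "+", ]
    rev <- a[a$strand == "-", ]
    tibble(
      consensus_id = id,
      position = seq_len(len) - 1L,
      depth_fwd = pile(fwd$start, fwd$aligned_length, len) / size_factor,
      depth_rev = pile(rev$start, rev$aligned_length, len) / size_factor
    )
  })
  counts <- bind_rows(lapply(names(consensus_lengths), function(id) {
    a <- alignments[alignments$consensus_id == id, ]
    tibble(
      sample = sample_id, consensus_id = id,
      reads_fwd = sum(a$strand == "+"), reads_rev = sum(a$strand == "-")
    )
  }))
  structure(
    bind_rows(profs),
    class = c("consensus_profile", class(profs[[1]])),
    counts = counts, size_factor = size_factor, sample_id = sample_id
  )
}

#' Per-sample, per-consensus, per-strand read counts
#'
#' Long table of raw and size-factor-normalized read counts, one row per
#' (sample, consensus, strand) — the numbers behind a strand-split
#' consensus expression comparison across conditions.
#'
#' @param profiles A [profile_consensus()] result or a list of them (one
#'   per sample).
#' @return Tibble `sample`, `consensus_id`, `strand`, `raw_count`,
#'   `normalized_count`, sorted.
#' @export
strand_count_table <- function(profiles) {
  if (inherits(profiles, "consensus_profile")) profiles <- list(profiles)
  bind_rows(lapply(profiles, function(p) {
    counts <- attr(p, "counts")
    sf <- attr(p, "size_factor")
    tidyr::pivot_longer(counts, c("reads_fwd", "reads_rev"),
                        names_to = "strand", values_to = "raw_count") |>
      mutate(
        strand = ifelse(.data$strand == "reads_fwd", "+", "-"),
        normalized_count = .data$raw_count / sf
      )
  })) |>
    arrange(.data$sample, .data$consensus_id, desc(.data$strand))
}

#' Plot a strand-split consensus depth profile
#'
#' @param profile A [profile_consensus()] result.
#' @return A ggplot: normalized depth along the consensus, one line per
#'   strand (minus-strand depth drawn downward).
#' @export
plot_consensus_profile <- function(profile) {
  df <- tidyr::pivot_longer(as_tibble(profile), c("depth_fwd", "depth_rev"),
                            names_to = "strand", values_to = "depth") |>
    mutate(
      strand = ifelse(.data$strand == "depth_fwd", "+", "-"),
      depth = ifelse(.data$strand == "-", -.data$depth, .data$depth)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$depth,
                                   colour = .data$strand)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::facet_wrap(~consensus_id, scales = "free") +
    ggplot2::labs(x = "consensus position (bp)",
                  y = "normalized depth (- strand downward)") +
    ggplot2::theme_minimal()
}

#' Write alignments as a minimal SAM file
#'
#' Emits `@SQ` headers and one primary record per alignment (flags 0/16,
#' CIGAR `<n>M`), sufficient for interchange with standard SAM tooling.
#' Sequences are written as `*` unless provided.
#'
#' @param alignments Tibble `read_id`, `consensus_id`, `strand`, `start`,
#'   `aligned_length`.
#' @param consensus_lengths Named vector of consensus lengths.
#' @param path Output path.
#' @param seqs Optional named character vector of read sequences.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, consensus_lengths, path, seqs = NULL) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(consensus_lengths),
            as.integer(consensus_lengths))
  )
  if (nrow(alignments) > 0) {
    seq_field <- if (is.null(seqs)) rep("*", nrow(alignments)) else seqs
    records <- sprintf(
      "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
      alignments$read_id,
      ifelse(alignments$strand == "-", 16L, 0L),
      alignments$consensus_id,
      alignments$start + 1L,
      alignments$aligned_length,
      seq_field
    )
  } else {
    records <- character(0)
  }
  writeLines(c(header, records), path)
  invisible(path)
}
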