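#' Stranded per-base coverage for one sample
#'
#' A `coverage_track` holds library-scaled, base-resolution RNA-seq coverage
#' for one sample, one numeric vector per chromosome and strand. It is the
#' substrate of bidirectional-transcription detection: stranded protocols
#' separate read pairs by their strand of origin, so sense and antisense
#' signal over the same locus are kept apart.
#'
#' Coverage values are multiplied by `scale_factor` at construction; the raw
#' values are not retained, mirroring library-size-scaled genome tracks.
#'
#' @param sample_id Sample label.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param forward,reverse Named lists of per-base numeric vectors, one per
#'   chromosome, for the plus and minus strand. Missing chromosomes are
#'   filled with zeros.
#' @param scale_factor Positive multiplier applied to all values (library
#'   scaling, e.g. 1/size-factor).
#'
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(sample_id, chrom_lengths, forward = NULL,
                           reverse = NULL, scale_factor = 1) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("`chrom_lengths` must be a named vector of chromosome lengths")
  }
  if (any(chrom_lengths < 1)) abort("chromosome lengths must be >= 1")
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 || scale_factor <= 0) {
    abort("`scale_factor` must be a single positive number")
  }
  fill <- function(arrays, strand) {
    out <- lapply(names(chrom_lengths), function(chrom) {
      x <- arrays[[chrom]]
      if (is.null(x)) return(numeric(chrom_lengths[[chrom]]))
      if (length(x) != chrom_lengths[[chrom]]) {
        abort(sprintf(
          "%s-strand array for %s has length %d, expected %d",
          strand, chrom, length(x), chrom_lengths[[chrom]]
        ))
      }
      if (any(x < 0)) abort(sprintf("negative coverage on %s (%s strand)", chrom, strand))
      x * scale_factor
    })
    names(out) <- names(chrom_lengths)
    out
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      chrom_lengths = chrom_lengths,
      forward = fill(forward, "+"),
      reverse = fill(reverse, "-"),
      scale_factor = scale_factor
    ),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> sample '%s': %d chromosome(s), %s bp, scale_factor %.4g\n",
    x$sample_id, length(x$chrom_lengths),
    format(sum(x$chrom_lengths), big.mark = ","), x$scale_factor
  ))
  invisible(x)
}

#' Read a bedGraph file into per-base arrays
#'
#' Expands a 4-column bedGraph (chrom, start, end, value; 0-based half-open)
#' into one numeric vector per declared chromosome. Records must be
#' non-overlapping and non-negative; bases not covered by any record are 0.
#'
#' @param path Path to a bedGraph file.
#' @param chrom_lengths Named vector of chromosome lengths. Records on
#'   undeclared chromosomes, or running past a chromosome end, are an error.
#'
#' @return Named list of per-base numeric vectors.
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  arrays <- lapply(chrom_lengths, numeric)
  if (file.size(path) == 0) return(arrays)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) return(arrays)

  chrom <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chrom), names(chrom_lengths))
  if (length(unknown) > 0) {
    abort(sprintf("bedGraph references undeclared chromosome(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  score <- S4Vectors::mcols(gr)$score
  if (any(score < 0)) abort(sprintf("negative value in bedGraph %s", path))
  # rtracklayer converts to 1-based closed; back to 0-based half-open
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (any(end0 > chrom_lengths[chrom])) {
    abort(sprintf("bedGraph record beyond declared chromosome length in %s", path))
  }
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hits) > 0) abort(sprintf("overlapping bedGraph records in %s", path))
  for (i in seq_along(gr)) {
    arrays[[chrom[i]]][(start0[i] + 1L):end0[i]] <- score[i]
  }
  arrays
}

#' Write per-base arrays as bedGraph
#'
#' Run-length compresses each per-base vector and writes non-zero runs as
#' 0-based half-open bedGraph records. `write_bedgraph(read_bedgraph(p))`
#' reproduces the per-base arrays exactly.
#'
#' @param arrays Named list of per-base numeric vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(arrays, path) {
  grs <- lapply(names(arrays), function(chrom) {
    r <- S4Vectors::Rle(arrays[[chrom]])
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    keep <- S4Vectors::runValue(r) != 0
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
      score = S4Vectors::runValue(r)[keep]
    )
  })
  gr <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a strand-separated pair of bedGraph files as one sample
#'
#' Stranded coverage is interchanged as two bedGraph files per sample
#' (conventionally `<prefix>.fwd.bedgraph` / `<prefix>.rev.bedgraph`).
#'
#' @param fwd_path,rev_path Paths to the plus- and minus-strand bedGraph.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param sample_id Sample label; defaults to the common file prefix.
#' @param scale_factor Library scale factor applied at load (see
#'   [coverage_track()]).
#'
#' @return A [coverage_track()].
#' @export
read_stranded_coverage <- function(fwd_path, rev_path, chrom_lengths,
                                   sample_id = NULL, scale_factor = 1) {
  sample_id <- sample_id %||%
    sub("\\.fwd\\.bedgraph$", "", basename(fwd_path))
  coverage_track(
    sample_id = sample_id,
    chrom_lengths = chrom_lengths,
    forward = read_bedgraph(fwd_path, chrom_lengths),
    reverse = read_bedgraph(rev_path, chrom_lengths),
    scale_factor = scale_factor
  )
}

#' Write a coverage track as a pair of bedGraph files
#'
#' @param track A [coverage_track()].
#' @param dir Output directory.
#' @param prefix File prefix; defaults to the sample id.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_stranded_coverage <- function(track, dir, prefix = track$sample_id) {
  stopifnot(inherits(track, "coverage_track"))
  fwd <- file.path(dir, paste0(prefix, ".fwd.bedgraph"))
  rev <- file.path(dir, paste0(prefix, ".rev.bedgraph"))
  write_bedgraph(track$forward, fwd)
  write_bedgraph(track$reverse, rev)
  invisible(c(fwd, rev))
}

#' Average replicate coverage tracks into one merged track
#'
#' Replicate merging is an explicit pipeline step: detection runs on one
#' merged track per condition, the per-base mean of the replicates.
#'
#' @param tracks List of [coverage_track()] objects on the same genome.
#' @param sample_id Label for the merged track.
#' @return A [coverage_track()] with `scale_factor = 1` (inputs are already
#'   scaled).
#' @export
merge_tracks <- function(tracks, sample_id = "merged") {
  stopifnot(length(tracks) >= 1, all(vapply(tracks, inherits, logical(1), "coverage_track")))
  cl <- tracks[[1]]$chrom_lengths
  for (tr in tracks[-1]) {
    if (!identical(tr$chrom_lengths, cl)) abort("tracks span different genomes")
  }
  avg <- function(field) {
    out <- lapply(names(cl), function(chrom) {
      Reduce(`+`, lapply(tracks, function(tr) tr[[field]][[chrom]])) / length(tracks)
    })
    names(out) <- names(cl)
    out
  }
  coverage_track(sample_id, cl, forward = avg("forward"), reverse = avg("reverse"))
}
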