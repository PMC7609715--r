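cl2 <- c(chrA = 200L, chrB = 150L)

write_bedgraph_text <- function(records, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", records$chrom, records$start,
                     records$end, format(records$value, trim = TRUE)), path)
}

# alternating segments between distinct sorted cut points: non-overlapping
# by construction
random_bedgraph_records <- function(chrom_lengths, n, seed) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(names(chrom_lengths), function(chrom) {
      cuts <- sort(sample(0:chrom_lengths[[chrom]], 2 * n))
      starts <- cuts[seq(1, 2 * n, 2)]
      ends <- cuts[seq(2, 2 * n, 2)]
      data.frame(chrom = chrom, start = starts, end = ends,
                 value = round(runif(n, 0.1, 9), 2))
    }))
  })
}

test_that("bedGraph records expand to per-base coverage with zero fill", {
  p <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chrA\t0\t10\t2.0", p)
  arr <- read_bedgraph(p, cl2)
  expect_equal(arr$chrA, c(rep(2, 10), rep(0, 190)))
  expect_equal(arr$chrB, rep(0, 150))
})

test_that("an empty bedGraph yields all-zero arrays", {
  p <- withr::local_tempfile(fileext = ".bedgraph")
  file.create(p)
  arr <- read_bedgraph(p, cl2)
  expect_true(all(vapply(arr, function(x) all(x == 0), logical(1))))
  expect_equal(lengths(arr), setNames(as.integer(cl2), names(cl2)))
})

test_that("random non-overlapping records match per-base fill oracle, any order", {
  recs <- random_bedgraph_records(cl2, 25, seed = 11)
  expect_gt(nrow(recs), 10)
  p <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph_text(recs, p)
  arr <- read_bedgraph(p, cl2)
  expect_equal(arr, oracle_expand_bedgraph(recs, cl2))
  # total mass equals sum(value * span)
  expect_equal(sum(unlist(arr)), sum(recs$value * (recs$end - recs$start)))
  # permuted file yields identical state
  p2 <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph_text(recs[withr::with_seed(1, sample(nrow(recs))), ], p2)
  expect_equal(read_bedgraph(p2, cl2), arr)
})

test_that("bedGraph round-trips exactly through write_bedgraph", {
  recs <- random_bedgraph_records(cl2, 20, seed = 5)
  p <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph_text(recs, p)
  arr <- read_bedgraph(p, cl2)
  p2 <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(arr, p2)
  expect_equal(read_bedgraph(p2, cl2), arr)
})

test_that("malformed bedGraph input is rejected with a useful error", {
  p <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chrA\t0\t10\t1.0", "chrA\t5\t15\t2.0"), p)
  expect_error(read_bedgraph(p, cl2), "overlap")
  writeLines("chrA\t0\t10\t-1.0", p)
  expect_error(read_bedgraph(p, cl2), "negative")
  writeLines("chrZ\t0\t10\t1.0", p)
  expect_error(read_bedgraph(p, cl2), "chrZ")
})

test_that("TE BED6 parses the subfamily:class dialect and sorts", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chrB\t500\t700\tAluY:SINE\t0\t-",
    "chrA\t100\t6164\tL1PA1:LINE\t0\t+",
    "chrA\t50\t80\tWeird:STUFF\t0\t+"
  ), p)
  te <- read_te_bed(p)
  expect_equal(te$chrom, c("chrA", "chrA", "chrB"))
  expect_equal(te$start, c(50L, 100L, 500L))
  expect_equal(te$subfamily, c("Weird", "L1PA1", "AluY"))
  expect_equal(te$te_class, c("other", "LINE", "SINE"))
  expect_equal(te$end[2] - te$start[2], 6064L)
  expect_equal(te$strand, c("+", "+", "-"))
})

test_that("TE names without a class default to 'other' with a warning", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t321\tAluY\t0\t+", p)
  expect_warning(te <- read_te_bed(p), "other")
  expect_equal(te$subfamily, "AluY")
  expect_equal(te$te_class, "other")
})

test_that("TE BED round-trips through write_te_bed", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t6164\tL1PA1:LINE\t0\t+",
               "chr1\t9000\t9311\tAluY:SINE\t0\t-"), p)
  te <- read_te_bed(p)
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_te_bed(te, p2)
  expect_equal(read_te_bed(p2), te)
})

test_that("gene tables parse labels and reject duplicate ids", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\ttss\tstrand\tlabels",
               "ISG15\tchr1\t1000\t+\tISG,upregulated",
               "OTHER1\tchr2\t5000\t-\tother"), p)
  g <- read_gene_table(p)
  expect_equal(nrow(g), 2)
  expect_equal(g$labels[[1]], c("ISG", "upregulated"))
  expect_equal(genes_with_label(g, "ISG")$gene_id, "ISG15")

  writeLines(c("gene_id\tchrom\ttss\tstrand\tlabels",
               "CCL5\tchr1\t1\t+\tISG",
               "CCL5\tchr1\t2\t+\tISG"), p)
  expect_error(read_gene_table(p), "CCL5")

  writeLines("gene_id\tchrom\ttss\tstrand\tlabels", p)
  expect_equal(nrow(read_gene_table(p)), 0)
})

test_that("SAM alignments convert coordinates, strand and reference widths", {
  p <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:L1PA1\tLN:6064",
    "r1\t0\tL1PA1\t11\t60\t50M\t*\t0\t0\t*\t*",
    "r2\t16\tL1PA1\t101\t60\t30M5D20M\t*\t0\t0\t*\t*",
    "r3\t0\tL1PA1\t201\t60\t10S40M3I10M\t*\t0\t0\t*\t*",
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"
  ), p)
  a <- read_consensus_alignments(p)
  expect_equal(nrow(a), 3)
  expect_equal(a$start[a$read_id == "r1"], 10L)
  expect_equal(a$aligned_length[a$read_id == "r1"], 50L)
  expect_equal(a$strand[a$read_id == "r2"], "-")
  # D consumes reference, I and S do not
  expect_equal(a$aligned_length[a$read_id == "r2"], 55L)
  expect_equal(a$aligned_length[a$read_id == "r3"], 50L)
  expect_equal(attr(a, "n_unmapped"), 1)
  expect_equal(attr(a, "consensus_lengths"), c(L1PA1 = 6064L))
})

test_that("mapped-read count matches a brute-force flag scan", {
  n <- 40
  flags <- withr::with_seed(3, sample(c(0L, 4L, 16L), n, replace = TRUE))
  lines <- c("@HD\tVN:1.6", "@SQ\tSN:C1\tLN:1000",
             sprintf("r%02d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                     seq_len(n), flags,
                     ifelse(flags == 4L, "*", "C1"),
                     ifelse(flags == 4L, 0L, 10L),
                     ifelse(flags == 4L, "*", "25M")))
  p <- withr::local_tempfile(fileext = ".sam")
  writeLines(lines, p)
  a <- read_consensus_alignments(p)
  expect_equal(nrow(a), sum(flags != 4L))
  expect_equal(attr(a, "n_unmapped"), sum(flags == 4L))
  expect_equal(sum(a$strand == "-"), sum(flags == 16L))
})

test_that("stranded coverage pairs load with library scaling applied", {
  d <- withr::local_tempdir()
  writeLines("chrA\t0\t4\t3.0", file.path(d, "s1.fwd.bedgraph"))
  writeLines("chrA\t2\t6\t1.0", file.path(d, "s1.rev.bedgraph"))
  tr <- read_stranded_coverage(file.path(d, "s1.fwd.bedgraph"),
                               file.path(d, "s1.rev.bedgraph"),
                               c(chrA = 10L), scale_factor = 2)
  expect_s3_class(tr, "coverage_track")
  expect_equal(tr$sample_id, "s1")
  expect_equal(tr$forward$chrA, c(rep(6, 4), rep(0, 6)))
  expect_equal(tr$reverse$chrA, c(0, 0, rep(2, 4), rep(0, 4)))

  m <- merge_tracks(list(tr, tr), "m")
  expect_equal(m$forward$chrA, tr$forward$chrA)
})
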