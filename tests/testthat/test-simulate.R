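# scaled-down spec so track-level checks stay fast; proportions mirror the
# defaults
small_spec <- function(...) {
  synthetic_spec(
    chrom_lengths = c(chr1 = 2e5, chr2 = 2e5),
    n_genes = 100, n_isg = 20, n_extra_upregulated = 10, n_l1_induced = 30,
    te_catalog = tibble::tibble(
      subfamily = c("L1PA1", "L1PA2", "L1M4", "LTR12", "LTR7", "AluY"),
      te_class = c("LINE", "LINE", "LINE", "LTR", "LTR", "SINE"),
      consensus_length = c(6064L, 6069L, 6300L, 1577L, 450L, 311L),
      n_full = c(6L, 3L, 0L, 6L, 6L, 8L),
      n_trunc = c(2L, 1L, 3L, 0L, 0L, 0L)
    ),
    n_bidirectional = 9, n_upregulated_ltr = 8,
    n_replicates = 1,
    ...
  )
}

test_that("generation is deterministic given the seed", {
  d1 <- generate_dataset(small_spec(), seed = 3)
  d2 <- generate_dataset(small_spec(), seed = 3)
  expect_identical(d1$te, d2$te)
  expect_identical(d1$genes$labels, d2$genes$labels)
  expect_identical(d1$tracks[[1]]$forward, d2$tracks[[1]]$forward)
  expect_identical(d1$consensus$alignments, d2$consensus$alignments)
  d3 <- generate_dataset(small_spec(), seed = 4)
  expect_false(identical(d1$te$start, d3$te$start))
})

test_that("the annotation honours the catalogue and non-overlap constraint", {
  ds <- generate_dataset(synthetic_spec(), seed = 11, tracks = FALSE)
  l1pa1_full <- dplyr::filter(ds$te, subfamily == "L1PA1", full_length_copy)
  expect_equal(nrow(l1pa1_full), 50)
  expect_true(all(l1pa1_full$end - l1pa1_full$start == 6064))
  # truncated copies are 5' truncations in [500, consensus)
  tr <- dplyr::filter(ds$te, !full_length_copy)
  expect_true(all(tr$end - tr$start >= 500 &
                    tr$end - tr$start < tr$consensus_length))
  # no two TE copies overlap
  by_chrom <- split(ds$te, ds$te$chrom)
  for (df in by_chrom) {
    df <- df[order(df$start), ]
    expect_true(all(df$start[-1] >= df$end[-nrow(df)]))
  }
  # truth lists are subsets of the annotation
  expect_true(all(ds$truth$bidirectional$start %in% ds$te$start))
  expect_equal(nrow(ds$truth$bidirectional), 70)
  expect_equal(sort(unique(ds$truth$bidirectional$subfamily)), c("L1PA1", "L1PA2"))
  expect_equal(nrow(ds$truth$near_isg_ltrs), 30)  # fraction 0.5 of 60
  # bidirectional truth is disjoint from sense-only truth
  expect_equal(nrow(dplyr::semi_join(ds$truth$sense_only, ds$truth$bidirectional,
                                     by = c("chrom", "start"))), 0)
})

test_that("gene TSSs keep clear of TE bodies except deliberate near-ISG LTRs", {
  ds <- generate_dataset(synthetic_spec(ltr_near_isg_fraction = 1), seed = 13,
                         tracks = FALSE)
  non_near <- dplyr::filter(ds$te, !near_isg)
  d <- suppressWarnings(distance_to_nearest_tss(
    non_near, dplyr::mutate(ds$genes, chrom = chrom)))
  expect_true(all(d$distance >= 1))
  # near-ISG LTRs sit within d_near of an ISG TSS
  isg <- genes_with_label(ds$genes, "ISG")
  dn <- distance_to_nearest_tss(ds$truth$near_isg_ltrs, isg)
  expect_true(all(dn$distance <= 20000))
  expect_equal(nrow(ds$truth$near_isg_ltrs), 60)
})

test_that("antisense signal at bidirectional loci dwarfs the background", {
  ds <- generate_dataset(small_spec(), seed = 21, tracks = "shControl")
  tr <- ds$tracks[["shControl_rep1"]]
  anti_of <- function(row) {
    arr <- if (row$strand == "+") tr$reverse[[row$chrom]] else tr$forward[[row$chrom]]
    mean(arr[(row$start + 1):row$end])
  }
  anti <- vapply(seq_len(nrow(ds$truth$bidirectional)),
                 function(i) anti_of(ds$truth$bidirectional[i, ]), numeric(1))
  genome_mean <- mean(c(unlist(tr$forward), unlist(tr$reverse)))
  expect_true(all(anti > 5 * genome_mean))
  # sense-only loci carry no designated antisense signal
  anti_so <- vapply(seq_len(nrow(ds$truth$sense_only)),
                    function(i) anti_of(ds$truth$sense_only[i, ]), numeric(1))
  expect_true(all(anti_so < 2))
})

test_that("knockdown multiplies consensus read counts on both strands", {
  ds <- generate_dataset(synthetic_spec(consensus_base_reads = tibble::tibble(
    consensus_id = "L1PA1", length = 6064L, fwd = 10000, rev = 10000
  )), seed = 31, tracks = FALSE)
  ctl <- ds$consensus$alignments$shControl
  kd <- ds$consensus$alignments$shMPP8
  for (s in c("+", "-")) {
    ratio <- sum(kd$strand == s) / sum(ctl$strand == s)
    expect_gt(ratio, 3)
    expect_lt(ratio, 5)
  }
  # zero requested reads: empty alignment table still typed correctly
  ds0 <- generate_dataset(synthetic_spec(consensus_base_reads = tibble::tibble(
    consensus_id = "L1PA1", length = 6064L, fwd = 0, rev = 0
  )), seed = 31, tracks = FALSE)
  expect_equal(nrow(ds0$consensus$alignments$shControl), 0)
})

test_that("a dataset round-trips to disk in interchange formats", {
  ds <- generate_dataset(small_spec(), seed = 8, tracks = "shMPP8")
  d <- withr::local_tempdir()
  write_synthetic_dataset(ds, d)
  te <- read_te_bed(file.path(d, "te.bed"))
  expect_equal(nrow(te), nrow(ds$te))
  expect_equal(te$start, ds$te$start)
  genes <- read_gene_table(file.path(d, "genes.tsv"))
  expect_equal(genes$labels, ds$genes$labels)
  tr <- read_stranded_coverage(file.path(d, "shMPP8_rep1.fwd.bedgraph"),
                               file.path(d, "shMPP8_rep1.rev.bedgraph"),
                               ds$spec$chrom_lengths)
  expect_equal(tr$forward$chr1, ds$tracks[[1]]$forward$chr1, tolerance = 1e-6)
  a <- read_consensus_alignments(file.path(d, "consensus.shMPP8.sam"))
  expect_equal(nrow(a), nrow(ds$consensus$alignments$shMPP8))
  expect_true(file.exists(file.path(d, "spec.resolved.yaml")))
  expect_true(file.exists(file.path(d, "truth", "bidirectional.bed")))
  fa <- readLines(file.path(d, "consensus.fa"))
  expect_equal(sum(startsWith(fa, ">")), 2)
})

test_that("infeasible placement requests error out", {
  spec <- small_spec()
  spec$chrom_lengths <- c(chr1 = 30000)
  expect_error(generate_dataset(spec, seed = 1, tracks = FALSE), "fit")
})
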