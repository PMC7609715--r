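#' Default TE catalogue for the synthetic genome
#'
#' Young hominid-specific LINE-1 subfamilies (L1PA1/L1HS at 6,064 bp and
#' L1PA2 at 6,069 bp consensus) provide the full-length copies that are
#' designated bidirectionally transcribed; an older LINE-1 family (L1M4)
#' contributes 5'-truncated sense-only copies; two endogenous-retrovirus
#' LTR subfamilies (LTR12/ERV9 and LTR7/HERVH) provide the derepressible
#' LTR loci; AluY copies are transcriptionally silent annotation ballast.
#'
#' @return Tibble `subfamily`, `te_class`, `consensus_length`, `n_full`,
#'   `n_trunc`.
#' @export
default_te_catalog <- function() {
  tibble(
    subfamily = c("L1PA1", "L1PA2", "L1M4", "LTR12", "LTR7", "AluY"),
    te_class = c("LINE", "LINE", "LINE", "LTR", "LTR", "SINE"),
    consensus_length = c(6064L, 6069L, 6300L, 1577L, 450L, 311L),
    n_full = c(50L, 20L, 0L, 50L, 50L, 80L),
    n_trunc = c(15L, 10L, 30L, 0L, 0L, 0L)
  )
}

#' Specification of a synthetic stranded RNA-seq dataset
#'
#' Collects every tunable of the generator with defaults that emulate the
#' statistical structure the detection pipeline assumes: a small
#' multi-chromosome genome; non-overlapping TE copies of which the
#' full-length young LINE-1s are bidirectionally transcribed while
#' truncated copies are sense-only decoys; interferon-stimulated genes
#' (ISGs) whose TSSs attract a fraction of the derepressed LTRs; patchy
#' background transcription; negative-binomial per-base coverage smoothed
#' to mimic read-span autocorrelation; and a knockdown condition that
#' multiplies signal at silencing-complex target loci.
#'
#' @param chrom_lengths Named chromosome lengths (default three 2-Mb
#'   chromosomes).
#' @param n_genes Total genes (default 2000), `n_isg` of them labelled
#'   `ISG` + `upregulated` (default 200).
#' @param n_extra_upregulated Non-ISG genes additionally labelled
#'   `upregulated` (default 100).
#' @param n_l1_induced Genes labelled `L1_induced`; half drawn from the
#'   ISGs so the gene-set overlap stage has signal (default 300).
#' @param te_catalog See [default_te_catalog()].
#' @param n_bidirectional Full-length copies designated bidirectionally
#'   transcribed, allocated L1PA1 first, then L1PA2, then remaining
#'   full-length LINEs (default 70 = all 50 L1PA1 + all 20 L1PA2).
#' @param n_upregulated_ltr LTR copies derepressed in the knockdown
#'   (default 60).
#' @param ltr_near_isg_fraction Fraction of derepressed LTRs placed near
#'   an ISG TSS (default 0.5); `d_near` caps the offset (default 20 kb)
#'   and `near_offset_mean` is the mean of the exponential offset
#'   distribution (default 2 kb — LTRs acting as cryptic
#'   promoters/enhancers sit proximally).
#' @param background_mean Per-base negative-binomial mean inside
#'   background transcription patches (default 0.5).
#' @param background_fraction Fraction of each strand covered by
#'   background patches (default 0.35); outside patches coverage is zero,
#'   as over most of a real genome.
#' @param expressed_mean Per-base sense-strand mean over expressed loci
#'   (default 10, i.e. 20x the background mean).
#' @param bidir_rev_mean Per-base antisense mean over bidirectional loci
#'   (default 10).
#' @param dispersion Negative-binomial dispersion (`var = mu + disp*mu^2`;
#'   default 0.3).
#' @param smooth_window Moving-average window mimicking read-span
#'   autocorrelation (default 50 bp).
#' @param knockdown_fold_change Multiplier applied to signal means at
#'   silencing-target loci in the knockdown condition (default 4; loci
#'   with fold change > 2 form the `upregulated` truth list).
#' @param n_replicates Replicates per condition (default 3).
#' @param conditions Condition names (default `shControl`, `shMPP8`; the
#'   second is the knockdown).
#' @param read_length Consensus-alignment read length (default 100).
#' @param consensus_base_reads Tibble `consensus_id`, `length`, `fwd`,
#'   `rev`: expected control-condition read counts per consensus strand.
#' @param tss_te_buffer Minimum distance between gene TSSs and TE bodies,
#'   deliberately placed near-ISG LTRs excepted (default 1 kb).
#'
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
                           n_genes = 2000,
                           n_isg = 200,
                           n_extra_upregulated = 100,
                           n_l1_induced = 300,
                           te_catalog = default_te_catalog(),
                           n_bidirectional = 70,
                           n_upregulated_ltr = 60,
                           ltr_near_isg_fraction = 0.5,
                           d_near = 20000,
                           near_offset_mean = 2000,
                           background_mean = 0.5,
                           background_fraction = 0.35,
                           expressed_mean = 10,
                           bidir_rev_mean = 10,
                           dispersion = 0.3,
                           smooth_window = 50,
                           knockdown_fold_change = 4,
                           n_replicates = 3,
                           conditions = c("shControl", "shMPP8"),
                           read_length = 100,
                           consensus_base_reads = tibble(
                             consensus_id = c("L1PA1", "L1PA2"),
                             length = c(6064L, 6069L),
                             fwd = c(1200, 600),
                             rev = c(300, 150)
                           ),
                           tss_te_buffer = 1000) {
  spec <- as.list(environment())
  stopifnot(
    all(chrom_lengths > 0), !is.null(names(chrom_lengths)),
    background_mean >= 0, expressed_mean >= 0, bidir_rev_mean >= 0,
    dispersion > 0, knockdown_fold_change > 0,
    ltr_near_isg_fraction >= 0, ltr_near_isg_fraction <= 1,
    background_fraction >= 0, background_fraction <= 1,
    n_isg <= n_genes, length(conditions) == 2
  )
  if (n_bidirectional > sum(te_catalog$n_full[te_catalog$te_class == "LINE"])) {
    abort("`n_bidirectional` exceeds the number of full-length LINE copies")
  }
  if (n_upregulated_ltr > sum(te_catalog$n_full[te_catalog$te_class == "LTR"] +
                                te_catalog$n_trunc[te_catalog$te_class == "LTR"])) {
    abort("`n_upregulated_ltr` exceeds the number of LTR copies")
  }
  structure(spec, class = "synthetic_spec")
}

# uniform non-overlapping placement with a clearance gap; errors when the
# requested copies do not fit after bounded retries
.place_intervals <- function(lengths, chrom_lengths, existing = NULL,
                             gap = 2000, avoid_points = NULL,
                             point_buffer = 0, max_tries = 2000) {
  chroms <- names(chrom_lengths)
  by_chrom <- setNames(lapply(chroms, function(chrom) {
    sel <- if (is.null(existing)) logical(0) else existing$chrom == chrom
    list(start = if (any(sel)) existing$start[sel] else numeric(0),
         end = if (any(sel)) existing$end[sel] else numeric(0),
         pts = if (is.null(avoid_points)) numeric(0)
               else avoid_points$pos[avoid_points$chrom == chrom])
  }), chroms)
  n <- length(lengths)
  out_chrom <- character(n); out_start <- numeric(n)
  for (i in seq_len(n)) {
    len <- lengths[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- sample(chroms, 1, prob = chrom_lengths)
      if (chrom_lengths[[chrom]] <= len + 2 * gap) next
      start <- floor(runif(1, gap, chrom_lengths[[chrom]] - len - gap))
      end <- start + len
      b <- by_chrom[[chrom]]
      if (any(start < b$end + gap & end > b$start - gap)) next
      if (any(b$pts > start - point_buffer & b$pts < end + point_buffer)) next
      ok <- TRUE
      break
    }
    if (!ok) abort("requested TE copies do not fit in the genome without overlap")
    out_chrom[i] <- chrom; out_start[i] <- start
    by_chrom[[chrom]]$start <- c(by_chrom[[chrom]]$start, start)
    by_chrom[[chrom]]$end <- c(by_chrom[[chrom]]$end, start + len)
  }
  tibble(chrom = out_chrom, start = out_start, end = out_start + lengths)
}

# centered moving average with shrinking windows at the edges
.smooth_ma <- function(x, window) {
  if (window <= 1) return(x)
  h <- floor(window / 2)
  n <- length(x)
  if (n <= 2L * h + 2L) {
    cs <- c(0, cumsum(x))
    i <- seq_len(n)
    lo <- pmax(i - h - 1L, 0L)
    hi <- pmin(i + h, n)
    return((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
  }
  cs <- cumsum(x)
  out <- numeric(n)
  w <- 2L * h + 1L
  out[h + 1L] <- cs[w] / w
  out[(h + 2L):(n - h)] <- (cs[(w + 1L):n] - cs[seq_len(n - w)]) / w
  for (k in seq_len(h)) {
    out[k] <- cs[k + h] / (k + h)
    out[n - k + 1L] <- (cs[n] - cs[n - k - h]) / (k + h)
  }
  out
}

#' Generate a synthetic stranded RNA-seq dataset
#'
#' Deterministically (given `seed`) builds a toy genome annotation, a
#' labelled gene/TSS table, strand-separated coverage tracks for a control
#' and a knockdown condition, consensus-alignment read sets, and the
#' ground-truth locus lists the pipeline's validation rests on. See
#' [synthetic_spec()] for what is emulated.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the generator never touches the global RNG.
#' @param tracks Which coverage tracks to generate: `TRUE` (all
#'   conditions, the default), `FALSE` (placement-only dataset — much
#'   cheaper, and sufficient for the distance and overlap stages), or a
#'   character vector of condition names. Each sample is drawn from its
#'   own named RNG substream, so a subset of conditions reproduces
#'   exactly the tracks a full generation would produce.
#'
#' @return List of class `synthetic_dataset`: `spec`, `seed`, `te`
#'   (annotation tibble with truth flag columns `bidirectional`,
#'   `expressed`, `hush_target`, `full_length_copy`), `genes`, `universe`,
#'   `truth` (tibbles `bidirectional`, `sense_only`, `upregulated`,
#'   `near_isg_ltrs`), `tracks` (named list of [coverage_track()], or
#'   `NULL`), `consensus` (`lengths`, `sequences`, `alignments` per
#'   condition) and `background_patches`.
#' @export
generate_dataset <- function(spec = synthetic_spec(), seed = 1, tracks = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(as.integer(seed), .generate_impl(spec, seed, tracks))
}

.generate_impl <- function(spec, seed, tracks) {
  cl <- spec$chrom_lengths

  ## --- TE copies ---------------------------------------------------------
  cat_rows <- spec$te_catalog
  te <- bind_rows(lapply(seq_len(nrow(cat_rows)), function(i) {
    r <- cat_rows[i, ]
    full <- tibble(
      subfamily = r$subfamily, te_class = r$te_class,
      consensus_length = r$consensus_length,
      length = rep(r$consensus_length, r$n_full), full_length_copy = TRUE
    )
    trunc_len <- if (r$n_trunc > 0) {
      floor(runif(r$n_trunc, min(500, r$consensus_length - 1), r$consensus_length))
    } else numeric(0)
    trunc <- tibble(
      subfamily = r$subfamily, te_class = r$te_class,
      consensus_length = r$consensus_length,
      length = trunc_len, full_length_copy = FALSE
    )
    bind_rows(full, trunc)
  }))
  te$strand <- sample(c("+", "-"), nrow(te), replace = TRUE)

  # bidirectional designation: full-length L1PA1, then L1PA2, then other LINEs
  is_full_line <- te$full_length_copy & te$te_class == "LINE"
  pref <- order(!is_full_line, match(te$subfamily, c("L1PA1", "L1PA2")))
  te$bidirectional <- FALSE
  te$bidirectional[pref[seq_len(spec$n_bidirectional)]] <- TRUE

  is_ltr <- te$te_class == "LTR"
  up_ltr_idx <- sample(which(is_ltr), spec$n_upregulated_ltr)
  te$upregulated_ltr <- FALSE
  te$upregulated_ltr[up_ltr_idx] <- TRUE

  # sense expression: truncated LINE decoys and derepressed LTRs (plus the
  # sense strand of every bidirectional locus)
  te$expressed <- te$bidirectional |
    (!te$full_length_copy & te$te_class == "LINE") |
    te$upregulated_ltr
  te$hush_target <- te$bidirectional | te$upregulated_ltr |
    (!te$full_length_copy & te$subfamily %in% c("L1PA1", "L1PA2"))

  ## --- placement: non-LTR TEs, then genes, then LTRs ---------------------
  non_ltr <- which(!is_ltr)
  pl <- .place_intervals(te$length[non_ltr], cl)
  te$chrom <- NA_character_; te$start <- NA_real_; te$end <- NA_real_
  te$chrom[non_ltr] <- pl$chrom; te$start[non_ltr] <- pl$start; te$end[non_ltr] <- pl$end

  # batch-rejection TSS placement clear of TE bodies (+ buffer)
  place_tss <- function(n, te_tbl) {
    chroms <- names(cl)
    placed <- te_tbl[!is.na(te_tbl$chrom), ]
    blocked <- setNames(lapply(chroms, function(chrom) {
      sel <- placed$chrom == chrom
      if (!any(sel)) return(list(start = numeric(0), end = numeric(0)))
      ir <- IRanges::reduce(IRanges::IRanges(
        start = placed$start[sel] - spec$tss_te_buffer + 1L,
        end = placed$end[sel] + spec$tss_te_buffer - 1L
      ))
      list(start = IRanges::start(ir), end = IRanges::end(ir))
    }), chroms)
    chrom_i <- integer(0); pos <- integer(0)
    need <- n
    while (need > 0) {
      ci <- sample.int(length(chroms), need, replace = TRUE, prob = cl)
      p <- floor(runif(need, 0, cl[ci]))
      bad <- logical(need)
      for (k in seq_along(chroms)) {
        sel <- which(ci == k)
        if (length(sel) == 0) next
        b <- blocked[[k]]
        if (length(b$start) == 0) next
        idx <- findInterval(p[sel] + 1L, b$start)
        bad[sel] <- idx >= 1 & (p[sel] + 1L) <= b$end[pmax(idx, 1L)]
      }
      chrom_i <- c(chrom_i, ci[!bad]); pos <- c(pos, p[!bad])
      need <- sum(bad)
    }
    tibble(chrom = chroms[chrom_i], tss = as.integer(pos))
  }
  genes <- place_tss(spec$n_genes, te)
  genes$gene_id <- sprintf("g%04d", seq_len(spec$n_genes))
  genes$strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
  isg_idx <- sample(spec$n_genes, spec$n_isg)
  extra_up <- sample(setdiff(seq_len(spec$n_genes), isg_idx), spec$n_extra_upregulated)
  n_l1_isg <- min(spec$n_l1_induced %/% 2, spec$n_isg)
  l1_idx <- c(
    sample(isg_idx, n_l1_isg),
    sample(setdiff(seq_len(spec$n_genes), isg_idx), spec$n_l1_induced - n_l1_isg)
  )
  genes$labels <- lapply(seq_len(spec$n_genes), function(i) {
    l <- character(0)
    if (i %in% isg_idx) l <- c(l, "ISG", "upregulated")
    if (i %in% extra_up) l <- c(l, "upregulated")
    if (i %in% l1_idx) l <- c(l, "L1_induced")
    if (length(l) == 0) l <- "other"
    l
  })
  genes <- genes[, c("gene_id", "chrom", "tss", "strand", "labels")]

  # LTRs: a fraction of the derepressed ones is deliberately placed near a
  # distinct ISG TSS; every other LTR is placed uniformly, clear of TSSs
  n_near <- round(spec$ltr_near_isg_fraction * spec$n_upregulated_ltr)
  near_idx <- if (n_near > 0) sample(up_ltr_idx, n_near) else integer(0)
  te$near_isg <- FALSE
  te$near_isg[near_idx] <- TRUE
  isg_pool <- sample(isg_idx, length(near_idx))
  occupied <- te[!is.na(te$chrom), c("chrom", "start", "end")]
  for (j in seq_along(near_idx)) {
    i <- near_idx[j]
    g <- genes[isg_pool[j], ]
    len <- te$length[i]
    ok <- FALSE
    for (try in seq_len(500)) {
      offset <- 100 + min(round(rexp(1, 1 / spec$near_offset_mean)), spec$d_near - 100)
      side <- sample(c(-1, 1), 1)
      start <- if (side < 0) g$tss - offset - len else g$tss + offset
      end <- start + len
      if (start < 0 || end > cl[[g$chrom]]) next
      near <- occupied[occupied$chrom == g$chrom, ]
      if (nrow(near) > 0 && any(start < near$end + 200 & end > near$start - 200)) next
      ok <- TRUE
      break
    }
    if (!ok) abort("could not place a near-ISG LTR without overlap")
    te$chrom[i] <- g$chrom; te$start[i] <- start; te$end[i] <- end
    occupied <- bind_rows(occupied, tibble(chrom = g$chrom, start = start, end = end))
  }
  rest <- which(is_ltr & is.na(te$chrom))
  if (length(rest) > 0) {
    pl <- .place_intervals(
      te$length[rest], cl, existing = occupied,
      avoid_points = tibble(chrom = genes$chrom, pos = genes$tss),
      point_buffer = spec$tss_te_buffer
    )
    te$chrom[rest] <- pl$chrom; te$start[rest] <- pl$start; te$end[rest] <- pl$end
  }
  te <- arrange(
    te[, c("chrom", "start", "end", "subfamily", "te_class", "strand",
           "consensus_length", "length", "full_length_copy", "bidirectional",
           "expressed", "upregulated_ltr", "near_isg", "hush_target")],
    .data$chrom, .data$start
  )
  te$start <- as.integer(te$start); te$end <- as.integer(te$end)

  ## --- background patches (shared across samples) ------------------------
  patches <- bind_rows(lapply(names(cl), function(chrom) {
    bind_rows(lapply(c("+", "-"), function(strand) {
      target <- spec$background_fraction * cl[[chrom]]
      lens <- integer(0)
      while (sum(lens) < target) lens <- c(lens, floor(runif(1, 2000, 10000)))
      starts <- floor(runif(length(lens), 0, cl[[chrom]] - lens))
      tibble(chrom = chrom, strand = strand, start = starts, end = starts + lens)
    }))
  }))

  ## --- truth lists --------------------------------------------------------
  truth <- list(
    bidirectional = filter(te, .data$bidirectional),
    sense_only = filter(te, .data$expressed & !.data$bidirectional),
    upregulated = filter(te, .data$hush_target),
    near_isg_ltrs = filter(te, .data$near_isg)
  )

  ## --- coverage tracks ----------------------------------------------------
  gen_conditions <- if (isTRUE(tracks)) spec$conditions
                    else if (is.character(tracks)) intersect(spec$conditions, tracks)
                    else character(0)
  track_list <- NULL
  if (length(gen_conditions) > 0) {
    mean_arrays <- function(fold) {
      out <- list()
      for (chrom in names(cl)) {
        for (strand in c("+", "-")) {
          mu <- numeric(cl[[chrom]])
          p <- patches[patches$chrom == chrom & patches$strand == strand, ]
          for (r in seq_len(nrow(p))) {
            idx <- (p$start[r] + 1L):p$end[r]
            mu[idx] <- mu[idx] + spec$background_mean
          }
          tt <- te[te$chrom == chrom & te$expressed, ]
          for (r in seq_len(nrow(tt))) {
            idx <- (tt$start[r] + 1L):tt$end[r]
            f <- if (tt$hush_target[r]) fold else 1
            if (tt$strand[r] == strand) {
              mu[idx] <- mu[idx] + spec$expressed_mean * f
            }
            if (tt$bidirectional[r] && tt$strand[r] != strand) {
              mu[idx] <- mu[idx] + spec$bidir_rev_mean * f
            }
          }
          out[[paste(chrom, strand)]] <- mu
        }
      }
      out
    }
    track_list <- list()
    for (cond in gen_conditions) {
      fold <- if (cond == spec$conditions[2]) spec$knockdown_fold_change else 1
      mu_cond <- mean_arrays(fold)
      for (rep_i in seq_len(spec$n_replicates)) {
        # named per-sample substream so a subset of conditions reproduces
        # exactly the tracks a full generation would produce
        k <- (match(cond, spec$conditions) - 1L) * spec$n_replicates + rep_i
        sub_seed <- (as.integer(seed) + 104729L * k) %% 2147483647L
        id <- paste0(cond, "_rep", rep_i)
        track_list[[id]] <- withr::with_seed(sub_seed, {
          fwd <- list(); rev <- list()
          for (chrom in names(cl)) {
            for (strand in c("+", "-")) {
              mu <- mu_cond[[paste(chrom, strand)]]
              x <- numeric(length(mu))
              nz <- which(mu > 0)
              x[nz] <- rnbinom(length(nz), mu = mu[nz], size = 1 / spec$dispersion)
              x <- .smooth_ma(x, spec$smooth_window)
              if (strand == "+") fwd[[chrom]] <- x else rev[[chrom]] <- x
            }
          }
          coverage_track(id, cl, forward = fwd, reverse = rev)
        })
      }
    }
  }

  ## --- consensus sequences and read sets ---------------------------------
  cons <- spec$consensus_base_reads
  lengths <- setNames(as.integer(cons$length), cons$consensus_id)
  sequences <- setNames(vapply(cons$length, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1)), cons$consensus_id)
  aln <- list()
  for (cond in spec$conditions) {
    fold <- if (cond == spec$conditions[2]) spec$knockdown_fold_change else 1
    rows <- lapply(seq_len(nrow(cons)), function(i) {
      n_f <- rpois(1, cons$fwd[i] * fold)
      n_r <- rpois(1, cons$rev[i] * fold)
      n <- n_f + n_r
      if (n == 0) {
        return(tibble(read_id = character(), consensus_id = character(),
                      strand = character(), start = integer(),
                      aligned_length = integer()))
      }
      tibble(
        read_id = sprintf("%s_%s_r%05d", cond, cons$consensus_id[i], seq_len(n)),
        consensus_id = cons$consensus_id[i],
        strand = rep(c("+", "-"), c(n_f, n_r)),
        start = sample.int(cons$length[i] - spec$read_length + 1L, n,
                           replace = TRUE) - 1L,
        aligned_length = spec$read_length
      )
    })
    a <- bind_rows(rows)
    attr(a, "consensus_lengths") <- lengths
    aln[[cond]] <- a
  }

  structure(
    list(
      spec = spec, seed = seed, te = te, genes = genes,
      universe = genes$gene_id, truth = truth, tracks = track_list,
      consensus = list(lengths = lengths, sequences = sequences, alignments = aln),
      background_patches = patches
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> seed %s: %d TE loci (%d bidirectional), %d genes, %s\n",
    format(x$seed), nrow(x$te), nrow(x$truth$bidirectional), nrow(x$genes),
    if (is.null(x$tracks)) "no coverage tracks"
    else sprintf("%d coverage track(s)", length(x$tracks))
  ))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Serializes every component in the package's interchange formats:
#' strand-separated bedGraph pairs per sample, `te.bed` (BED6,
#' `subfamily:class` names), `genes.tsv`, `universe.txt`, truth BED files
#' under `truth/`, `consensus.fa` and one SAM per condition, plus
#' `spec.resolved.yaml` recording every parameter and the seed.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_te_bed(dataset$te, file.path(dir, "te.bed"))
  write_gene_table(dataset$genes, file.path(dir, "genes.tsv"))
  writeLines(dataset$universe, file.path(dir, "universe.txt"))
  for (nm in names(dataset$truth)) {
    tr <- dataset$truth[[nm]]
    if (nrow(tr) > 0) write_te_bed(tr, file.path(dir, "truth", paste0(nm, ".bed")))
  }
  for (id in names(dataset$tracks)) {
    write_stranded_coverage(dataset$tracks[[id]], dir, prefix = id)
  }
  fa <- file.path(dir, "consensus.fa")
  writeLines(unlist(lapply(names(dataset$consensus$sequences), function(id) {
    c(paste0(">", id),
      substring(dataset$consensus$sequences[[id]],
                seq(1, nchar(dataset$consensus$sequences[[id]]), 70),
                pmin(seq(1, nchar(dataset$consensus$sequences[[id]]), 70) + 69,
                     nchar(dataset$consensus$sequences[[id]]))))
  })), fa)
  for (cond in names(dataset$consensus$alignments)) {
    write_sam(dataset$consensus$alignments[[cond]], dataset$consensus$lengths,
              file.path(dir, sprintf("consensus.%s.sam", cond)))
  }
  resolved <- dataset$spec
  resolved$te_catalog <- as.data.frame(resolved$te_catalog)
  resolved$consensus_base_reads <- as.data.frame(resolved$consensus_base_reads)
  resolved$seed <- dataset$seed
  yaml::write_yaml(lapply(unclass(resolved), function(x) {
    if (is.data.frame(x)) lapply(x, I) else x
  }), file.path(dir, "spec.resolved.yaml"))
  invisible(dir)
}
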