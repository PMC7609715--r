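#' Read a gene/TSS table
#'
#' Tab-delimited with header `gene_id, chrom, tss, strand, labels`; `tss`
#' is the 0-based transcription start position and `labels` a
#' comma-separated set of gene-set labels (e.g. `ISG,upregulated`;
#' `L1_induced`, `KZNF`, `other` are also used). Labels become a
#' list-column.
#'
#' @param path Path to the TSV.
#' @return Tibble `gene_id`, `chrom`, `tss`, `strand`, `labels`
#'   (list-column of character vectors).
#' @export
read_gene_table <- function(path) {
  genes <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      chrom = readr::col_character(),
      tss = readr::col_integer(),
      strand = readr::col_character(),
      labels = readr::col_character()
    ),
    progress = FALSE
  )
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene_id in %s: %s", path,
                  paste(unique(dup), collapse = ", ")))
  }
  genes$labels <- lapply(genes$labels, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, ",", fixed = TRUE)[[1]]
  })
  genes
}

#' Write a gene table (labels collapsed to comma-separated text)
#'
#' @param genes Tibble as from [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  if (is.list(out$labels)) {
    out$labels <- vapply(out$labels, paste, character(1), collapse = ",")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Select genes carrying any of a set of labels
#'
#' @param genes Gene tibble with a `labels` list-column.
#' @param labels Character vector of labels; a gene matches when it carries
#'   at least one of them.
#' @return The matching rows of `genes`.
#' @export
genes_with_label <- function(genes, labels) {
  keep <- vapply(genes$labels, function(l) any(labels %in% l), logical(1))
  genes[keep, ]
}
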