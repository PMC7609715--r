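#' Observed overlap between two gene sets
#'
#' Size of the intersection of a query and a reference gene-id set within a
#' stated universe. Ids outside the universe are dropped with a warning —
#' the universe must be supplied explicitly, since overlap significance is
#' meaningless without it.
#'
#' @param query,reference Character vectors of gene ids.
#' @param universe Character vector of all eligible gene ids.
#' @return Integer overlap count `k`.
#' @export
observed_overlap <- function(query, reference, universe) {
  if (length(universe) == 0) abort("empty universe")
  universe <- unique(universe)
  stray <- unique(c(setdiff(query, universe), setdiff(reference, universe)))
  if (length(stray) > 0) {
    warn(sprintf("%d id(s) outside the universe dropped (e.g. '%s')",
                 length(stray), stray[1]))
  }
  length(intersect(intersect(query, universe), intersect(reference, universe)))
}

#' Null overlap distribution by gene-set randomization
#'
#' Draws `n_rand` gene sets of `sample_size` ids uniformly without
#' replacement from the universe (reference genes remain eligible) and
#' records the overlap of each draw with the reference set.
#'
#' @param reference Character vector of reference gene ids.
#' @param universe Character vector of all eligible gene ids.
#' @param sample_size Ids drawn per randomization.
#' @param n_rand Number of randomizations (default 10000).
#' @param seed Optional integer seed (isolated from the global RNG).
#' @return List with `mean_null` and the integer vector `null_counts`.
#' @export
overlap_randomization <- function(reference, universe, sample_size,
                                  n_rand = 10000, seed = NULL) {
  universe <- unique(universe)
  if (sample_size > length(universe)) {
    abort("`sample_size` exceeds the universe size")
  }
  in_ref <- universe %in% reference
  draw <- function() {
    vapply(seq_len(n_rand),
           function(i) sum(in_ref[sample.int(length(universe), sample_size)]),
           integer(1))
  }
  null_counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(mean_null = mean(null_counts), null_counts = null_counts)
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of observing at least `k` reference genes in a draw of `n`
#' genes from a universe of `N` containing `K` reference genes — the
#' standard over-representation test for gene-set overlap (the tail
#' includes `k` itself). Evaluated in log space via the stable
#' hypergeometric tail.
#'
#' @param k Observed overlap.
#' @param N Universe size.
#' @param K Reference-set size.
#' @param n Query-set size.
#' @return The p-value in (0, 1].
#' @export
hypergeometric_upper_tail <- function(k, N, K, n) {
  if (K > N || n > N) abort("`K` and `n` must not exceed `N`")
  if (k < max(0, n + K - N)) {
    abort(sprintf("infeasible overlap: k = %d below the minimum %d", k, max(0, n + K - N)))
  }
  if (k > min(K, n)) abort(sprintf("infeasible overlap: k = %d above min(K, n) = %d", k, min(K, n)))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set overlap test: randomization null plus hypergeometric p
#'
#' Quantifies the overlap between a query and a reference gene set (e.g.
#' genes derepressed on HUSH loss vs genes induced by an engineered
#' LINE-1), estimates the expected overlap of random gene sets of the
#' query's size, and computes the upper-tail hypergeometric probability of
#' an overlap at least as large as observed.
#'
#' @inheritParams observed_overlap
#' @param n_rand Number of randomizations (default 10000).
#' @param sample_size Genes per random draw; defaults to the query size
#'   ("the same number of random genes").
#' @param seed Optional integer seed.
#' @return Object of class `overlap_test` with elements `k`, `N`, `K`,
#'   `n`, `mean_null`, `null_counts`, `p_hyper`, `n_rand`, `seed`. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
overlap_test <- function(query, reference, universe, n_rand = 10000,
                         sample_size = NULL, seed = NULL) {
  universe <- unique(universe)
  k <- observed_overlap(query, reference, universe)
  query <- intersect(unique(query), universe)
  reference <- intersect(unique(reference), universe)
  sample_size <- sample_size %||% length(query)
  rnd <- overlap_randomization(reference, universe, sample_size, n_rand, seed)
  structure(
    list(
      k = k, N = length(universe), K = length(reference), n = length(query),
      mean_null = rnd$mean_null, null_counts = rnd$null_counts,
      p_hyper = hypergeometric_upper_tail(k, length(universe),
                                          length(reference), length(query)),
      n_rand = n_rand, seed = seed
    ),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test> k = %d of query n = %d vs reference K = %d (universe N = %d)\n  mean null overlap %.2f over %d randomizations; hypergeometric P(X >= k) = %.4g\n",
    x$k, x$n, x$K, x$N, x$mean_null, x$n_rand, x$p_hyper
  ))
  invisible(x)
}

#' @rdname overlap_test
#' @param x An `overlap_test` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.overlap_test <- function(x, ...) {
  tibble(k = x$k, N = x$N, K = x$K, n = x$n,
         mean_null = x$mean_null, p_hyper = x$p_hyper, n_rand = x$n_rand)
}

#' @rdname overlap_test
#' @exportS3Method generics::glance
glance.overlap_test <- function(x, ...) {
  tibble(p_hyper = x$p_hyper, k = x$k, mean_null = x$mean_null)
}

#' @rdname overlap_test
#' @param object An `overlap_test` object.
#' @exportS3Method ggplot2::autoplot
autoplot.overlap_test <- function(object, ...) {
  ggplot2::ggplot(tibble(null_overlap = object$null_counts),
                  ggplot2::aes(x = .data$null_overlap)) +
    ggplot2::geom_bar(fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$k, colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = "null overlap with reference set", y = "randomizations",
      title = sprintf("observed k = %d, mean null %.2f, hypergeometric p = %.3g",
                      object$k, object$mean_null, object$p_hyper)
    ) +
    ggplot2::theme_minimal()
}
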