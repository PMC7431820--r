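## Generic hypergeometric overlap test with fold enrichment, for
## gene/CpG set intersections (e.g. testing a significant-CpG set for
## overrepresentation of polycomb-group target genes).

#' Hypergeometric set-overlap test
#'
#' Upper-tail probability `P(X >= k)` of observing at least `k` overlaps
#' when drawing `n` items from a universe of `N` containing `K` targets,
#' with fold enrichment `k / (K * n / N)` and overlap fraction `k / K`.
#' The observed count is included in the tail (standard
#' overrepresentation convention).
#'
#' @param k observed overlap count.
#' @param K target-set size in the universe.
#' @param n query-set size in the universe.
#' @param N universe size.
#' @return list of class `overlap_test`: `k`, `K`, `n`, `N`, `p_upper`,
#'   `fold_enrichment`, `overlap_fraction`.
#' @examples
#' hypergeom_overlap(k = 293, K = 1861, n = 493, N = 14000)
#' @export
hypergeom_overlap <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need k <= min(K, n) and K, n <= N")
  p_upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(k = k, K = K, n = n, N = N, p_upper = p_upper,
                 fold_enrichment = if (K * n > 0) k / (K * n / N) else NA_real_,
                 overlap_fraction = if (K > 0) k / K else NA_real_),
            class = "overlap_test")
}

#' @rdname hypergeom_overlap
#' @param query,target,universe character vectors of ids; the counts are
#'   taken after intersecting both sets with the universe.
#' @export
overlap_test_sets <- function(query, target, universe) {
  universe <- unique(universe)
  q <- intersect(unique(query), universe)
  t <- intersect(unique(target), universe)
  hypergeom_overlap(length(intersect(q, t)), length(t), length(q),
                    length(universe))
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Hypergeometric overlap test\n")
  cat(sprintf("  k = %d of target K = %d, query n = %d, universe N = %d\n",
              x$k, x$K, x$n, x$N))
  cat(sprintf("  overlap %.1f%% of target, fold enrichment %.2f, P(X >= k) = %.3g\n",
              100 * x$overlap_fraction, x$fold_enrichment, x$p_upper))
  invisible(x)
}
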