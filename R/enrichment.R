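# Gene-set enrichment by exact hypergeometric tails.
#
# The upper tail P(X >= k) is summed directly in log space from k upward
# (log-sum-exp over exact log binomial terms) rather than as 1 - CDF, so
# deep tails keep full relative precision instead of cancelling.

# log of P(X = j) for X ~ Hypergeometric(N, K, n), vectorized over j.
.lhyper <- function(j, N, K, n) {
  lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
}

#' Exact hypergeometric upper-tail probability
#'
#' P(X >= k) where X counts query genes falling in a size-K set under
#' uniform sampling of n query genes from a universe of N.
#'
#' @param k observed overlap.
#' @param K set size.
#' @param n query size.
#' @param N universe size.
#' @return The exact upper-tail probability (1 when k <= 0).
#' @export
hyper_upper_tail <- function(k, K, n, N) {
  .assert(N >= 1, "empty universe")
  .assert(k <= min(K, n) && K <= N && n <= N, "inconsistent table")
  j <- seq(max(k, max(0, K + n - N)), min(K, n))
  if (k <= max(0, K + n - N)) return(1)   # tail covers the whole support
  lt <- .lhyper(j, N, K, n)
  m <- max(lt)
  min(1, exp(m + log(sum(exp(lt - m)))))
}

#' Hypergeometric enrichment of target sets in a query gene set
#'
#' For each target set, the exact upper-tail probability of the observed
#' overlap between the query and the set within the universe, followed by
#' Benjamini-Hochberg adjustment across sets. Query or set members outside
#' the universe are reported and clipped.
#'
#' @param query character vector of query gene ids.
#' @param sets named list of target sets (character vectors).
#' @param universe character vector of background gene ids (e.g. all genes
#'   surviving the expression filter).
#' @return data.frame: \code{set}, \code{k} (overlap), \code{K} (set
#'   size), \code{n} (query size), \code{N} (universe size), \code{p}
#'   (upper tail), \code{q} (BH).
#' @export
hypergeom_enrichment <- function(query, sets, universe) {
  .assert(length(universe) >= 1, "empty universe")
  universe <- unique(universe)
  out_q <- setdiff(query, universe)
  if (length(out_q))
    warning(length(out_q), " query genes outside the universe were clipped")
  query <- intersect(unique(query), universe)
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(sets), function(s) {
    set <- intersect(unique(sets[[s]]), universe)
    if (length(set) < length(unique(sets[[s]])))
      warning("set ", s, ": members outside the universe were clipped")
    k <- length(intersect(query, set))
    data.frame(set = s, k = k, K = length(set), n = n, N = N,
               p = hyper_upper_tail(k, length(set), n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- p.adjust(res$p, method = "BH")
  res
}

#' One-sided Fisher exact test on a 2x2 table
#'
#' Tests over-representation of the a-cell: with the table
#' \code{rbind(c(a, b), c(c, d))}, the p-value is the hypergeometric upper
#' tail with \code{k = a}, \code{K = a + b}, \code{n = a + c},
#' \code{N = a + b + c + d}.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return One-sided (greater) p-value.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  .assert(all(c(a, b, c, d) >= 0) && all(c(a, b, c, d) == round(c(a, b, c, d))),
          "cells must be non-negative integers")
  N <- a + b + c + d
  .assert(N > 0, "undefined for an all-zero table")
  hyper_upper_tail(a, a + b, a + c, N)
}
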