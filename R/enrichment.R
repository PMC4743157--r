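#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ hypergeometric(N, K, n): the probability that a uniform
#' draw of `n` genes from a universe of `N` contains at least `k` of the `K`
#' genes annotated to a term. This is the one-sided Fisher over-representation
#' statistic. Evaluated through the log-scale tail of [stats::phyper] for
#' numerical stability; an exact zero underflow is clamped to the smallest
#' positive double so that `-log10(p)` stays finite.
#'
#' @param N universe size.
#' @param K term size (genes annotated to the term), `K <= N`.
#' @param n query size, `n <= N`.
#' @param k overlap, `0 <= k <= min(K, n)`.
#' @return The tail probability, in (0, 1].
#' @examples
#' hypergeom_upper_tail(10, 4, 5, 4)  # 6/252
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (is.na(N) || is.na(K) || is.na(n) || is.na(k))
    stop("hypergeometric arguments must be non-missing")
  if (N < 0 || K < 0 || n < 0 || k < 0 || K > N || n > N || k > min(K, n))
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), K <= N, n <= N")
  if (k == 0) return(1)
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  p <- exp(lp)
  if (p <= 0) p <- .Machine$double.xmin
  min(p, 1)
}

#' Over-representation test of a gene list
#'
#' Tests every annotation term overlapping the query (overlap `k >= 1`)
#' with the upper-tail hypergeometric statistic against the annotation set's
#' universe, adjusts for multiplicity over the tested terms, and keeps terms
#' with adjusted p at or below `alpha`. The number of tests entering the
#' correction is the number of terms with `k >= 1`.
#'
#' Results are ordered by adjusted p, then raw p, then term size (larger
#' first), then term id — a stable, fully deterministic ranking.
#'
#' @param query a [gene_list()] or character vector of gene ids.
#' @param ann an [annotation_set()].
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @param correction a [stats::p.adjust] method (default `"BH"`,
#'   Benjamini-Hochberg).
#' @return An `enriched_terms` data frame with columns `term_id`, `term_name`,
#'   `source`, `N`, `K`, `n`, `k`, `p_raw`, `p_adj`. Attribute `n_tested`
#'   records the number of terms entering the correction.
#' @export
enrich <- function(query, ann, alpha = 0.05, correction = "BH") {
  stopifnot(inherits(ann, "annotation_set"))
  genes <- if (inherits(query, "gene_list")) query$genes else unique(as.character(query))
  genes <- intersect(genes, ann$universe)
  if (length(genes) == 0)
    stop("query has no genes in the annotation universe; ",
         "check gene identifiers or supply a matching universe")
  N <- length(ann$universe)
  n <- length(genes)
  k <- vapply(ann$term_genes, function(tg) sum(tg %in% genes), integer(1))
  tested <- which(k >= 1)
  K <- lengths(ann$term_genes)[tested]
  k <- k[tested]
  p_raw <- vapply(seq_along(tested), function(i)
    hypergeom_upper_tail(N, K[i], n, k[i]), numeric(1))
  p_adj <- stats::p.adjust(p_raw, method = correction)
  res <- data.frame(
    term_id = ann$term_ids[tested],
    term_name = unname(ann$term_names[ann$term_ids[tested]]),
    source = unname(ann$source[ann$term_ids[tested]]),
    N = rep(N, length(tested)), K = as.numeric(K),
    n = rep(n, length(tested)), k = as.numeric(k),
    p_raw = p_raw, p_adj = p_adj,
    stringsAsFactors = FALSE)
  res <- res[order_terms(res), , drop = FALSE]
  res <- res[res$p_adj <= alpha, , drop = FALSE]
  res <- enriched_terms(res)
  attr(res, "n_tested") <- length(tested)
  res
}

# deterministic significance ordering: p_adj, p_raw, larger K first, id
order_terms <- function(terms) {
  K <- terms$K
  K[is.na(K)] <- -Inf
  order(terms$p_adj, terms$p_raw, -K, terms$term_id, method = "radix")
}
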