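# Category over-representation of a query gene set versus an annotated
# background, by one-sided hypergeometric upper-tail test with BH FDR.
# The background universe is per aspect: all items with at least one
# annotation in that aspect.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` of which `K` belong to the category.
#'
#' @param k Observed category hits in the query.
#' @param n Query size (annotated query items).
#' @param K Category size in the background.
#' @param N Background universe size.
#' @return The upper-tail p-value (exact; computed via the cumulative
#'   distribution in log-capable form).
#' @export
hypergeometric_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K)) {
    stop("impossible hypergeometric counts (need 0 <= k <= min(n, K), n <= N, K <= N)")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Category enrichment of a query set
#'
#' For the chosen aspect, the universe `N` is the number of annotated items,
#' `n` the number of query items among them; per category, `K` and `k` are
#' counted on those universes, the p-value is the hypergeometric upper tail
#' and the q-value is the BH adjustment across all tested categories of the
#' aspect. Categories smaller than `min_category_size` (or empty) are
#' skipped. Output is sorted by ascending p.
#'
#' @param query Character vector of query item ids.
#' @param annotations Annotation data.frame (`item_id`, `category_id`,
#'   `aspect`).
#' @param aspect Aspect to test (`BP`, `MF` or `CC`; default `BP`).
#' @param min_category_size Minimum background category size (default 1).
#' @return A data.frame with columns `category_id`, `aspect`, `query_count`,
#'   `query_total`, `background_count`, `background_total`, `p_value`,
#'   `q_value`.
#' @export
enrich <- function(query, annotations, aspect = "BP", min_category_size = 1L) {
  ann <- annotations[annotations$aspect == aspect, , drop = FALSE]
  universe <- unique(ann$item_id)
  if (!length(universe)) stop("empty annotated universe for aspect ", aspect)
  N <- length(universe)
  query <- unique(query)
  q_ann <- intersect(query, universe)
  n <- length(q_ann)
  cats <- split(ann$item_id, ann$category_id)
  cats <- cats[lengths(cats) >= min_category_size]
  rows <- lapply(names(cats), function(cat) {
    members <- unique(cats[[cat]])
    K <- length(members)
    k <- length(intersect(q_ann, members))
    data.frame(category_id = cat, aspect = aspect,
               query_count = k, query_total = n,
               background_count = K, background_total = N,
               p_value = hypergeometric_tail(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$category_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
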