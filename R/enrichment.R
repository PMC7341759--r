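# Hypergeometric over-representation analysis of gene lists against GMT
# collections.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` when drawing `n` genes from a universe of `N` containing
#' `K` set members.
#'
#' @param k Overlap count observed.
#' @param K Set size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @examples
#' hypergeom_p(5, 5, 5, 10)  # 1/252
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(n, K))
    stop("inconsistent counts: need 0 <= k <= min(n, K) and K, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis against a gene-set collection
#'
#' Tests each set's overlap with the query against the hypergeometric
#' null over the given universe.  Query genes outside the universe are
#' dropped with a warning; sets are intersected with the universe and
#' only sets with a nonzero universe intersection are reported.
#'
#' @param query Character vector of genes of interest.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene vector (non-empty).
#' @param alpha Significance level on the raw p-value (default 0.01).
#' @return Data frame sorted by `p` ascending (ties by `set_name`):
#'   `set_name`, `k`, `K`, `n`, `N`, `p`, `q` (BH, informational),
#'   `significant`.
#' @export
run_ora <- function(query, sets, universe, alpha = 0.01) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped))
    warning(length(dropped), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  inter <- lapply(sets, intersect, universe)
  keep <- lengths(inter) > 0L
  inter <- inter[keep]
  if (length(inter) == 0L)
    return(data.frame(set_name = character(0L), k = integer(0L),
                      K = integer(0L), n = integer(0L), N = integer(0L),
                      p = numeric(0L), q = numeric(0L),
                      significant = logical(0L), stringsAsFactors = FALSE))
  K <- lengths(inter)
  k <- vapply(inter, function(s) length(intersect(s, query)), 0L)
  n <- length(query)
  N <- length(universe)
  p <- vapply(seq_along(inter), function(i) hypergeom_p(k[i], K[i], n, N), 0)
  out <- data.frame(set_name = names(inter), k = k, K = K, n = n, N = N,
                    p = p, q = benjamini_hochberg(p),
                    significant = p < alpha, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$p, out$set_name), , drop = FALSE]
}
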