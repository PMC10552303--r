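#' Hypergeometric over-representation analysis
#'
#' Tests each gene set of a GMT collection for over-representation in a
#' query gene list drawn from a measured-gene universe. The p-value is the
#' exact upper tail P(X >= k) of the hypergeometric distribution with
#' universe size N, term size K (after intersecting the set with the
#' universe), query size n and overlap k; Benjamini-Hochberg adjustment is
#' applied across all tested terms of the collection. Terms overlapping
#' the query by fewer than `min_overlap` genes are never called
#' significant, regardless of p.
#'
#' @param query_genes Character vector of query gene ids.
#' @param universe_genes Character vector; genes in the query but not the
#'   universe are dropped with a warning.
#' @param sets A [gene_set_collection()].
#' @param alpha BH significance level (default 0.05).
#' @param min_overlap Minimum overlap for significance (default 2).
#' @return Data.frame sorted by p: term_id, overlap, term_size,
#'   query_size, universe_size, p, p_adj, significant.
#' @export
ora <- function(query_genes, universe_genes, sets, alpha = 0.05,
                min_overlap = 2) {
  universe <- unique(as.character(universe_genes))
  query <- unique(as.character(query_genes))
  if (!length(universe)) stopf("empty universe")
  if (!length(query)) stopf("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warnf("%d query gene(s) outside the universe dropped", length(outside))
    query <- intersect(query, universe)
    if (!length(query)) stopf("no query gene lies in the universe")
  }
  N <- length(universe)
  n <- length(query)
  in_query <- stats::setNames(rep(FALSE, N), universe)
  in_query[query] <- TRUE
  rows <- lapply(names(sets$sets), function(id) {
    members <- intersect(sets$sets[[id]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- sum(in_query[members])
    data.frame(term_id = id, overlap = k, term_size = K, query_size = n,
               universe_size = N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(0), overlap = integer(0),
                      term_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  }
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res$significant <- res$p_adj < alpha & res$overlap >= min_overlap
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count significant ORA terms for one feature's route gene set
#'
#' Convenience wrapper used by the scoring stage: runs [ora()] on the gene
#' set a route associates with one metabolite and returns the number of
#' significant terms. An empty gene set yields a count of zero, not an
#' error.
#'
#' @param feature_id Metabolite feature id (carried through).
#' @param route Route label (carried through).
#' @param route_genes Character vector of associated genes (may be empty).
#' @param universe_genes Universe gene ids.
#' @param sets A [gene_set_collection()].
#' @param alpha,min_overlap Passed to [ora()].
#' @return Data.frame: feature_id, route, n_significant_terms.
#' @export
ora_for_route <- function(feature_id, route, route_genes, universe_genes,
                          sets, alpha = 0.05, min_overlap = 2) {
  n_sig <- if (!length(route_genes) || !length(sets$sets)) 0L else {
    res <- suppressWarnings(ora(route_genes, universe_genes, sets,
                                alpha = alpha, min_overlap = min_overlap))
    sum(res$significant)
  }
  data.frame(feature_id = feature_id, route = route,
             n_significant_terms = as.integer(n_sig),
             stringsAsFactors = FALSE)
}
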