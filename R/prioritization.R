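#' Assemble the three route gene sets for one metabolite
#'
#' direct = genes with a retained direct pair with the feature;
#' cluster = union of member genes of gene clusters linked to the
#' feature's cluster; bicluster = union of gene members of the selected
#' biclusters that contain the feature. Any set may be empty.
#'
#' @param feature_id Metabolite feature id (must be in the analysis set).
#' @param pairs Direct-screen output ([spearman_screen()]).
#' @param links Cluster-link output ([link_clusters()]).
#' @param gene_clusters,feature_clusters [hierarchical_clusters()] outputs.
#' @param top_biclusters [select_top_biclusters()] output.
#' @param analysis_features Character vector defining the analysis set.
#' @return Named list of character vectors: direct, cluster, bicluster.
#' @export
route_gene_sets <- function(feature_id, pairs, links, gene_clusters,
                            feature_clusters, top_biclusters,
                            analysis_features) {
  if (!feature_id %in% analysis_features) {
    stopf("feature '%s' is not in the analysis set", feature_id)
  }
  direct <- sort(unique(pairs$gene_id[pairs$feature_id == feature_id]))
  fc <- feature_clusters$cluster[feature_clusters$item_id == feature_id]
  cluster <- character(0)
  if (length(fc) == 1 && !is.na(fc)) {
    gcs <- links$gene_cluster[links$feature_cluster == fc]
    cluster <- sort(unique(
      gene_clusters$item_id[gene_clusters$cluster %in% gcs]))
  }
  bic <- character(0)
  for (b in top_biclusters) {
    if (feature_id %in% b$row_ids) bic <- c(bic, b$col_ids)
  }
  list(direct = direct, cluster = cluster, bicluster = sort(unique(bic)))
}

# Vectorized significant-term counter: same statistics as ora(), applied
# to many queries against one collection/universe. Cross-checked against
# ora() in the test suite.
count_significant_terms <- function(queries, universe_genes, sets, alpha,
                                    min_overlap) {
  universe <- unique(as.character(universe_genes))
  N <- length(universe)
  members <- lapply(sets$sets, function(g) intersect(g, universe))
  keep <- lengths(members) > 0
  members <- members[keep]
  if (!length(members)) return(rep(0L, length(queries)))
  K <- lengths(members)
  M <- vapply(members, function(g) universe %in% g,
              logical(N))                       # N x terms incidence
  vapply(queries, function(q) {
    q <- intersect(unique(q), universe)
    n <- length(q)
    if (n == 0) return(0L)
    qi <- universe %in% q
    k <- as.integer(crossprod(M, qi))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_adj <- stats::p.adjust(p, "BH")
    sum(p_adj < alpha & k >= min_overlap)
  }, integer(1), USE.NAMES = FALSE)
}

#' Combine route-wise ORA hit counts into the final metabolite ranking
#'
#' Within each route, features are ranked by descending number of
#' significant ORA terms (average ranks for ties); the combined score is
#' the sum of the three route ranks (or the raw hit sum with
#' `method = "hit_sum"`). The final order is ascending combined score,
#' ties broken by total hits descending, then feature id.
#'
#' @param route_hits Data.frame with columns feature_id, hits_direct,
#'   hits_cluster, hits_bicluster (one row per analysis-set feature).
#' @param method `"rank_sum"` (default) or `"hit_sum"`.
#' @return Data.frame with route ranks, combined_score and final_rank,
#'   sorted by final_rank.
#' @export
score_features <- function(route_hits, method = c("rank_sum", "hit_sum")) {
  method <- match.arg(method)
  if (!nrow(route_hits)) stopf("no features to score")
  h <- route_hits
  h$rank_direct <- avg_rank(-h$hits_direct)
  h$rank_cluster <- avg_rank(-h$hits_cluster)
  h$rank_bicluster <- avg_rank(-h$hits_bicluster)
  total <- h$hits_direct + h$hits_cluster + h$hits_bicluster
  h$combined_score <- if (method == "rank_sum") {
    h$rank_direct + h$rank_cluster + h$rank_bicluster
  } else {
    -total  # more hits = better, keep ascending-combined convention
  }
  ord <- order(h$combined_score, -total, h$feature_id)
  h <- h[ord, , drop = FALSE]
  h$final_rank <- seq_len(nrow(h))
  rownames(h) <- NULL
  h
}

#' Summarize a differential-expression table
#'
#' Counts genes with adjusted p below `alpha`, split by fold-change sign
#' (negative = downregulated in GF), and expresses them as percentages of
#' the prefiltered gene count, rounded to one decimal at or above 1% and
#' two decimals below.
#'
#' @param de_table Data.frame with log2_fold_change and p_adj.
#' @param n_prefiltered Number of genes passing prefiltering (positive).
#' @param alpha Significance level (default 0.05).
#' @return List: n_prefiltered, n_down, n_up, pct_down, pct_up.
#' @export
summarize_de <- function(de_table, n_prefiltered, alpha = 0.05) {
  if (n_prefiltered <= 0) stopf("n_prefiltered must be positive")
  sig <- de_table$p_adj < alpha
  n_down <- sum(sig & de_table$log2_fold_change < 0, na.rm = TRUE)
  n_up <- sum(sig & de_table$log2_fold_change > 0, na.rm = TRUE)
  pct <- function(n) {
    x <- 100 * n / n_prefiltered
    round(x, if (x >= 1) 1 else 2)
  }
  list(n_prefiltered = n_prefiltered, n_down = n_down, n_up = n_up,
       pct_down = pct(n_down), pct_up = pct(n_up))
}
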