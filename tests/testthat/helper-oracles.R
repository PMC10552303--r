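# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and base shortcuts like rank()/cor(method =
# "spearman")) so they can stand as references.

# average ranks via counting, no rank()
naive_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

naive_spearman <- function(a, b) {
  ra <- naive_rank(a)
  rb <- naive_rank(b)
  ra <- ra - mean(ra)
  rb <- rb - mean(rb)
  den <- sqrt(sum(ra^2) * sum(rb^2))
  if (den == 0) return(NA_real_)
  sum(ra * rb) / den
}

# brute-force double-loop screen
naive_screen <- function(fm, gm, threshold, use_absolute) {
  out <- list()
  for (i in seq_len(nrow(fm))) {
    for (j in seq_len(nrow(gm))) {
      r <- naive_spearman(fm[i, ], gm[j, ])
      if (is.na(r)) next
      crit <- if (use_absolute) abs(r) else r
      if (crit > threshold) {
        out[[length(out) + 1]] <- data.frame(
          feature_id = rownames(fm)[i], gene_id = rownames(gm)[j],
          rho = r, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(feature_id = character(0), gene_id = character(0),
                      rho = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$feature_id, res$gene_id), , drop = FALSE]
}

# hypergeometric upper tail by explicit enumeration of all n-subsets of a
# universe of size N whose first K elements form the term
enum_hyper_p <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# hypergeometric upper tail as an explicit binomial-coefficient sum
sum_hyper_p <- function(N, K, n, k) {
  j <- max(k, max(0, n - (N - K))):min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# hand step-up BH
manual_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# small fast study configuration for smoke-level tests
small_config <- function(seed = 1, ...) {
  sim_config(n_genes = 300, n_features = 120, n_gene_sets = 30,
             n_driver_features = 3, genes_per_driver = 15,
             n_de_genes = 40, n_discordant_pairs = 8,
             tissues = "intestine", sex_effect_genes = 10,
             seed = seed, ...)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
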