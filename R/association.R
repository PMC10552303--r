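restrict_spf <- function(litter) {
  grp <- attr(litter, "dam_group")
  if (is.null(grp)) return(litter)
  keep <- colnames(litter)[grp[colnames(litter)] == "SPF"]
  litter[, keep, drop = FALSE]
}

# Spearman correlation between rows of two matrices over shared dam
# columns; constant rows yield NA (undefined ranks).
spearman_cross <- function(a, b) {
  suppressWarnings(stats::cor(t(a), t(b), method = "spearman"))
}

#' Direct metabolite-gene Spearman screen
#'
#' All-pairs Spearman correlation (average-rank tie handling) between
#' metabolite and gene dam-level means restricted to SPF dams; a pair is
#' retained iff rho > threshold (|rho| > threshold when `use_absolute`).
#' Constant vectors have undefined rank correlation and are excluded with
#' a log entry.
#'
#' @param feature_litter Metabolite dam-mean matrix (features x SPF dams).
#' @param gene_litter Gene dam-mean matrix (genes x SPF dams), same dams
#'   in the same order.
#' @param threshold Retention threshold (default 0.9).
#' @param use_absolute Screen on |rho| (default TRUE).
#' @return Data.frame: feature_id, gene_id, rho, route = "direct".
#' @export
spearman_screen <- function(feature_litter, gene_litter, threshold = 0.9,
                            use_absolute = TRUE) {
  if (!identical(colnames(feature_litter), colnames(gene_litter))) {
    stopf("feature and gene litter matrices must share the same dams")
  }
  if (ncol(feature_litter) < 4) {
    stopf("need at least 4 dams for a meaningful Spearman screen")
  }
  const_f <- apply(feature_litter, 1, function(x) stats::sd(x) == 0)
  const_g <- apply(gene_litter, 1, function(x) stats::sd(x) == 0)
  if (any(const_f) || any(const_g)) {
    log_stage("spearman_screen", excluded_constant_features = sum(const_f),
              excluded_constant_genes = sum(const_g))
  }
  fm <- feature_litter[!const_f, , drop = FALSE]
  gm <- gene_litter[!const_g, , drop = FALSE]
  if (!nrow(fm) || !nrow(gm)) {
    return(data.frame(feature_id = character(0), gene_id = character(0),
                      rho = numeric(0), route = character(0),
                      stringsAsFactors = FALSE))
  }
  rho <- spearman_cross(fm, gm)
  crit <- if (use_absolute) abs(rho) else rho
  hit <- which(crit > threshold, arr.ind = TRUE)
  res <- data.frame(feature_id = rownames(rho)[hit[, 1]],
                    gene_id = colnames(rho)[hit[, 2]],
                    rho = rho[hit], route = "direct",
                    stringsAsFactors = FALSE)
  res <- res[order(res$feature_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  log_stage("spearman_screen", threshold = threshold,
            use_absolute = use_absolute, n_pairs = nrow(res))
  res
}

#' Complete-linkage hierarchical clustering on 1 - Spearman
#'
#' Builds an agglomerative complete-linkage tree on the dissimilarity
#' 1 - rho between item profiles over SPF dam means, then cuts it at the
#' number of clusters whose mean cluster size falls inside
#' `target_size_range`; if no cut achieves it, the closest mean size is
#' used and a warning logged. Constant items are assigned singleton
#' clusters.
#'
#' @param litter Items x dams matrix of SPF dam means.
#' @param target_size_range Length-2 target range for the mean cluster
#'   size (genes 16-43, features 7-15 in the study's calibration).
#' @return Data.frame item_id/cluster with attributes `k`, `mean_size`,
#'   `hclust`.
#' @export
hierarchical_clusters <- function(litter, target_size_range) {
  if (nrow(litter) < 2) stopf("need at least 2 items to cluster")
  const <- apply(litter, 1, function(x) stats::sd(x) == 0)
  ids <- rownames(litter)
  work <- litter[!const, , drop = FALSE]
  labels <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  tree <- NULL
  k <- 0L
  if (nrow(work) >= 2) {
    rho <- suppressWarnings(stats::cor(t(work), method = "spearman"))
    d <- stats::as.dist(1 - rho)
    tree <- stats::hclust(d, method = "complete")
    n <- nrow(work)
    mean_sizes <- n / seq_len(n)                # mean size at k clusters
    in_range <- which(mean_sizes >= target_size_range[1] &
                        mean_sizes <= target_size_range[2])
    if (length(in_range)) {
      # finest cut consistent with the calibrated mean size, so natural
      # fine structure stays resolved
      k <- max(in_range)
    } else {
      k <- which.min(pmin(abs(mean_sizes - target_size_range[1]),
                          abs(mean_sizes - target_size_range[2])))
      warnf("no cut gives mean cluster size in [%g, %g]; using k=%d (mean %.2f)",
            target_size_range[1], target_size_range[2], k, n / k)
    }
    labels[rownames(work)] <- stats::cutree(tree, k = k)
  } else if (nrow(work) == 1) {
    labels[rownames(work)] <- 1L
    k <- 1L
  }
  if (any(const)) {
    labels[ids[const]] <- k + seq_len(sum(const))
    log_stage("hierarchical_clusters", singleton_constant_items = sum(const))
  }
  res <- data.frame(item_id = ids, cluster = unname(labels[ids]),
                    stringsAsFactors = FALSE)
  attr(res, "k") <- max(res$cluster)
  attr(res, "mean_size") <- nrow(res) / max(res$cluster)
  attr(res, "hclust") <- tree
  log_stage("hierarchical_clusters", n_items = nrow(res),
            k = attr(res, "k"), mean_size = signif(attr(res, "mean_size"), 4))
  res
}

#' Link gene clusters with metabolite clusters
#'
#' For every (gene cluster, feature cluster) pair, the mean over all
#' member gene x feature pairs of the signed Spearman correlation on SPF
#' dam means; a link is retained iff the mean exceeds `threshold`.
#'
#' @param gene_clusters,feature_clusters Outputs of
#'   [hierarchical_clusters()].
#' @param gene_litter,feature_litter SPF dam-mean matrices.
#' @param threshold Mean-rho threshold (default 0.7; the study used 0.6
#'   for brain).
#' @param use_absolute Use |rho| instead of signed rho (default FALSE).
#' @return Data.frame: gene_cluster, feature_cluster, mean_rho, n_pairs.
#' @export
link_clusters <- function(gene_clusters, feature_clusters, gene_litter,
                          feature_litter, threshold = 0.7,
                          use_absolute = FALSE) {
  rho <- spearman_cross(feature_litter, gene_litter)
  if (use_absolute) rho <- abs(rho)
  out <- list()
  for (gc in sort(unique(gene_clusters$cluster))) {
    g_ids <- intersect(gene_clusters$item_id[gene_clusters$cluster == gc],
                       colnames(rho))
    if (!length(g_ids)) { warnf("gene cluster %s empty; skipped", gc); next }
    for (fc in sort(unique(feature_clusters$cluster))) {
      f_ids <- intersect(
        feature_clusters$item_id[feature_clusters$cluster == fc],
        rownames(rho))
      if (!length(f_ids)) next
      block <- rho[f_ids, g_ids, drop = FALSE]
      m <- mean(block)
      if (!is.na(m) && m > threshold) {
        out[[length(out) + 1]] <- data.frame(
          gene_cluster = gc, feature_cluster = fc, mean_rho = m,
          n_pairs = length(block), stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(gene_cluster = integer(0), feature_cluster = integer(0),
                  mean_rho = numeric(0), n_pairs = integer(0))
  log_stage("link_clusters", threshold = threshold, n_links = nrow(res))
  res
}

#' Classify metabolite-gene dependency shape
#'
#' The analysis-set metabolites are lowest (often absent) in GF, so linear
#' extrapolation of the within-SPF correlation predicts the GF expression
#' shift: rho_spf < 0 predicts GF expression above SPF, rho_spf > 0
#' predicts below. Agreement gives `linear_consistent`; disagreement
#' (e.g. a negatively correlated gene that is nonetheless downregulated in
#' GF) gives `nonlinear_discordant`. A zero GF shift is
#' `linear_consistent` with `zero_effect = TRUE`.
#'
#' @param pairs Data.frame with feature_id, gene_id, rho (association
#'   pairs whose feature is gf_absent or spf_higher).
#' @param gene_group_means Data.frame gene_id, mean_gf, mean_spf (e.g.
#'   mean normalized expression per group).
#' @return `pairs` with gf_direction, label, zero_effect columns; pairs
#'   with undefined rho are excluded.
#' @export
classify_dependency <- function(pairs, gene_group_means) {
  keep <- !is.na(pairs$rho)
  if (any(!keep)) log_stage("classify_dependency", excluded_na_rho = sum(!keep))
  pairs <- pairs[keep, , drop = FALSE]
  idx <- match(pairs$gene_id, gene_group_means$gene_id)
  if (anyNA(idx)) stopf("group means missing for gene '%s'",
                        pairs$gene_id[which(is.na(idx))[1]])
  gf_dir <- sign(gene_group_means$mean_gf[idx] -
                   gene_group_means$mean_spf[idx])
  expected <- -sign(pairs$rho)
  label <- ifelse(gf_dir == 0 | gf_dir == expected,
                  "linear_consistent", "nonlinear_discordant")
  res <- data.frame(pairs[, c("feature_id", "gene_id", "rho")],
                    gf_direction = gf_dir, label = label,
                    zero_effect = gf_dir == 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  log_stage("classify_dependency", n_pairs = nrow(res),
            n_discordant = sum(res$label == "nonlinear_discordant"))
  res
}
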