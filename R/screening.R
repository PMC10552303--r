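#' Prefilter genes by read support
#'
#' Keeps exactly the genes with at least `min_reads` reads in at least
#' `min_samples` samples (the count of fetuses in one group); order is
#' preserved.
#'
#' @param counts An [omics_matrix()] of kind counts.
#' @param min_reads Minimum reads per sample (default 5).
#' @param min_samples Minimum number of samples meeting `min_reads`
#'   (default 12).
#' @return The filtered count matrix.
#' @export
prefilter_genes <- function(counts, min_reads = 5, min_samples = 12) {
  if (!identical(matrix_kind(counts), "counts")) {
    stopf("prefilter_genes expects a count matrix")
  }
  if (min_samples > ncol(counts)) {
    stopf("min_samples (%d) exceeds number of samples (%d)",
          min_samples, ncol(counts))
  }
  keep <- rowSums(counts >= min_reads) >= min_samples
  log_stage("prefilter_genes", min_reads = min_reads,
            min_samples = min_samples, n_in = nrow(counts),
            n_out = sum(keep))
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios normalization
#'
#' Size factor per sample = median over reference genes of
#' count / geometric mean across samples, using only genes with
#' all-positive counts; normalized value = count / size factor.
#'
#' @param counts Prefiltered count matrix.
#' @return An [omics_matrix()] of kind intensities (normalized counts),
#'   with the size factors in attribute `size_factors`.
#' @export
normalize_counts <- function(counts) {
  m <- unclass(counts)
  attr(m, "kind") <- NULL
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    stopf(paste("no gene has positive counts in every sample;",
                "consider a pseudo-reference (e.g. adding 1) upstream"))
  }
  log_geo <- rowMeans(log(m[all_pos, , drop = FALSE]))
  sf <- apply(log(m[all_pos, , drop = FALSE]) - log_geo, 2,
              function(lr) exp(stats::median(lr)))
  norm <- sweep(m, 2, sf, "/")
  out <- omics_matrix(norm, "intensities")
  attr(out, "size_factors") <- sf
  log_stage("normalize_counts", n_reference = sum(all_pos),
            sf_range = paste(signif(range(sf), 3), collapse = "-"))
  out
}

#' Differential-expression stand-in
#'
#' A simple, clearly flagged substitute used only when no external DE
#' table is supplied: per gene, an ordinary linear model on
#' log2(normalized + 1) with group and sex terms; two-sided t-test on the
#' group (GF vs SPF) coefficient; Benjamini-Hochberg adjustment.
#'
#' @param norm_counts Normalized expression matrix (genes x samples).
#' @param metadata Sample metadata covering the matrix columns.
#' @return A `de_table` data.frame: gene_id, log2_fold_change (GF vs SPF),
#'   p, p_adj, zero_variance, source = "standin".
#' @export
de_standin <- function(norm_counts, metadata) {
  md <- metadata[match(colnames(norm_counts), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stopf("metadata missing some matrix samples")
  for (g in c("GF", "SPF")) {
    if (sum(md$group == g) < 2) stopf("group %s has fewer than 2 samples", g)
  }
  if (length(unique(md$sex)) < 2) stopf("both sexes must be present")
  y <- log2(unclass(norm_counts) + 1)
  design <- stats::model.matrix(~ group + sex,
                                data.frame(group = factor(md$group,
                                                          c("SPF", "GF")),
                                           sex = factor(md$sex)))
  qr_d <- qr(design)
  coefs <- t(qr.coef(qr_d, t(y)))
  resid <- t(qr.resid(qr_d, t(y)))
  df_res <- ncol(y) - qr_d$rank
  sigma2 <- rowSums(resid^2) / df_res
  xtx_inv <- chol2inv(qr.R(qr_d))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  lfc <- coefs[, "groupGF"]
  tstat <- lfc / se
  p <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
  zero_var <- sigma2 <= .Machine$double.eps * 100
  p[zero_var | !is.finite(p)] <- 1
  res <- data.frame(gene_id = rownames(y), log2_fold_change = lfc,
                    p = p, p_adj = stats::p.adjust(p, "BH"),
                    zero_variance = zero_var, source = "standin",
                    row.names = NULL, stringsAsFactors = FALSE)
  log_stage("de_standin", n_genes = nrow(res),
            n_significant = sum(res$p_adj < 0.05))
  res
}

#' Classify metabolite differential status
#'
#' Per feature of one tissue's metabolome: `gf_absent` if it has zero GF
#' detections and detections in at least half of the SPF samples;
#' otherwise `spf_higher` if a two-group test on log2(intensity + 1) gives
#' BH-adjusted p < alpha with the SPF mean higher; otherwise `unchanged`.
#' Features qualifying in at least one tissue form the association
#' analysis set.
#'
#' @param intensities Metabolome intensity matrix (one tissue).
#' @param metadata Sample metadata covering the matrix columns.
#' @param alpha BH significance level (default 0.05).
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return Data.frame: feature_id, status, n_detect_gf, n_detect_spf, p,
#'   p_adj, direction (sign of SPF mean - GF mean).
#' @export
classify_metabolites <- function(intensities, metadata, alpha = 0.05,
                                 test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  md <- metadata[match(colnames(intensities), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stopf("metadata missing some matrix samples")
  is_gf <- md$group == "GF"
  if (sum(is_gf) < 3 || sum(!is_gf) < 3) {
    stopf("need at least 3 samples per group")
  }
  m <- unclass(intensities)
  m[is.na(m)] <- 0  # NA-encoded non-detects
  y <- log2(m + 1)
  n_det_gf <- rowSums(m[, is_gf, drop = FALSE] > 0)
  n_det_spf <- rowSums(m[, !is_gf, drop = FALSE] > 0)
  mean_gf <- rowMeans(y[, is_gf, drop = FALSE])
  mean_spf <- rowMeans(y[, !is_gf, drop = FALSE])
  p <- vapply(seq_len(nrow(y)), function(i) {
    a <- y[i, !is_gf]
    b <- y[i, is_gf]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) return(1)
      return(0)  # two distinct constants: maximal evidence
    }
    if (test == "welch") {
      stats::t.test(a, b)$p.value
    } else {
      stats::wilcox.test(a, b, exact = FALSE)$p.value
    }
  }, numeric(1))
  p_adj <- stats::p.adjust(p, "BH")
  direction <- sign(mean_spf - mean_gf)
  status <- rep("unchanged", nrow(y))
  status[p_adj < alpha & direction > 0] <- "spf_higher"
  status[n_det_gf == 0 & n_det_spf >= ceiling(sum(!is_gf) / 2)] <- "gf_absent"
  res <- data.frame(feature_id = rownames(m), status = status,
                    n_detect_gf = n_det_gf, n_detect_spf = n_det_spf,
                    p = p, p_adj = p_adj, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  log_stage("classify_metabolites", test = test, alpha = alpha,
            gf_absent = sum(status == "gf_absent"),
            spf_higher = sum(status == "spf_higher"),
            unchanged = sum(status == "unchanged"))
  res
}

#' Average fetuses into litter (dam-level) means
#'
#' Replaces the fetuses of each dam by their arithmetic mean, one column
#' per dam, dams ordered by id. Singleton litters are allowed and
#' recorded.
#'
#' @param matrix Features x samples matrix from one tissue and assay.
#' @param metadata Sample metadata covering the matrix columns.
#' @return Features x dams matrix with attribute `n_fetuses` (named
#'   integer vector per dam).
#' @export
average_litters <- function(matrix, metadata) {
  md <- metadata[match(colnames(matrix), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stopf("metadata missing some matrix samples")
  if (length(unique(md$tissue)) > 1 || length(unique(md$assay)) > 1) {
    stopf("average_litters expects samples from one tissue and one assay")
  }
  dams <- sort(unique(md$dam_id))
  m <- unclass(matrix)
  out <- vapply(dams, function(d) {
    rowMeans(m[, md$dam_id == d, drop = FALSE])
  }, numeric(nrow(m)))
  out <- base::matrix(out, nrow = nrow(m), dimnames = list(rownames(m), dams))
  nf <- vapply(dams, function(d) sum(md$dam_id == d), integer(1))
  if (any(nf == 1)) {
    log_stage("average_litters", singleton_dams = names(nf)[nf == 1])
  }
  attr(out, "n_fetuses") <- nf
  attr(out, "dam_group") <- stats::setNames(
    md$group[match(dams, md$dam_id)], dams)
  out
}

#' Twin-similarity permutation test
#'
#' Tests whether fetuses from the same dam have more similar profiles than
#' fetuses from different dams. The statistic is
#' mean(within-litter pairwise sample Spearman) - mean(between-litter
#' pairwise Spearman); its one-sided permutation p-value is computed over
#' `n_perm` random reassignments of fetuses to dams (litter sizes
#' preserved), with the add-one correction
#' p = (1 + #\{perm >= observed\}) / (1 + n_perm).
#'
#' @param matrix Features x samples matrix (one tissue, one assay).
#' @param metadata Sample metadata covering the matrix columns.
#' @param n_perm Number of permutations (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed Integer seed for the permutations.
#' @return List: statistic, within_rho_range, between_rho_range, p_perm,
#'   n_within_pairs, n_between_pairs.
#' @export
twin_similarity_test <- function(matrix, metadata, n_perm = 1000, seed = 1) {
  if (n_perm < 100) warnf("n_perm = %d is small; p resolution is coarse",
                          n_perm)
  md <- metadata[match(colnames(matrix), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stopf("metadata missing some matrix samples")
  litters <- table(md$dam_id)
  if (sum(litters >= 2) < 2) stopf("need at least 2 dams with 2+ fetuses")
  m <- unclass(matrix)
  m[is.na(m)] <- 0
  constant <- apply(m, 2, function(x) stats::sd(x) == 0)
  if (all(constant)) {
    return(list(statistic = 0, within_rho_range = c(NA_real_, NA_real_),
                between_rho_range = c(NA_real_, NA_real_), p_perm = 1,
                n_within_pairs = 0, n_between_pairs = 0))
  }
  rho <- stats::cor(m, method = "spearman")
  same_dam <- outer(md$dam_id, md$dam_id, "==")
  ut <- upper.tri(rho)
  stat_for <- function(same) {
    mean(rho[ut & same]) - mean(rho[ut & !same])
  }
  obs <- stat_for(same_dam)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    lab <- sample(md$dam_id)
    stat_for(outer(lab, lab, "=="))
  }, numeric(1))
  p_perm <- (1 + sum(perm >= obs)) / (1 + n_perm)
  res <- list(statistic = obs,
              within_rho_range = range(rho[ut & same_dam]),
              between_rho_range = range(rho[ut & !same_dam]),
              p_perm = p_perm,
              n_within_pairs = sum(ut & same_dam),
              n_between_pairs = sum(ut & !same_dam))
  log_stage("twin_similarity_test", statistic = signif(obs, 4),
            p_perm = p_perm, n_perm = n_perm)
  res
}
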