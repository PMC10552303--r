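#' Pipeline configuration
#'
#' All tunable thresholds of the association pipeline, with the study's
#' defaults. Brain tissue gets laxer cluster-link and prefilter settings
#' (fewer differentially expressed genes, one excluded outlier sample), via
#' `brain_tissues` overrides applied by [run_pipeline()].
#'
#' @param rho_pair Spearman threshold for the direct metabolite-gene screen
#'   on SPF dam means (default 0.9).
#' @param rho_cluster Mean-Spearman threshold to link a gene cluster with a
#'   metabolite cluster (default 0.7).
#' @param rho_cluster_brain Cluster-link threshold used for brain tissue
#'   (default 0.6).
#' @param alpha Benjamini-Hochberg significance level used throughout
#'   (default 0.05).
#' @param prefilter_min_reads,prefilter_min_samples Keep genes with at least
#'   `prefilter_min_reads` reads in at least `prefilter_min_samples` fetuses
#'   (defaults 5 and 12).
#' @param prefilter_min_samples_brain Prefilter sample quorum for brain
#'   (default 11).
#' @param use_absolute_rho Screen on |rho| rather than signed rho
#'   (default TRUE; the sign is retained on every reported pair).
#' @param max_layers,row_release,col_release,n_shuffles,iter_startup,iter_layer
#'   Plaid biclustering parameters: layer budget, row/column release
#'   thresholds, number of permuted copies for layer acceptance, and
#'   iteration counts (defaults 10, 0.7, 0.7, 3, 5, 10).
#' @param ora_min_overlap Minimum query/term overlap for an ORA term to be
#'   eligible for significance (default 2).
#' @param target_cluster_genes,target_cluster_features Target mean cluster
#'   sizes used to choose the tree cut (defaults 16-43 genes, 7-15
#'   features).
#' @param n_perm Permutations for the twin-similarity test (default 1000).
#' @param seed Integer seed for all stochastic steps.
#' @param de_genes_only Restrict correlation/clustering to genes significant
#'   in the DE table (default TRUE).
#' @param metabolite_test Two-group test for metabolite abundance:
#'   `"welch"` (default) or `"wilcoxon"`.
#' @param signed_cluster_link Use signed (TRUE, default) or absolute mean
#'   Spearman for cluster linking.
#' @param top_bicluster_count How many accepted biclusters to keep after
#'   ranking by mean internal correlation; `NULL` (default) keeps the top
#'   half (minimum one).
#' @param score_method Combined score: `"rank_sum"` (default) or
#'   `"hit_sum"`.
#' @param top_n_detail Number of top-ranked features reported in detail
#'   (default 20).
#' @param brain_tissues Tissue labels that receive the brain overrides
#'   (default `"brain"`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(rho_pair = 0.9,
                            rho_cluster = 0.7,
                            rho_cluster_brain = 0.6,
                            alpha = 0.05,
                            prefilter_min_reads = 5,
                            prefilter_min_samples = 12,
                            prefilter_min_samples_brain = 11,
                            use_absolute_rho = TRUE,
                            max_layers = 10,
                            row_release = 0.7,
                            col_release = 0.7,
                            n_shuffles = 3,
                            iter_startup = 5,
                            iter_layer = 10,
                            ora_min_overlap = 2,
                            target_cluster_genes = c(16, 43),
                            target_cluster_features = c(7, 15),
                            n_perm = 1000,
                            seed = 1,
                            de_genes_only = TRUE,
                            metabolite_test = c("welch", "wilcoxon"),
                            signed_cluster_link = TRUE,
                            top_bicluster_count = NULL,
                            score_method = c("rank_sum", "hit_sum"),
                            top_n_detail = 20,
                            brain_tissues = "brain") {
  metabolite_test <- match.arg(metabolite_test)
  score_method <- match.arg(score_method)
  cfg <- list(rho_pair = rho_pair, rho_cluster = rho_cluster,
              rho_cluster_brain = rho_cluster_brain, alpha = alpha,
              prefilter_min_reads = prefilter_min_reads,
              prefilter_min_samples = prefilter_min_samples,
              prefilter_min_samples_brain = prefilter_min_samples_brain,
              use_absolute_rho = isTRUE(use_absolute_rho),
              max_layers = max_layers, row_release = row_release,
              col_release = col_release, n_shuffles = n_shuffles,
              iter_startup = iter_startup, iter_layer = iter_layer,
              ora_min_overlap = ora_min_overlap,
              target_cluster_genes = target_cluster_genes,
              target_cluster_features = target_cluster_features,
              n_perm = n_perm, seed = seed,
              de_genes_only = isTRUE(de_genes_only),
              metabolite_test = metabolite_test,
              signed_cluster_link = isTRUE(signed_cluster_link),
              top_bicluster_count = top_bicluster_count,
              score_method = score_method,
              top_n_detail = top_n_detail,
              brain_tissues = as.character(brain_tissues))
  for (nm in c("rho_pair", "rho_cluster", "rho_cluster_brain")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      stopf("%s must be in (0, 1], got %s", nm, format(v))
    }
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stopf("alpha must be in (0, 1)")
  }
  for (nm in c("prefilter_min_reads", "prefilter_min_samples",
               "prefilter_min_samples_brain", "max_layers", "n_shuffles",
               "iter_startup", "iter_layer", "ora_min_overlap", "n_perm",
               "top_n_detail")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stopf("%s must be a positive integer, got %s", nm, format(v))
    }
    cfg[[nm]] <- as.integer(v)
  }
  for (nm in c("row_release", "col_release")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stopf("%s must be in [0, 1]", nm)
  }
  for (nm in c("target_cluster_genes", "target_cluster_features")) {
    v <- cfg[[nm]]
    if (length(v) != 2 || any(v < 1) || v[1] > v[2]) {
      stopf("%s must be an increasing pair of positive sizes", nm)
    }
  }
  if (!is.null(cfg$top_bicluster_count) &&
      (cfg$top_bicluster_count < 1 ||
       cfg$top_bicluster_count != round(cfg$top_bicluster_count))) {
    stopf("top_bicluster_count must be a positive integer or NULL")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys absent from the file take their defaults; unknown keys are an error
#' so that typos never silently fall back to defaults. The full effective
#' configuration is echoed to the log.
#'
#' @param path Path to a YAML file (may be empty).
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- do.call(pipeline_config, vals)
  log_stage("load_config", path = path,
            effective = paste(names(cfg), vapply(cfg, function(v)
              paste(format(v), collapse = "/"), character(1)),
              sep = ":", collapse = " "))
  cfg
}

# Per-tissue view of the config: brain overrides applied.
config_for_tissue <- function(config, tissue) {
  if (tissue %in% config$brain_tissues) {
    config$rho_cluster <- config$rho_cluster_brain
    config$prefilter_min_samples <- config$prefilter_min_samples_brain
  }
  config
}
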