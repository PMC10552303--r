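run_tissue <- function(tissue, counts, intensities, metadata, gene_sets,
                       config, de_table = NULL) {
  cfg <- config_for_tissue(config, tissue)
  md_tx <- metadata[metadata$tissue == tissue &
                      metadata$assay == "transcriptome", ]
  md_mb <- metadata[metadata$tissue == tissue &
                      metadata$assay == "metabolome", ]
  cts <- counts[, intersect(colnames(counts), md_tx$sample_id),
                drop = FALSE]
  ints <- intensities[, intersect(colnames(intensities), md_mb$sample_id),
                      drop = FALSE]
  if (!ncol(cts) || !ncol(ints)) {
    stopf("tissue '%s' lacks transcriptome or metabolome samples", tissue)
  }

  filtered <- prefilter_genes(cts, cfg$prefilter_min_reads,
                              cfg$prefilter_min_samples)
  if (!nrow(filtered)) stopf("no genes pass prefiltering")
  norm <- normalize_counts(filtered)

  if (is.null(de_table)) {
    de_table <- de_standin(norm, md_tx)
  } else {
    de_table$source <- de_table$source %||% "external"
    log_stage("de_table", source = "external", n_genes = nrow(de_table))
  }
  de_summary <- summarize_de(de_table, nrow(filtered), cfg$alpha)

  status <- classify_metabolites(ints, md_mb, alpha = cfg$alpha,
                                 test = cfg$metabolite_test)
  analysis_features <- status$feature_id[status$status != "unchanged"]
  if (!length(analysis_features)) {
    stopf("no metabolite enters the analysis set")
  }

  qc <- list(
    transcriptome = twin_similarity_test(norm, md_tx, cfg$n_perm, cfg$seed),
    metabolome = twin_similarity_test(ints, md_mb, cfg$n_perm,
                                      cfg$seed + 1L))

  assoc_genes <- if (cfg$de_genes_only) {
    intersect(de_table$gene_id[de_table$p_adj < cfg$alpha], rownames(norm))
  } else rownames(norm)
  if (length(assoc_genes) < 2) {
    stopf("fewer than 2 genes available for the association routes")
  }
  log_stage("association_genes", n = length(assoc_genes),
            de_genes_only = cfg$de_genes_only)

  gene_litter <- restrict_spf(average_litters(norm, md_tx))
  feat_litter <- restrict_spf(average_litters(ints, md_mb))
  if (ncol(gene_litter) < 4) {
    stopf("fewer than 4 SPF dams; dam-level correlations refused")
  }
  gene_litter <- gene_litter[assoc_genes, , drop = FALSE]
  feat_litter <- feat_litter[analysis_features, , drop = FALSE]

  pairs <- spearman_screen(feat_litter, gene_litter, cfg$rho_pair,
                           cfg$use_absolute_rho)

  gene_clusters <- hierarchical_clusters(gene_litter,
                                         cfg$target_cluster_genes)
  feature_clusters <- hierarchical_clusters(feat_litter,
                                            cfg$target_cluster_features)
  links <- link_clusters(gene_clusters, feature_clusters, gene_litter,
                         feat_litter, cfg$rho_cluster,
                         use_absolute = !cfg$signed_cluster_link)

  rho_cross <- spearman_cross(feat_litter, gene_litter)
  ok_rows <- rowSums(is.na(rho_cross)) < ncol(rho_cross)
  ok_cols <- colSums(is.na(rho_cross)) < nrow(rho_cross)
  corr_abs <- abs(rho_cross[ok_rows, ok_cols, drop = FALSE])
  biclusters <- if (nrow(corr_abs) >= 2 && ncol(corr_abs) >= 2) {
    plaid_biclustering(corr_abs, max_layers = cfg$max_layers,
                       row_release = cfg$row_release,
                       col_release = cfg$col_release,
                       n_shuffles = cfg$n_shuffles,
                       iter_startup = cfg$iter_startup,
                       iter_layer = cfg$iter_layer, seed = cfg$seed)
  } else list()
  top_bics <- select_top_biclusters(biclusters, cfg$top_bicluster_count)

  route_sets <- lapply(analysis_features, route_gene_sets, pairs = pairs,
                       links = links, gene_clusters = gene_clusters,
                       feature_clusters = feature_clusters,
                       top_biclusters = top_bics,
                       analysis_features = analysis_features)
  names(route_sets) <- analysis_features
  universe <- rownames(norm)
  hits <- data.frame(
    feature_id = analysis_features,
    hits_direct = count_significant_terms(
      lapply(route_sets, `[[`, "direct"), universe, gene_sets,
      cfg$alpha, cfg$ora_min_overlap),
    hits_cluster = count_significant_terms(
      lapply(route_sets, `[[`, "cluster"), universe, gene_sets,
      cfg$alpha, cfg$ora_min_overlap),
    hits_bicluster = count_significant_terms(
      lapply(route_sets, `[[`, "bicluster"), universe, gene_sets,
      cfg$alpha, cfg$ora_min_overlap),
    stringsAsFactors = FALSE)
  scores <- score_features(hits, cfg$score_method)

  is_gf <- md_tx$group[match(colnames(norm), md_tx$sample_id)] == "GF"
  gene_group_means <- data.frame(
    gene_id = rownames(norm),
    mean_gf = rowMeans(unclass(norm)[, is_gf, drop = FALSE]),
    mean_spf = rowMeans(unclass(norm)[, !is_gf, drop = FALSE]),
    stringsAsFactors = FALSE)
  dependency <- classify_dependency(pairs, gene_group_means)

  top_ids <- scores$feature_id[seq_len(min(cfg$top_n_detail, nrow(scores)))]
  detail <- do.call(rbind, lapply(top_ids, function(f) {
    res <- if (length(route_sets[[f]]$direct)) {
      suppressWarnings(ora(route_sets[[f]]$direct, universe, gene_sets,
                           cfg$alpha, cfg$ora_min_overlap))
    } else NULL
    data.frame(feature_id = f,
               final_rank = scores$final_rank[scores$feature_id == f],
               n_direct_genes = length(route_sets[[f]]$direct),
               direct_genes = paste(route_sets[[f]]$direct, collapse = ","),
               significant_terms = if (is.null(res)) "" else
                 paste(res$term_id[res$significant], collapse = ","),
               stringsAsFactors = FALSE)
  }))

  list(tissue = tissue, config = cfg, de_table = de_table,
       de_summary = de_summary, feature_status = status, qc = qc,
       n_prefiltered = nrow(filtered), analysis_features = analysis_features,
       pairs = pairs, gene_clusters = gene_clusters,
       feature_clusters = feature_clusters, links = links,
       biclusters = biclusters, top_biclusters = top_bics,
       route_sets = route_sets, route_hits = hits, scores = scores,
       dependency = dependency, top_detail = detail)
}

write_tissue_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(res$de_table, "de_table.tsv")
  wt(res$feature_status, "feature_status.tsv")
  wt(res$pairs, "association_pairs.tsv")
  wt(res$gene_clusters, "gene_clusters.tsv")
  wt(res$feature_clusters, "feature_clusters.tsv")
  wt(res$links, "cluster_links.tsv")
  wt(res$route_hits, "route_hits.tsv")
  wt(res$scores, "feature_scores.tsv")
  wt(res$dependency, "dependency_labels.tsv")
  wt(res$top_detail, "top_features.tsv")
  jsonlite::write_json(
    list(de_summary = res$de_summary, qc = res$qc,
         background = attr(res$biclusters, "background"),
         biclusters = lapply(res$biclusters, function(b)
           b[c("row_ids", "col_ids", "layer_mean", "background",
               "importance", "mean_internal_corr")])),
    file.path(dir, "tissue_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full per-tissue association and prioritization pipeline
#'
#' For each tissue: gene prefiltering, median-of-ratios normalization,
#' differential expression (an external table when supplied, otherwise the
#' flagged stand-in), metabolite status classification, litter averaging,
#' twin-similarity QC, the three association routes on SPF dam means, ORA
#' per route per metabolite, combined scoring and dependency labeling. A
#' failing tissue is reported and skipped; other tissues proceed. With the
#' same inputs, config and seed the outputs are identical.
#'
#' @param counts Gene count [omics_matrix()] (all tissues).
#' @param intensities Metabolite intensity [omics_matrix()].
#' @param metadata Sample metadata data.frame.
#' @param gene_sets A [gene_set_collection()].
#' @param config A [pipeline_config()].
#' @param de_tables Optional named list (per tissue) of external DE
#'   tables; tissues without an entry use the stand-in.
#' @param tissues Tissues to run (default: all in metadata).
#' @param outdir Optional output directory; per-tissue TSV/JSON outputs
#'   and a manifest.json are written there.
#' @return List with `tissues` (per-tissue results or error message),
#'   `manifest`.
#' @export
run_pipeline <- function(counts, intensities, metadata, gene_sets,
                         config = pipeline_config(), de_tables = NULL,
                         tissues = NULL, outdir = NULL) {
  metadata <- validate_metadata(metadata)
  if (is.null(tissues)) tissues <- sort(unique(metadata$tissue))
  results <- list()
  for (tissue in tissues) {
    results[[tissue]] <- tryCatch(
      run_tissue(tissue, counts, intensities, metadata, gene_sets,
                 config, de_tables[[tissue]]),
      error = function(e) {
        log_stage("tissue_failed", tissue = tissue,
                  reason = conditionMessage(e))
        structure(list(tissue = tissue, error = conditionMessage(e)),
                  class = "tissue_error")
      })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("fetomics")),
    config = unclass(config), seed = config$seed,
    tissues_requested = tissues,
    tissues_completed = names(results)[!vapply(results, inherits,
                                               logical(1), "tissue_error")],
    dims = list(counts = dim(counts), intensities = dim(intensities),
                metadata = nrow(metadata), gene_sets = length(gene_sets)),
    input_checksums = list(counts = sum(counts),
                           intensities = sum(intensities)))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (tissue in names(results)) {
      if (!inherits(results[[tissue]], "tissue_error")) {
        write_tissue_outputs(results[[tissue]], file.path(outdir, tissue))
      }
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(tissues = results, manifest = manifest)
}
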