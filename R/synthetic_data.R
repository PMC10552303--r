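#' Synthetic-study configuration
#'
#' Parameters of the twin-litter GF/SPF multi-omics generator. Defaults
#' emulate the study design: 6 dams per group, two fetuses per dam per
#' assay (transcriptomics and metabolomics on different fetuses), three
#' tissues, strong within-litter similarity, a subset of metabolite
#' features absent or reduced in GF, and dose-response couplings between
#' dam-level metabolite exposure and fetal gene expression within SPF.
#'
#' @param n_dams_per_group Dams per group (default 6; at least 3).
#' @param fetuses_per_dam_per_assay Fetuses per dam per assay (default 2).
#' @param tissues Tissue labels (default intestine, brain, placenta).
#' @param n_genes,n_features Numbers of genes and molecular features.
#' @param n_driver_features Planted driver metabolites (default 5).
#' @param genes_per_driver Genes coupled to each driver (default 30).
#' @param n_gene_sets,gene_set_size_range Emitted GMT collection size and
#'   per-set member range (defaults 100 sets of 10-80 genes).
#' @param sets_per_driver Overlapping enriched sets planted per driver
#'   (default 8), emulating the redundancy of real ontology collections
#'   where one transcriptional program lights up several related terms.
#' @param frac_gf_absent,frac_spf_higher Fractions of features planted as
#'   GF-absent (default 0.05) or SPF-elevated (default 0.15); assigned in
#'   whole families (rounded to family granularity).
#' @param features_per_family Non-driver features are grouped into
#'   families of this size (default 12) sharing a dam-level latent, the
#'   way chemically related compounds (e.g. aryl sulfates) co-vary in
#'   LC-MS data; differential status is assigned family-wise.
#' @param family_sd Log-scale SD of the shared family dam latent
#'   (default 0, i.e. families are labels only; positive values
#'   add realistic compound-family covariance, which makes driver
#'   recovery genuinely harder at six dams).
#' @param litter_sd Log-scale SD of the per-gene / per-feature dam random
#'   effect (default 0.3).
#' @param sex_effect_genes Genes with a planted sex effect (default 50).
#' @param nb_dispersion Range of per-gene negative-binomial dispersions
#'   (default 0.05-0.3; driver-linked genes use the lower bound).
#' @param detection_limit Intensity floor below which a measurement is
#'   recorded as a non-detect, i.e. zero (default 1000).
#' @param coupling_strength Target within-SPF dam-level Spearman |rho| for
#'   driver-gene links (default 0.95).
#' @param n_discordant_pairs Linked pairs additionally given a GF-specific
#'   gene suppression that contradicts the within-SPF trend (default 20).
#' @param n_de_genes Genes with a planted GF-vs-SPF effect independent of
#'   any driver (default 200).
#' @param genes_per_module Differentially expressed genes are grouped
#'   into co-regulated modules of this size (default 20) sharing a
#'   dam-level latent, emulating co-expression programs.
#' @param gene_module_sd Log-scale SD of the shared module dam latent
#'   (default 0; positive values add co-expression covariance).
#' @param spf_fold Fold-excess of SPF over GF for non-driver spf_higher
#'   features (default 4).
#' @param fetus_noise_sd Log-scale SD of fetus-level metabolite noise
#'   (default 0.15).
#' @param library_size_sd Log-scale SD of per-sample library-size factors
#'   (default 0.25).
#' @param two_male_exception If TRUE, one dam per group contributes two
#'   male fetuses to the metabolome assay instead of one of each sex.
#' @param nondetect_as_na Encode non-detects as NA instead of 0.
#' @param seed Integer seed; all randomness flows from it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_dams_per_group = 6,
                       fetuses_per_dam_per_assay = 2,
                       tissues = c("intestine", "brain", "placenta"),
                       n_genes = 2000,
                       n_features = 500,
                       n_driver_features = 5,
                       genes_per_driver = 30,
                       n_gene_sets = 100,
                       gene_set_size_range = c(10, 80),
                       sets_per_driver = 8,
                       frac_gf_absent = 0.05,
                       frac_spf_higher = 0.15,
                       features_per_family = 12,
                       family_sd = 0,
                       litter_sd = 0.3,
                       sex_effect_genes = 50,
                       nb_dispersion = c(0.05, 0.3),
                       detection_limit = 1000,
                       coupling_strength = 0.95,
                       n_discordant_pairs = 20,
                       n_de_genes = 200,
                       genes_per_module = 20,
                       gene_module_sd = 0,
                       spf_fold = 4,
                       fetus_noise_sd = 0.15,
                       library_size_sd = 0.25,
                       two_male_exception = FALSE,
                       nondetect_as_na = FALSE,
                       seed = 1) {
  cfg <- list(n_dams_per_group = n_dams_per_group,
              fetuses_per_dam_per_assay = fetuses_per_dam_per_assay,
              tissues = as.character(tissues),
              n_genes = n_genes, n_features = n_features,
              n_driver_features = n_driver_features,
              genes_per_driver = genes_per_driver,
              n_gene_sets = n_gene_sets,
              gene_set_size_range = gene_set_size_range,
              sets_per_driver = sets_per_driver,
              frac_gf_absent = frac_gf_absent,
              frac_spf_higher = frac_spf_higher,
              features_per_family = features_per_family,
              family_sd = family_sd,
              litter_sd = litter_sd,
              sex_effect_genes = sex_effect_genes,
              nb_dispersion = nb_dispersion,
              detection_limit = detection_limit,
              coupling_strength = coupling_strength,
              n_discordant_pairs = n_discordant_pairs,
              n_de_genes = n_de_genes, genes_per_module = genes_per_module,
              gene_module_sd = gene_module_sd, spf_fold = spf_fold,
              fetus_noise_sd = fetus_noise_sd,
              library_size_sd = library_size_sd,
              two_male_exception = isTRUE(two_male_exception),
              nondetect_as_na = isTRUE(nondetect_as_na),
              seed = as.integer(seed))
  for (nm in c("n_dams_per_group", "fetuses_per_dam_per_assay", "n_genes",
               "n_features", "genes_per_driver", "n_gene_sets",
               "sets_per_driver", "features_per_family",
               "genes_per_module")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stopf("%s must be a positive integer", nm)
    }
    cfg[[nm]] <- as.integer(v)
  }
  for (nm in c("n_driver_features", "n_discordant_pairs", "n_de_genes",
               "sex_effect_genes")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v != round(v)) {
      stopf("%s must be a non-negative integer", nm)
    }
    cfg[[nm]] <- as.integer(v)
  }
  for (nm in c("frac_gf_absent", "frac_spf_higher")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stopf("%s must be in [0, 1]", nm)
  }
  if (cfg$coupling_strength <= 0 || cfg$coupling_strength > 1) {
    stopf("coupling_strength must be in (0, 1]")
  }
  if (cfg$litter_sd < 0) stopf("litter_sd must be non-negative")
  if (cfg$family_sd < 0) stopf("family_sd must be non-negative")
  if (cfg$gene_module_sd < 0) stopf("gene_module_sd must be non-negative")
  if (length(cfg$nb_dispersion) != 2 || any(cfg$nb_dispersion <= 0)) {
    stopf("nb_dispersion must be a pair of positive values")
  }
  if (length(cfg$gene_set_size_range) != 2 ||
      cfg$gene_set_size_range[1] < 1 ||
      cfg$gene_set_size_range[1] > cfg$gene_set_size_range[2]) {
    stopf("gene_set_size_range must be an increasing pair")
  }
  structure(cfg, class = "sim_config")
}

# Latent Pearson correlation whose expected Spearman (bivariate normal,
# n points) equals the requested target; classical Pearson-Spearman
# moment relation inverted numerically.
latent_r_for_spearman <- function(target, n) {
  if (target >= 1) return(1)
  es <- function(r) (6 / (pi * (n + 1))) * (asin(r) + (n - 2) * asin(r / 2))
  if (es(1 - 1e-12) <= target) return(1)
  stats::uniroot(function(r) es(r) - target, c(0, 1 - 1e-12))$root
}

# Shared sample layout: per tissue x assay x dam, fetuses with alternating
# sexes (optionally one dam per group contributing two males to the
# metabolome assay).
build_metadata <- function(cfg) {
  dams <- c(paste0("GF", seq_len(cfg$n_dams_per_group)),
            paste0("SPF", seq_len(cfg$n_dams_per_group)))
  groups <- rep(c("GF", "SPF"), each = cfg$n_dams_per_group)
  rows <- list()
  for (tissue in cfg$tissues) {
    for (assay in c("transcriptome", "metabolome")) {
      code <- if (assay == "transcriptome") "tx" else "mb"
      for (i in seq_along(dams)) {
        for (k in seq_len(cfg$fetuses_per_dam_per_assay)) {
          sex <- if (k %% 2 == 1) "M" else "F"
          if (cfg$two_male_exception && assay == "metabolome" &&
              dams[i] %in% c("GF1", "SPF1")) {
            sex <- "M"
          }
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = paste(dams[i], tissue, code, k, sep = "_"),
            dam_id = dams[i], group = groups[i], sex = sex,
            tissue = tissue, assay = assay,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  validate_metadata(do.call(rbind, rows))
}

simulate_study <- function(cfg, null_model) {
  if (cfg$n_dams_per_group < 3) {
    stopf("n_dams_per_group must be at least 3 (dam-level Spearman needs it)")
  }
  if (!null_model &&
      cfg$genes_per_driver * cfg$n_driver_features > cfg$n_genes) {
    stopf("genes_per_driver x n_driver_features exceeds n_genes")
  }
  set.seed(cfg$seed)
  n_spf <- cfg$n_dams_per_group
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  feat_ids <- sprintf("F%04d", seq_len(cfg$n_features))
  dams <- c(paste0("GF", seq_len(n_spf)), paste0("SPF", seq_len(n_spf)))
  dam_group <- stats::setNames(rep(c("GF", "SPF"), each = n_spf), dams)
  metadata <- build_metadata(cfg)

  # Gene-level parameters, shared across tissues
  baseline <- stats::rlnorm(cfg$n_genes, meanlog = log(200), sdlog = 1.5)
  dispersion <- stats::runif(cfg$n_genes, cfg$nb_dispersion[1],
                             cfg$nb_dispersion[2])
  feat_base <- stats::rlnorm(cfg$n_features, meanlog = log(1e5), sdlog = 1)

  if (cfg$frac_gf_absent + cfg$frac_spf_higher > 1) {
    stopf("frac_gf_absent + frac_spf_higher exceeds available features")
  }
  n_drv <- if (null_model) 0L else cfg$n_driver_features
  if (n_drv > cfg$n_features) {
    stopf("not enough features to host %d drivers", n_drv)
  }
  driver_ids <- if (n_drv) sample(feat_ids, n_drv) else character(0)

  # remaining features are grouped into compound families that share a
  # dam-level latent; differential status is assigned family-wise
  other_ids <- sample(setdiff(feat_ids, driver_ids))
  fam_of <- stats::setNames(rep(NA_integer_, cfg$n_features), feat_ids)
  fam_of[other_ids] <- (seq_along(other_ids) - 1) %/%
    cfg$features_per_family + 1L
  n_fam <- max(fam_of, na.rm = TRUE)

  n_drv_abs <- if (null_model || cfg$frac_gf_absent == 0) 0L
  else min(ceiling(n_drv / 2), n_drv)
  gf_absent_ids <- character(0)
  spf_higher_ids <- character(0)
  if (!null_model) {
    n_abs_target <- round(cfg$frac_gf_absent * cfg$n_features)
    n_high_target <- round(cfg$frac_spf_higher * cfg$n_features)
    fam_order <- sample(n_fam)
    k_abs <- min(n_fam, max(0, round((n_abs_target - n_drv_abs) /
                                       cfg$features_per_family)))
    k_high <- min(n_fam - k_abs,
                  max(0, round((n_high_target - (n_drv - n_drv_abs)) /
                                 cfg$features_per_family)))
    abs_fams <- fam_order[seq_len(k_abs)]
    high_fams <- fam_order[k_abs + seq_len(k_high)]
    gf_absent_ids <- sort(c(other_ids[fam_of[other_ids] %in% abs_fams],
                            driver_ids[seq_len(n_drv_abs)]))
    spf_higher_ids <- sort(c(other_ids[fam_of[other_ids] %in% high_fams],
                             driver_ids[seq_len(n_drv) > n_drv_abs]))
  }

  # Dam-level latent exposure: an evenly spaced dose gradient across SPF
  # dams (randomly assigned), GF dams pinned well below it.
  z <- matrix(0, length(dams), max(n_drv, 1),
              dimnames = list(dams, if (n_drv) driver_ids else "none"))
  if (n_drv > 0) {
    grid <- seq(-1.5, 1.5, length.out = n_spf)
    for (d in seq_len(n_drv)) {
      z[dam_group == "SPF", d] <- sample(grid)
      z[dam_group == "GF", d] <- -3
    }
  }

  # Driver -> gene links: disjoint gene blocks, random coupling sign;
  # discordant pairs are negative within SPF plus a GF-only suppression.
  linked <- NULL
  if (n_drv > 0) {
    link_genes <- sample(gene_ids, cfg$genes_per_driver * n_drv)
    linked <- data.frame(
      feature_id = rep(driver_ids, each = cfg$genes_per_driver),
      gene_id = link_genes,
      # dose-response couplings are mostly activating; a minority of
      # genes respond negatively (as translation-related genes did)
      slope = sample(c(-1, 1), cfg$genes_per_driver * n_drv,
                     replace = TRUE, prob = c(0.2, 0.8)),
      discordant = FALSE, stringsAsFactors = FALSE)
    n_disc <- min(cfg$n_discordant_pairs, nrow(linked))
    if (n_disc > 0) {
      idx <- sample(nrow(linked), n_disc)
      linked$discordant[idx] <- TRUE
      linked$slope[idx] <- -1
    }
    # linked genes must survive prefiltering and carry low count noise so
    # the dose-response is visible at the dam level
    gi <- match(linked$gene_id, gene_ids)
    baseline[gi] <- pmax(baseline[gi], 500)
    dispersion[gi] <- cfg$nb_dispersion[1]
  }

  de_ids <- character(0)
  de_lfc <- numeric(0)
  mod_of <- integer(0)
  n_mod <- 0L
  if (!null_model && cfg$n_de_genes > 0) {
    pool <- setdiff(gene_ids, if (is.null(linked)) NULL else linked$gene_id)
    de_ids <- sample(pool, min(cfg$n_de_genes, length(pool)))
    de_lfc <- sample(c(-1, 1), length(de_ids), TRUE) *
      stats::runif(length(de_ids), 1, 2.5)
    # co-regulated modules: DE genes share a dam-level expression latent
    mod_of <- stats::setNames((seq_along(de_ids) - 1) %/%
                                cfg$genes_per_module + 1L, de_ids)
    n_mod <- max(mod_of)
    # DE genes must be quantifiable for the association stage
    gi <- match(de_ids, gene_ids)
    baseline[gi] <- pmax(baseline[gi], 100)
  }
  sex_ids <- character(0)
  sex_lfc <- numeric(0)
  if (cfg$sex_effect_genes > 0) {
    sex_ids <- sample(gene_ids, min(cfg$sex_effect_genes, cfg$n_genes))
    sex_lfc <- sample(c(-1, 1), length(sex_ids), TRUE)
  }

  # coupling noise: latent Pearson chosen so dam-level Spearman
  # concentrates at coupling_strength
  r_latent <- latent_r_for_spearman(cfg$coupling_strength, n_spf)
  couple_noise_sd <- if (n_drv) sqrt(1 - r_latent^2) / r_latent *
    stats::sd(z[dam_group == "SPF", 1]) else 0

  counts_list <- list()
  intens_list <- list()
  for (tissue in cfg$tissues) {
    md_tx <- metadata[metadata$tissue == tissue &
                        metadata$assay == "transcriptome", ]
    md_mb <- metadata[metadata$tissue == tissue &
                        metadata$assay == "metabolome", ]

    # per-gene, per-dam litter random effect (tissue-specific biology)
    dam_re <- matrix(stats::rnorm(cfg$n_genes * length(dams), 0,
                                  cfg$litter_sd),
                     cfg$n_genes, length(dams), dimnames = list(NULL, dams))
    log_mu <- matrix(log(baseline), cfg$n_genes, nrow(md_tx)) +
      dam_re[, md_tx$dam_id]
    if (length(sex_ids)) {
      gi <- match(sex_ids, gene_ids)
      log_mu[gi, md_tx$sex == "M"] <- log_mu[gi, md_tx$sex == "M"] +
        log(2) * sex_lfc
    }
    if (length(de_ids)) {
      gi <- match(de_ids, gene_ids)
      log_mu[gi, md_tx$group == "GF"] <- log_mu[gi, md_tx$group == "GF"] +
        log(2) * de_lfc
      if (n_mod > 0 && cfg$gene_module_sd > 0) {
        mod_latent <- matrix(stats::rnorm(n_mod * length(dams), 0,
                                          cfg$gene_module_sd),
                             n_mod, length(dams),
                             dimnames = list(NULL, dams))
        log_mu[gi, ] <- log_mu[gi, ] +
          mod_latent[mod_of, md_tx$dam_id, drop = FALSE]
      }
    }
    if (!is.null(linked)) {
      for (p in seq_len(nrow(linked))) {
        gi <- match(linked$gene_id[p], gene_ids)
        d <- match(linked$feature_id[p], driver_ids)
        x_dam <- z[, d] + stats::rnorm(length(dams), 0, couple_noise_sd)
        if (linked$discordant[p]) {
          spf_cols <- md_tx$group == "SPF"
          log_mu[gi, spf_cols] <- log_mu[gi, spf_cols] +
            linked$slope[p] * x_dam[md_tx$dam_id[spf_cols]]
          log_mu[gi, !spf_cols] <- log_mu[gi, !spf_cols] - log(2) * 2.5
        } else {
          log_mu[gi, ] <- log_mu[gi, ] + linked$slope[p] *
            x_dam[md_tx$dam_id]
        }
      }
    }
    lib <- stats::rlnorm(nrow(md_tx), 0, cfg$library_size_sd)
    mu <- exp(log_mu) %*% diag(lib)
    cts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                 size = rep(1 / dispersion, ncol(mu))),
                  nrow(mu), ncol(mu),
                  dimnames = list(gene_ids, md_tx$sample_id))
    counts_list[[tissue]] <- cts

    # metabolome: dam latent exposure drives driver features; everything
    # else gets a per-feature litter effect plus fetus noise
    dam_me <- matrix(stats::rnorm(cfg$n_features * length(dams), 0,
                                  cfg$litter_sd),
                     cfg$n_features, length(dams),
                     dimnames = list(NULL, dams))
    fam_latent <- matrix(stats::rnorm(n_fam * length(dams), 0,
                                      cfg$family_sd),
                         n_fam, length(dams), dimnames = list(NULL, dams))
    fam_effect <- matrix(0, cfg$n_features, length(dams),
                         dimnames = list(NULL, dams))
    has_fam <- !is.na(fam_of)
    fam_effect[has_fam, ] <- fam_latent[fam_of[has_fam], , drop = FALSE]
    log_int <- matrix(log(feat_base), cfg$n_features, nrow(md_mb)) +
      dam_me[, md_mb$dam_id] + fam_effect[, md_mb$dam_id] +
      matrix(stats::rnorm(cfg$n_features * nrow(md_mb), 0,
                          cfg$fetus_noise_sd),
             cfg$n_features, nrow(md_mb))
    if (n_drv > 0) {
      for (d in seq_len(n_drv)) {
        fi <- match(driver_ids[d], feat_ids)
        # for drivers the dam effect IS the exposure
        log_int[fi, ] <- log(feat_base[fi]) + z[md_mb$dam_id, d] +
          stats::rnorm(nrow(md_mb), 0, cfg$fetus_noise_sd)
      }
    }
    if (length(spf_higher_ids)) {
      fi <- match(setdiff(spf_higher_ids, driver_ids), feat_ids)
      gf_cols <- md_mb$group == "GF"
      log_int[fi, gf_cols] <- log_int[fi, gf_cols] - log(cfg$spf_fold)
    }
    intens <- exp(log_int)
    if (length(gf_absent_ids)) {
      fi <- match(gf_absent_ids, feat_ids)
      intens[fi, md_mb$group == "GF"] <- 0
    }
    intens[intens < cfg$detection_limit] <- 0
    if (cfg$nondetect_as_na) intens[intens == 0] <- NA_real_
    dimnames(intens) <- list(feat_ids, md_mb$sample_id)
    intens_list[[tissue]] <- intens
  }

  counts <- omics_matrix(do.call(cbind, counts_list), "counts")
  intensities <- omics_matrix(do.call(cbind, intens_list), "intensities")

  # gene-set collection: one enriched set per driver plus background sets
  sets <- list()
  enriched_ids <- list()
  if (n_drv > 0) {
    # a specificity ladder per driver, like real ontologies: broad terms
    # covering most of the program down to small specific terms that only
    # near-complete gene recovery can light up
    core_frac <- seq(0.1, 0.9, length.out = cfg$sets_per_driver)
    for (d in seq_len(n_drv)) {
      members <- linked$gene_id[linked$feature_id == driver_ids[d]]
      ids_d <- character(cfg$sets_per_driver)
      for (v in seq_len(cfg$sets_per_driver)) {
        core <- sample(members, max(2, round(core_frac[v] *
                                               length(members))))
        filler <- sample(setdiff(gene_ids, core),
                         max(0, cfg$gene_set_size_range[1] -
                               length(core)) + 5)
        id <- sprintf("SET_DRV%02d_%02d", d, v)
        sets[[id]] <- unique(c(core, filler))
        ids_d[v] <- id
      }
      enriched_ids[[driver_ids[d]]] <- ids_d
    }
  }
  n_bg <- max(0, cfg$n_gene_sets - length(sets))
  for (b in seq_len(n_bg)) {
    sz <- sample(cfg$gene_set_size_range[1]:min(cfg$gene_set_size_range[2],
                                                cfg$n_genes), 1)
    sets[[sprintf("SET_BG%03d", b)]] <- sample(gene_ids, sz)
  }
  collection <- gene_set_collection(sets)

  truth <- structure(list(
    driver_feature_ids = as.character(driver_ids),
    gf_absent_feature_ids = gf_absent_ids,
    spf_higher_feature_ids = spf_higher_ids,
    linked_pairs = if (is.null(linked))
      data.frame(feature_id = character(0), gene_id = character(0),
                 slope = numeric(0), discordant = logical(0))
    else linked,
    enriched_set_ids = enriched_ids,
    discordant_pairs = if (is.null(linked))
      data.frame(feature_id = character(0), gene_id = character(0))
    else linked[linked$discordant, c("feature_id", "gene_id")],
    de_gene_ids = data.frame(gene_id = de_ids, log2_fold_change = de_lfc,
                             stringsAsFactors = FALSE),
    sex_effect_gene_ids = sex_ids,
    feature_families = data.frame(feature_id = feat_ids,
                                  family = unname(fam_of[feat_ids]),
                                  stringsAsFactors = FALSE),
    dam_latent_exposures = if (n_drv) z[, , drop = FALSE]
    else z[, 0, drop = FALSE]),
    class = "synthetic_truth")

  log_stage("simulate_study", null = null_model, seed = cfg$seed,
            genes = cfg$n_genes, features = cfg$n_features,
            samples = nrow(metadata), drivers = n_drv)
  list(counts = counts, intensities = intensities, metadata = metadata,
       gene_sets = collection, truth = truth)
}

#' Generate a synthetic GF/SPF twin-litter study
#'
#' Produces per-fetus gene counts (negative binomial: gene baseline x dam
#' random effect x sex effect x group effect x library size), per-fetus
#' metabolite intensities (log-normal with dam-level latent exposure shared
#' by both metabolome fetuses of a dam), sample metadata, a GMT gene-set
#' collection containing one enriched set per planted driver, and the
#' ground truth needed for recovery tests. The same seed gives identical
#' output.
#'
#' @param config A [sim_config()].
#' @return List with elements `counts`, `intensities`, `metadata`,
#'   `gene_sets`, `truth`.
#' @export
generate_synthetic_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  simulate_study(config, null_model = FALSE)
}

#' Generate a matched null study
#'
#' Identical generative model with all group effects, drivers, couplings
#' and planted metabolite differences set to zero; the truth lists are
#' empty. Used as the type-I-error harness for the screening stages.
#'
#' @param config A [sim_config()].
#' @return Same shape as [generate_synthetic_study()].
#' @export
generate_null_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  simulate_study(config, null_model = TRUE)
}

#' Write a synthetic study to pipeline input files
#'
#' Emits counts.tsv, intensities.tsv, metadata.tsv, gene_sets.gmt and
#' truth.json under `dir`.
#'
#' @param study Output of [generate_synthetic_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(study$counts, file.path(dir, "counts.tsv"))
  write_matrix(study$intensities, file.path(dir, "intensities.tsv"))
  write_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  tr <- study$truth
  tr$dam_latent_exposures <- as.data.frame(tr$dam_latent_exposures)
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
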