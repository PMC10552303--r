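make_counts <- function(values, n_samples = ncol(values)) {
  omics_matrix(values, "counts")
}

test_that("prefilter keeps exactly the genes meeting the read/sample quorum", {
  m <- matrix(0L, 3, 24, dimnames = list(c("at_boundary", "below", "rich"),
                                         paste0("s", 1:24)))
  m["at_boundary", 1:12] <- 5L        # 5 reads in exactly 12 samples
  m["below", ] <- 4L                  # never reaches 5 reads
  m["rich", ] <- 50L
  out <- suppressMessages(prefilter_genes(make_counts(m), 5, 12))
  expect_identical(rownames(out), c("at_boundary", "rich"))

  expect_error(suppressMessages(prefilter_genes(make_counts(m), 5, 25)),
               "exceeds")
})

test_that("prefilter agrees with a brute-force double loop on random data", {
  set.seed(11)
  m <- matrix(rnbinom(500 * 24, mu = 8, size = 0.5), 500, 24,
              dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:24)))
  out <- suppressMessages(prefilter_genes(make_counts(m), 5, 12))
  keep <- character(0)
  for (g in rownames(m)) {
    n_ok <- 0
    for (s in colnames(m)) if (m[g, s] >= 5) n_ok <- n_ok + 1
    if (n_ok >= 12) keep <- c(keep, g)
  }
  expect_identical(rownames(out), keep)
})

test_that("prefilter is monotone in both thresholds", {
  set.seed(12)
  m <- matrix(rnbinom(200 * 24, mu = 6, size = 0.7), 200, 24,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:24)))
  base <- rownames(suppressMessages(prefilter_genes(make_counts(m), 5, 12)))
  for (args in list(c(6, 12), c(5, 14), c(8, 20))) {
    stricter <- rownames(suppressMessages(
      prefilter_genes(make_counts(m), args[1], args[2])))
    expect_true(all(stricter %in% base))
  }
})

test_that("median-of-ratios size factors behave under scaling", {
  m <- matrix(c(10, 20, 30, 40), 4, 1)[, c(1, 1)]
  dimnames(m) <- list(paste0("g", 1:4), c("a", "b"))
  n1 <- suppressMessages(normalize_counts(make_counts(m)))
  expect_equal(unname(attr(n1, "size_factors")), c(1, 1))
  expect_equal(unclass(n1), m, ignore_attr = TRUE)

  m2 <- cbind(a = c(10, 20, 30, 40), b = c(20, 40, 60, 80))
  rownames(m2) <- paste0("g", 1:4)
  n2 <- suppressMessages(normalize_counts(make_counts(m2)))
  sf <- attr(n2, "size_factors")
  expect_equal(unname(sf["b"] / sf["a"]), 2)
  expect_equal(unclass(n2)[, "a"], unclass(n2)[, "b"])

  zeros <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
                  dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(suppressMessages(normalize_counts(make_counts(zeros))),
               "pseudo-reference")
})

test_that("size factors recover known library-size multipliers within 5%", {
  set.seed(13)
  base <- rlnorm(400, log(300), 1)
  mult <- c(0.5, 1, 2)
  m <- sapply(rep(mult, each = 4), function(f) rpois(400, base * f))
  dimnames(m) <- list(paste0("g", 1:400), paste0("s", 1:12))
  sf <- attr(suppressMessages(normalize_counts(make_counts(m))),
             "size_factors")
  sf_rel <- sf / sf[5]                       # normalize to a multiplier-1 sample
  expected <- rep(mult, each = 4)
  expect_true(all(abs(sf_rel - expected) / expected < 0.05))
})

test_that("median-of-ratios matches the DESeq2 reference implementation", {
  set.seed(14)
  m <- matrix(rnbinom(300 * 10, mu = 50, size = 2) + 1L, 300, 10,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:10)))
  sf <- attr(suppressMessages(normalize_counts(make_counts(m))),
             "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("DE stand-in recovers planted fold changes and flags degenerates", {
  set.seed(15)
  n <- 12
  md <- data.frame(sample_id = paste0("s", 1:(2 * n)),
                   dam_id = rep(paste0("d", 1:12), each = 2)[1:(2 * n)],
                   group = rep(c("GF", "SPF"), each = n),
                   sex = rep(c("M", "F"), n), tissue = "gut",
                   assay = "transcriptome")
  hit_rates <- vapply(1:5, function(s) {
    set.seed(100 + s)
    base <- rlnorm(200, log(200), 0.5)
    m <- sapply(seq_len(2 * n), function(i) {
      mu <- base
      mu[1:50] <- mu[1:50] * ifelse(i <= n, 4, 1)   # planted log2FC = 2 in GF
      rnbinom(200, mu = mu, size = 1 / 0.02)
    })
    dimnames(m) <- list(paste0("g", 1:200), md$sample_id)
    de <- suppressMessages(de_standin(
      omics_matrix(m + 0, "intensities"), md))
    mean(de$p_adj[1:50] < 0.05)
  }, numeric(1))
  expect_true(all(hit_rates >= 0.95))

  m <- matrix(5, 10, 2 * n,
              dimnames = list(paste0("g", 1:10), md$sample_id))
  m[1, ] <- rpois(2 * n, 50) + 1
  de <- suppressMessages(de_standin(omics_matrix(m, "intensities"), md))
  expect_true(all(de$p[2:10] == 1))
  expect_true(all(de$zero_variance[2:10]))
  expect_identical(unique(de$source), "standin")

  bad_md <- md
  bad_md$group <- c("GF", rep("SPF", 2 * n - 1))
  expect_error(suppressMessages(de_standin(
    omics_matrix(m, "intensities"), bad_md)), "fewer than 2")
})

test_that("metabolite classification follows the detection and test rules", {
  md <- data.frame(sample_id = paste0("s", 1:24),
                   dam_id = rep(paste0("d", 1:12), each = 2),
                   group = rep(c("GF", "SPF"), each = 12),
                   sex = "M", tissue = "gut", assay = "metabolome")
  set.seed(16)
  m <- rbind(absent = c(rep(0, 12), rlnorm(12, 10, 0.2)),
             flat = rep(1000, 24),
             up = c(rlnorm(12, 8, 0.2), rlnorm(12, 11, 0.2)))
  colnames(m) <- md$sample_id
  st <- suppressMessages(classify_metabolites(
    omics_matrix(m, "intensities"), md, alpha = 0.05))
  expect_identical(st$status[st$feature_id == "absent"], "gf_absent")
  expect_identical(st$status[st$feature_id == "flat"], "unchanged")
  expect_identical(st$status[st$feature_id == "up"], "spf_higher")
  expect_equal(st$n_detect_gf[st$feature_id == "absent"], 0)

  expect_error(suppressMessages(classify_metabolites(
    omics_matrix(m[, 1:4], "intensities"), md[1:4, ])), "3 samples")
})

test_that("a planted 4-fold SPF excess is detected in at least 95% of features", {
  md <- data.frame(sample_id = paste0("s", 1:24),
                   dam_id = rep(paste0("d", 1:12), each = 2),
                   group = rep(c("GF", "SPF"), each = 12),
                   sex = "M", tissue = "gut", assay = "metabolome")
  rates <- vapply(1:5, function(s) {
    set.seed(200 + s)
    # CV 30% on the natural scale ~ sdlog 0.294
    m <- t(sapply(1:100, function(f) {
      mu <- rep(c(1e4, 4e4), each = 12)
      rlnorm(24, log(mu), sqrt(log(1 + 0.3^2)))
    }))
    dimnames(m) <- list(paste0("f", 1:100), md$sample_id)
    st <- suppressMessages(classify_metabolites(
      omics_matrix(m, "intensities"), md, alpha = 0.05))
    mean(st$status == "spf_higher")
  }, numeric(1))
  expect_true(all(rates >= 0.95))
})

test_that("relabeling GF and SPF mirrors the direction and keeps |statistics|", {
  md <- data.frame(sample_id = paste0("s", 1:24),
                   dam_id = rep(paste0("d", 1:12), each = 2),
                   group = rep(c("GF", "SPF"), each = 12),
                   sex = "M", tissue = "gut", assay = "metabolome")
  set.seed(17)
  m <- matrix(rlnorm(50 * 24, 9, 0.6), 50, 24,
              dimnames = list(paste0("f", 1:50), md$sample_id))
  m[1:10, 13:24] <- m[1:10, 13:24] * 5
  a <- suppressMessages(classify_metabolites(
    omics_matrix(m, "intensities"), md))
  md_flip <- md
  md_flip$group <- ifelse(md$group == "GF", "SPF", "GF")
  b <- suppressMessages(classify_metabolites(
    omics_matrix(m, "intensities"), md_flip))
  expect_equal(a$p, b$p)
  expect_equal(a$direction, -b$direction)
  expect_false(any(b$status[a$status == "spf_higher"] == "spf_higher"))
})

test_that("litter averaging means fetuses per dam and commutes with subsetting", {
  md <- data.frame(sample_id = c("a1", "a2", "b1"),
                   dam_id = c("dA", "dA", "dB"),
                   group = c("SPF", "SPF", "GF"), sex = c("M", "F", "M"),
                   tissue = "gut", assay = "metabolome")
  m <- matrix(c(2, 4, 7,
                10, 30, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("f1", "f2"), md$sample_id))
  lit <- suppressMessages(average_litters(m, md))
  expect_equal(lit["f1", "dA"], 3)
  expect_equal(lit["f2", "dA"], 20)
  expect_equal(lit["f1", "dB"], 7)
  expect_equal(unname(attr(lit, "n_fetuses")["dB"]), 1L)

  sub <- suppressMessages(average_litters(m["f2", , drop = FALSE], md))
  expect_equal(sub["f2", ], lit["f2", ])

  st <- suppressMessages(generate_synthetic_study(small_config(seed = 8)))
  md_mb <- st$metadata[st$metadata$assay == "metabolome", ]
  lit2 <- suppressMessages(average_litters(st$intensities, md_mb))
  expect_equal(ncol(lit2), 12)
})

test_that("twin similarity statistic matches the hand-computed toy value", {
  # 4 dams x 2 identical twins; dams 1,3 share an increasing profile and
  # dams 2,4 its reversal: within-mean 1, between-mean -1/3, statistic 4/3
  inc <- c(1, 2, 3, 4, 5)
  md <- data.frame(sample_id = paste0("s", 1:8),
                   dam_id = rep(paste0("d", 1:4), each = 2),
                   group = rep(c("GF", "SPF"), each = 4),
                   sex = "M", tissue = "gut", assay = "transcriptome")
  m <- cbind(inc, inc, rev(inc), rev(inc), inc, inc, rev(inc), rev(inc))
  dimnames(m) <- list(paste0("f", 1:5), md$sample_id)
  res <- suppressMessages(suppressWarnings(
    twin_similarity_test(m, md, n_perm = 99, seed = 1)))
  expect_equal(res$statistic, 4 / 3)
  expect_equal(res$within_rho_range, c(1, 1))

  # maximal separation: identical twins, independent dams (6 dams so the
  # chance of a permutation reproducing the litter partition is negligible)
  set.seed(18)
  md6 <- data.frame(sample_id = paste0("t", 1:12),
                    dam_id = rep(paste0("d", 1:6), each = 2),
                    group = rep(c("GF", "SPF"), each = 6),
                    sex = "M", tissue = "gut", assay = "transcriptome")
  m2 <- matrix(rnorm(40 * 6), 40, 6)[, rep(1:6, each = 2)]
  dimnames(m2) <- list(paste0("f", 1:40), md6$sample_id)
  res2 <- suppressMessages(twin_similarity_test(m2, md6, n_perm = 199,
                                                seed = 2))
  expect_equal(res2$within_rho_range, c(1, 1))
  expect_equal(res2$p_perm, 1 / 200)

  # identical profiles everywhere: no signal
  m3 <- matrix(rep(inc, 8), 5, 8,
               dimnames = list(paste0("f", 1:5), md$sample_id))
  res3 <- suppressMessages(suppressWarnings(
    twin_similarity_test(m3, md, n_perm = 99, seed = 3)))
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_perm, 1)

  expect_warning(twin_similarity_test(m2, md6, n_perm = 50, seed = 1),
                 "small")
})
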