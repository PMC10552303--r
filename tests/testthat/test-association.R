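litter_mat <- function(values, ids, dams = paste0("d", seq_len(ncol(values)))) {
  dimnames(values) <- list(ids, dams)
  values
}

test_that("direct screen keeps monotone pairs and honors the sign switch", {
  fm <- litter_mat(rbind(1:6), "f1")
  gm <- litter_mat(rbind(1:6, 6:1), c("g_up", "g_down"))
  res <- suppressMessages(spearman_screen(fm, gm, 0.9, use_absolute = TRUE))
  expect_setequal(res$gene_id, c("g_up", "g_down"))
  expect_equal(res$rho[res$gene_id == "g_up"], 1)
  expect_equal(res$rho[res$gene_id == "g_down"], -1)

  signed <- suppressMessages(spearman_screen(fm, gm, 0.9,
                                             use_absolute = FALSE))
  expect_identical(signed$gene_id, "g_up")

  expect_error(spearman_screen(fm, litter_mat(rbind(1:6), "g",
                                              paste0("x", 1:6))),
               "same dams")
  expect_error(spearman_screen(fm[, 1:3, drop = FALSE],
                               gm[, 1:3, drop = FALSE]), "at least 4")
})

test_that("screen output matches the naive double-loop oracle pair-for-pair", {
  set.seed(21)
  fm <- litter_mat(matrix(rnorm(50 * 6), 50, 6), sprintf("f%02d", 1:50))
  gm <- litter_mat(matrix(rnorm(80 * 6), 80, 6), sprintf("g%02d", 1:80))
  # plant some strong pairs so the comparison is not vacuous
  for (i in 1:10) gm[i, ] <- fm[i, ] * (2 - (i %% 2) * 4) + rnorm(6, 0, 0.05)
  for (thr in c(0.6, 0.9)) {
    mine <- suppressMessages(spearman_screen(fm, gm, thr, TRUE))
    oracle <- naive_screen(fm, gm, thr, TRUE)
    expect_equal(nrow(mine), nrow(oracle))
    expect_identical(paste(mine$feature_id, mine$gene_id),
                     paste(oracle$feature_id, oracle$gene_id))
    expect_equal(mine$rho, oracle$rho, tolerance = 1e-12)
  }
})

test_that("Spearman screening is invariant to monotone transforms and symmetric", {
  set.seed(22)
  for (i in 1:10) {
    a <- rnorm(6)
    b <- rnorm(6)
    r0 <- naive_spearman(a, b)
    expect_equal(naive_spearman(exp(a), b), r0)
    expect_equal(naive_spearman(a, b^3 + 2 * b), r0)
    expect_equal(naive_spearman(b, a), r0)
    fm <- litter_mat(rbind(a), "f1")
    gm <- litter_mat(rbind(b), "g1")
    mine <- suppressMessages(spearman_screen(litter_mat(rbind(exp(a)), "f1"),
                                             gm, 0, TRUE))
    expect_equal(mine$rho[1], r0)
  }
})

test_that("constant profiles are excluded from the screen, not correlated", {
  fm <- litter_mat(rbind(rep(1, 6), 1:6), c("flat", "ok"))
  gm <- litter_mat(rbind(1:6), "g1")
  res <- suppressMessages(spearman_screen(fm, gm, 0.5, TRUE))
  expect_identical(res$feature_id, "ok")
})

test_that("complete-linkage heights on 1 - Spearman match hand computation", {
  # identical items merge at 0; perfectly anticorrelated at 2
  two <- litter_mat(rbind(1:6, 1:6), c("a", "b"))
  cl <- suppressMessages(hierarchical_clusters(two, c(1, 2)))
  expect_equal(attr(cl, "hclust")$height, 0)

  anti <- litter_mat(rbind(1:6, 6:1), c("a", "b"))
  cl2 <- suppressMessages(hierarchical_clusters(anti, c(1, 2)))
  expect_equal(attr(cl2, "hclust")$height, 2)

  # a,b nearly identical (one adjacent rank swap: rho = 1 - 6*2/210),
  # c unrelated by construction; complete linkage merges a,b first
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(1, 2, 3, 4, 6, 5)
  cc <- c(4, 6, 2, 5, 1, 3)
  rho_ab <- 1 - 6 * 2 / (6 * 35)
  rho_ac <- naive_spearman(a, cc)
  rho_bc <- naive_spearman(b, cc)
  three <- litter_mat(rbind(a, b, cc), c("a", "b", "c"))
  cl3 <- suppressMessages(hierarchical_clusters(three, c(1, 3)))
  h <- attr(cl3, "hclust")$height
  expect_equal(h[1], 1 - rho_ab)
  expect_equal(h[2], max(1 - rho_ac, 1 - rho_bc))
})

test_that("the tree cut lands the mean cluster size in the target range", {
  set.seed(23)
  m <- litter_mat(matrix(rnorm(60 * 6), 60, 6), sprintf("i%02d", 1:60))
  cl <- suppressMessages(hierarchical_clusters(m, c(7, 15)))
  expect_gte(attr(cl, "mean_size"), 7)
  expect_lte(attr(cl, "mean_size"), 15)
  expect_true(all(table(cl$cluster) >= 1))
  # partition: every item exactly one label
  expect_identical(sort(cl$item_id), sort(rownames(m)))
  expect_false(anyNA(cl$cluster))
})

test_that("cluster links require coherent member correlations", {
  inc <- 1:6 + 0
  gm <- litter_mat(rbind(inc, inc + 0.1, inc * 2), paste0("g", 1:3))
  fm <- litter_mat(rbind(inc, inc + 5), paste0("f", 1:2))
  gcl <- data.frame(item_id = paste0("g", 1:3), cluster = 1L)
  fcl <- data.frame(item_id = paste0("f", 1:2), cluster = 1L)
  links <- suppressMessages(link_clusters(gcl, fcl, gm, fm, 0.7))
  expect_equal(nrow(links), 1)
  expect_equal(links$mean_rho, 1)

  # independent noise clusters never reach the 0.7 link threshold
  worst <- vapply(1:20, function(s) {
    set.seed(300 + s)
    gm2 <- litter_mat(matrix(rnorm(18), 3, 6), paste0("g", 1:3))
    fm2 <- litter_mat(matrix(rnorm(18), 3, 6), paste0("f", 1:3))
    fcl2 <- data.frame(item_id = paste0("f", 1:3), cluster = 1L)
    l <- suppressMessages(link_clusters(gcl, fcl2, gm2, fm2, -2))
    l$mean_rho[1]
  }, numeric(1))
  expect_lt(max(worst), 0.5)

  # threshold monotonicity
  set.seed(24)
  gm3 <- litter_mat(matrix(rnorm(60), 10, 6), paste0("g", 1:10))
  fm3 <- litter_mat(matrix(rnorm(36), 6, 6), paste0("f", 1:6))
  gcl3 <- data.frame(item_id = paste0("g", 1:10),
                     cluster = rep(1:5, each = 2))
  fcl3 <- data.frame(item_id = paste0("f", 1:6),
                     cluster = rep(1:3, each = 2))
  l07 <- suppressMessages(link_clusters(gcl3, fcl3, gm3, fm3, 0.7))
  l06 <- suppressMessages(link_clusters(gcl3, fcl3, gm3, fm3, 0.6))
  expect_true(all(paste(l07$gene_cluster, l07$feature_cluster) %in%
                    paste(l06$gene_cluster, l06$feature_cluster)))
})

test_that("plaid rejects structureless input and refuses bad matrices", {
  cm <- matrix(0.4, 12, 12,
               dimnames = list(paste0("r", 1:12), paste0("c", 1:12)))
  expect_length(suppressMessages(plaid_biclustering(cm, seed = 1)), 0)

  expect_error(plaid_biclustering(matrix(2, 3, 3)), "\\[0, 1\\]")
  expect_error(plaid_biclustering(matrix(0.5, 1, 5)), "at least 2")
})

test_that("plaid recovers a planted block and its layers reduce the residual", {
  for (s in 1:3) {
    set.seed(400 + s)
    X <- matrix(runif(100 * 100, 0, 0.2), 100, 100,
                dimnames = list(sprintf("r%03d", 1:100),
                                sprintf("c%03d", 1:100)))
    rows <- sprintf("r%03d", 1:15)
    cols <- sprintf("c%03d", 1:20)
    X[rows, cols] <- X[rows, cols] + 0.6
    layers <- suppressMessages(plaid_biclustering(X, seed = s))
    expect_gte(length(layers), 1)
    expect_gte(jaccard(layers[[1]]$row_ids, rows), 0.9)
    expect_gte(jaccard(layers[[1]]$col_ids, cols), 0.9)
    expect_gt(layers[[1]]$mean_internal_corr, 0.5)

    # residual sum of squares is non-increasing as layers are applied
    Z <- X - mean(X)
    rss <- sum(Z^2)
    for (b in layers) {
      Z[b$row_ids, b$col_ids] <- Z[b$row_ids, b$col_ids] - b$layer_mean
      expect_lte(sum(Z^2), rss + 1e-9)
      rss <- sum(Z^2)
    }
  }
})

test_that("plaid on the transpose recovers the transposed block", {
  set.seed(41)
  X <- matrix(runif(80 * 60, 0, 0.2), 80, 60,
              dimnames = list(sprintf("r%02d", 1:80), sprintf("c%02d", 1:60)))
  rows <- sprintf("r%02d", 1:12)
  cols <- sprintf("c%02d", 1:15)
  X[rows, cols] <- X[rows, cols] + 0.6
  a <- suppressMessages(plaid_biclustering(X, seed = 5))
  b <- suppressMessages(plaid_biclustering(t(X), seed = 5))
  expect_gte(length(a), 1)
  expect_gte(length(b), 1)
  expect_gte(jaccard(a[[1]]$row_ids, b[[1]]$col_ids), 0.9)
  expect_gte(jaccard(a[[1]]$col_ids, b[[1]]$row_ids), 0.9)
})

test_that("top-bicluster selection ranks by internal correlation with tie rules", {
  mk <- function(corr, nr = 2, nc = 2, tag = "r") {
    list(row_ids = paste0(tag, seq_len(nr)), col_ids = paste0("c", seq_len(nc)),
         layer_mean = 0.5, background = 0.1, importance = 1,
         mean_internal_corr = corr, accepted = TRUE)
  }
  one <- list(mk(0.5))
  expect_identical(select_top_biclusters(one), one)

  four <- list(mk(0.9), mk(0.5), mk(0.4), mk(0.2))
  kept <- select_top_biclusters(four)
  expect_length(kept, 2)
  expect_equal(vapply(kept, `[[`, numeric(1), "mean_internal_corr"),
               c(0.9, 0.5))

  tied <- list(mk(0.5, nr = 2, tag = "b"), mk(0.5, nr = 3, tag = "a"))
  kept2 <- select_top_biclusters(tied, n_top = 2)
  expect_identical(kept2[[1]]$row_ids, paste0("a", 1:3))  # larger area first

  expect_length(select_top_biclusters(list()), 0)
})

test_that("dependency labels implement the extrapolation-contradiction rule", {
  pairs <- data.frame(feature_id = c("f1", "f1", "f2", "f3"),
                      gene_id = c("g1", "g2", "g3", "g4"),
                      rho = c(-0.95, -0.95, 0.95, NA))
  gm <- data.frame(gene_id = paste0("g", 1:4),
                   mean_gf = c(5, 20, 5, 1),
                   mean_spf = c(10, 10, 10, 1))
  lab <- suppressMessages(classify_dependency(pairs, gm))
  expect_equal(nrow(lab), 3)                      # NA rho excluded
  # negative SPF correlation but lower GF expression: discordant
  expect_identical(lab$label[lab$gene_id == "g1"], "nonlinear_discordant")
  # negative correlation and higher GF expression: the linear expectation
  expect_identical(lab$label[lab$gene_id == "g2"], "linear_consistent")
  # positive correlation, lower GF expression: consistent
  expect_identical(lab$label[lab$gene_id == "g3"], "linear_consistent")

  zero <- suppressMessages(classify_dependency(
    data.frame(feature_id = "f", gene_id = "g1", rho = 0.9),
    data.frame(gene_id = "g1", mean_gf = 3, mean_spf = 3)))
  expect_identical(zero$label, "linear_consistent")
  expect_true(zero$zero_effect)
})
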