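# Best layer over several seeded fits. Each fit grows a layer from the
# row holding one of the largest-magnitude residual cells, which keeps
# layers anchored to coherent blocks instead of drifting into large
# diluted unions; the same schedule is applied to the permuted copies so
# the acceptance comparison is fair.
best_plaid_layer <- function(Z, iter_startup, iter_layer, row_release,
                             col_release, n_restarts) {
  nr <- nrow(Z)
  top_cells <- order(abs(Z), decreasing = TRUE)[
    seq_len(min(length(Z), 10L * n_restarts))]
  seed_rows <- unique((top_cells - 1L) %% nr + 1L)
  seed_rows <- seed_rows[seq_len(min(length(seed_rows), n_restarts))]
  best <- NULL
  for (r in seed_rows) {
    f <- fit_plaid_layer(Z, r, iter_startup, iter_layer, row_release,
                         col_release)
    if (is.null(best) || f$importance > best$importance) best <- f
  }
  best %||% list(rows = logical(nr), cols = logical(ncol(Z)), mu = 0,
                 importance = 0)
}

# Null copy for layer acceptance: entries shuffled within every row, then
# within every column, destroying any row-column association while
# preserving the marginal value distribution.
shuffle_residual <- function(Z) {
  Zp <- t(apply(Z, 1, sample))
  apply(Zp, 2, sample)
}

# Fit one plaid layer with a constant layer mean on a residual matrix,
# grown from a seed row: the initial columns are those where the seed
# row's residual reaches at least three quarters of its extreme value
# (with the extreme's sign). Alternating updates: the layer mean is the mean
# residual over current members; a row (column) is a member iff adding it
# reduces the squared residual, i.e. sign(mu) * mean(residual over member
# columns) > |mu|/2. The release thresholds tighten that criterion to
# |mu|(1+release)/2 in a final pruning pass. Returns memberships, layer
# mean and importance (sum over member cells of the squared fitted
# effect).
fit_plaid_layer <- function(Z, seed_row, iter_startup, iter_layer,
                            row_release, col_release) {
  nr <- nrow(Z); nc <- ncol(Z)
  dead <- list(rows = logical(nr), cols = logical(nc), mu = 0,
               importance = 0)
  zr <- Z[seed_row, ]
  s0 <- zr[which.max(abs(zr))]
  if (s0 == 0) return(dead)
  s0 <- sign(s0)
  cols <- s0 * zr > 0.75 * max(s0 * zr)
  rows <- seq_len(nr) == seed_row
  for (it in seq_len(iter_startup + iter_layer)) {
    if (!any(rows) || !any(cols)) return(dead)
    mu <- mean(Z[rows, cols, drop = FALSE])
    if (mu == 0) return(dead)
    s <- sign(mu)
    # membership must beat the residual-reduction bound |mu|/2 tightened
    # by the release thresholds, so layers converge on their coherent
    # core instead of accreting weakly attached members
    r_thr <- abs(mu) / 2 * (1 + row_release)
    c_thr <- abs(mu) / 2 * (1 + col_release)
    row_means <- rowMeans(Z[, cols, drop = FALSE])
    new_rows <- s * row_means > r_thr
    if (!any(new_rows)) return(dead)
    col_means <- colMeans(Z[new_rows, , drop = FALSE])
    new_cols <- s * col_means > c_thr
    if (identical(new_rows, rows) && identical(new_cols, cols) &&
        it > iter_startup) {
      rows <- new_rows; cols <- new_cols
      break
    }
    rows <- new_rows; cols <- new_cols
  }
  if (!any(rows) || !any(cols)) return(dead)
  # release pruning, iterated to a fixpoint: members must carry at least
  # (1+release)/2 of the layer mean. As weakly attached rows/columns drop
  # out the layer mean rises, tightening the criterion until the layer
  # stabilizes on its coherent core.
  for (it in seq_len(iter_layer)) {
    mu <- mean(Z[rows, cols, drop = FALSE])
    if (mu == 0) return(dead)
    s <- sign(mu)
    new_rows <- rows & (s * rowMeans(Z[, cols, drop = FALSE]) >=
                          abs(mu) * (1 + row_release) / 2)
    if (!any(new_rows)) break
    new_cols <- cols & (s * colMeans(Z[new_rows, , drop = FALSE]) >=
                          abs(mu) * (1 + col_release) / 2)
    if (!any(new_cols)) break
    stable <- identical(new_rows, rows) && identical(new_cols, cols)
    rows <- new_rows
    cols <- new_cols
    if (stable) break
  }
  if (!any(rows) || !any(cols)) return(dead)
  mu <- mean(Z[rows, cols, drop = FALSE])
  list(rows = rows, cols = cols, mu = mu,
       importance = sum(rows) * sum(cols) * mu^2)
}

#' Plaid-model biclustering of an absolute-correlation matrix
#'
#' Fits a plaid model with a background mean and per-layer constant means
#' (no row/column effects) to a features x genes matrix of |Spearman rho|
#' computed on SPF dam means. Layers are fitted iteratively on the
#' residual matrix; each candidate layer is accepted only if its
#' importance exceeds the maximum importance obtained on `n_shuffles`
#' copies of the residual whose entries are independently permuted within
#' rows and then within columns (destroying row-column association);
#' fitting stops at the first rejection or at `max_layers`. Each fit
#' takes the best of up to `n_restarts` seeded growths (anchored at the
#' rows holding the largest-magnitude residual cells), with the same
#' schedule applied to the permuted copies.
#'
#' @param corr_abs Numeric matrix with entries in `[0, 1]`, at least 2x2.
#' @param max_layers Layer budget (default 10).
#' @param row_release,col_release Release thresholds in `[0, 1]`
#'   (default 0.7).
#' @param n_shuffles Permuted copies per acceptance test (default 3).
#' @param iter_startup,iter_layer Iteration counts (defaults 5 and 10).
#' @param n_restarts Seeded growths per layer fit (default 10).
#' @param seed Integer seed for the permutation shuffles.
#' @return List of accepted biclusters, each with row_ids, col_ids,
#'   layer_mean, background, importance, mean_internal_corr, accepted;
#'   attribute `background` holds the fitted background mean.
#' @export
plaid_biclustering <- function(corr_abs, max_layers = 10,
                               row_release = 0.7, col_release = 0.7,
                               n_shuffles = 3, iter_startup = 5,
                               iter_layer = 10, n_restarts = 10,
                               seed = 1) {
  if (!is.matrix(corr_abs) || nrow(corr_abs) < 2 || ncol(corr_abs) < 2) {
    stopf("corr_abs must be a matrix with at least 2 rows and 2 columns")
  }
  if (anyNA(corr_abs) || any(corr_abs < 0 | corr_abs > 1)) {
    stopf("corr_abs entries must lie in [0, 1]")
  }
  set.seed(seed)
  mu0 <- mean(corr_abs)
  Z <- corr_abs - mu0
  layers <- list()
  for (k in seq_len(max_layers)) {
    cand <- best_plaid_layer(Z, iter_startup, iter_layer, row_release,
                             col_release, n_restarts)
    perm_imp <- vapply(seq_len(n_shuffles), function(s) {
      Zp <- shuffle_residual(Z)
      best_plaid_layer(Zp, iter_startup, iter_layer, row_release,
                       col_release, n_restarts)$importance
    }, numeric(1))
    if (!(cand$importance > max(perm_imp))) break
    row_ids <- rownames(corr_abs)[cand$rows] %||%
      as.character(which(cand$rows))
    col_ids <- colnames(corr_abs)[cand$cols] %||%
      as.character(which(cand$cols))
    layers[[k]] <- list(
      row_ids = row_ids, col_ids = col_ids,
      layer_mean = cand$mu, background = mu0,
      importance = cand$importance,
      mean_internal_corr = mean(corr_abs[cand$rows, cand$cols,
                                         drop = FALSE]),
      accepted = TRUE)
    Z[cand$rows, cand$cols] <- Z[cand$rows, cand$cols] - cand$mu
  }
  log_stage("plaid_biclustering", n_layers = length(layers),
            background = signif(mu0, 4))
  attr(layers, "background") <- mu0
  layers
}

#' Select the strongest biclusters
#'
#' Sorts accepted biclusters by mean internal correlation (descending)
#' and keeps the top half (minimum one), or `n_top` when given. Ties are
#' broken by larger area (rows x cols), then by lexicographic first row
#' id.
#'
#' @param biclusters Output of [plaid_biclustering()].
#' @param n_top Optional explicit number to keep.
#' @return The selected sublist, strongest first.
#' @export
select_top_biclusters <- function(biclusters, n_top = NULL) {
  if (!length(biclusters)) return(biclusters)
  corr <- vapply(biclusters, `[[`, numeric(1), "mean_internal_corr")
  area <- vapply(biclusters, function(b)
    length(b$row_ids) * length(b$col_ids), numeric(1))
  first_row <- vapply(biclusters, function(b) min(b$row_ids), character(1))
  ord <- order(-corr, -area, first_row)
  keep <- if (is.null(n_top)) max(1L, ceiling(length(biclusters) / 2))
  else min(n_top, length(biclusters))
  biclusters[ord][seq_len(keep)]
}
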