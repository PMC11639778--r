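#' The 90-configuration kNN parameter grid
#'
#' Enumerates the full grid of 3 distances x 10 k values x 3 weight schemes
#' in a fixed deterministic order: distance-major (cityblock, euclidean,
#' cosine), then k = 1..10, then weight (equal, inverse, squared_inverse).
#'
#' @param k_max Largest neighbor count (default 10).
#' @return Data frame with 90 rows and columns `distance`, `k`, `weight`.
#' @export
knn_grid <- function(k_max = 10L) {
  g <- expand.grid(weight = KNN_WEIGHTS, k = seq_len(k_max),
                   distance = KNN_DISTANCES,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("distance", "k", "weight")]
}

# Pooled cross-validated predictions for every grid configuration:
# one n-vector of integer class codes per config (columns), pooled over folds.
pooled_grid_predictions <- function(X, y_codes, n_classes, folds_vec, grid) {
  n <- nrow(X)
  pot <- matrix(NA_integer_, n, nrow(grid))
  for (f in sort(unique(folds_vec))) {
    te <- folds_vec == f
    trX <- X[!te, , drop = FALSE]
    teX <- X[te, , drop = FALSE]
    try <- y_codes[!te]
    for (a in seq_len(nrow(grid))) {
      # degenerate tiny folds: fall back to all available neighbors
      pot[te, a] <- knn_predict_cpp(
        trX, try, teX, match(grid$distance[a], KNN_DISTANCES) - 1L,
        min(grid$k[a], nrow(trX)), match(grid$weight[a], KNN_WEIGHTS) - 1L,
        n_classes)
    }
  }
  pot
}

#' Parameter-based outcome pool of the kNN ensemble
#'
#' Runs every configuration of [knn_grid()] under the supplied fold
#' assignment, pooling each configuration's per-fold test predictions into
#' one full-length prediction vector, and scores each against the labels.
#' With the default grid this yields exactly 90 outcomes. Deterministic:
#' the kNN rules contain no randomness. A configuration whose `k` exceeds a
#' fold's training size falls back to all available neighbors (only relevant
#' for degenerately small folds).
#'
#' @param X Sample matrix.
#' @param y Labels.
#' @param folds_vec Integer fold assignment, one entry per row of `X` (e.g.,
#'   from a CV driver); fold `f`'s rows are predicted by a model trained on
#'   all other rows.
#' @param grid Configuration grid (default [knn_grid()]).
#' @return List with `pot` (n x 90 integer matrix of class codes), `ca`
#'   (90 accuracies), `grid`, and `levels` (class level order).
#' @export
generate_parameter_outcomes <- function(X, y, folds_vec, grid = knn_grid()) {
  X <- as.matrix(X)
  y <- factor(y)
  stopifnot(nrow(X) == length(y), length(folds_vec) == length(y))
  pot <- pooled_grid_predictions(X, as.integer(y), nlevels(y), folds_vec, grid)
  ca <- colMeans(pot == as.integer(y))
  list(pot = pot, ca = ca, grid = grid, levels = levels(y))
}

# Row-wise mode with ties to the smallest class code; incremental counting
# over growing prefixes of the given column order.
prefix_modes <- function(pred_mat, col_order, depths, n_classes) {
  n <- nrow(pred_mat)
  counts <- matrix(0L, n, n_classes)
  out <- matrix(NA_integer_, n, length(depths))
  oi <- 1L
  for (j in seq_along(col_order)) {
    cl <- pred_mat[, col_order[j]]
    counts[cbind(seq_len(n), cl)] <- counts[cbind(seq_len(n), cl)] + 1L
    if (oi <= length(depths) && j == depths[oi]) {
      out[, oi] <- max.col(counts, ties.method = "first")
      oi <- oi + 1L
    }
  }
  out
}

#' Iterative majority voting over the accuracy-sorted outcome pool
#'
#' Sorts the parameter-based outcomes by descending accuracy (stable: ties
#' keep grid order) and forms the element-wise mode of the top 3, 4, ...,
#' up to all outcomes — 88 voted outcomes for the 90-outcome pool. Mode ties
#' resolve to the smallest class code.
#'
#' @param pot Integer matrix of pooled predictions (samples x outcomes).
#' @param ca Accuracy of each outcome column.
#' @param n_classes Number of classes.
#' @return List with `vot` (samples x (ncol(pot) - 2) integer matrix) and
#'   `ix` (the accuracy sort order).
#' @export
imv_vote <- function(pot, ca, n_classes) {
  stopifnot(ncol(pot) == length(ca), ncol(pot) >= 3L)
  ix <- order(-ca) # stable: ties by original (grid) order
  depths <- 3:ncol(pot)
  list(vot = prefix_modes(pot, ix, depths, n_classes), ix = ix)
}

#' Greedy selection of the best outcome among the full candidate pool
#'
#' Concatenates the parameter-based outcomes (indices 1..90) and the voted
#' outcomes (indices 91..178), scores all of them against the labels, and
#' returns the first index attaining the maximum accuracy — so on a tie a
#' parameter-based outcome beats a voted one, and earlier grid entries beat
#' later ones.
#'
#' @param pot,vot Integer prediction matrices from
#'   [generate_parameter_outcomes()] and [imv_vote()].
#' @param y_codes Integer class codes of the true labels.
#' @return List with `final` (integer prediction vector), `winner_index`
#'   (1..178), and `ca` (all 178 accuracies).
#' @export
greedy_select <- function(pot, vot, y_codes) {
  all_pred <- cbind(pot, vot)
  ca <- colMeans(all_pred == y_codes)
  winner <- which.max(ca) # first index attaining the max
  list(final = all_pred[, winner], winner_index = winner, ca = ca)
}

# Honest-mode fold step: score all grid configurations by leave-one-out on
# the training rows, run IMV and greedy selection there, then apply the
# winning configuration (or vote depth) to the test rows. Test labels are
# never consulted.
honest_fold_predict <- function(trX, try_codes, teX, grid, n_classes) {
  pot_tr <- matrix(NA_integer_, nrow(trX), nrow(grid))
  for (a in seq_len(nrow(grid))) {
    pot_tr[, a] <- knn_predict_cpp(
      trX, try_codes, trX, match(grid$distance[a], KNN_DISTANCES) - 1L,
      min(grid$k[a], nrow(trX) - 1L),
      match(grid$weight[a], KNN_WEIGHTS) - 1L, n_classes,
      loo = TRUE)
  }
  ca_tr <- colMeans(pot_tr == try_codes)
  iv_tr <- imv_vote(pot_tr, ca_tr, n_classes)
  gs_tr <- greedy_select(pot_tr, iv_tr$vot, try_codes)
  w <- gs_tr$winner_index
  predict_cfg <- function(a) {
    knn_predict_cpp(trX, try_codes, teX,
                    match(grid$distance[a], KNN_DISTANCES) - 1L,
                    min(grid$k[a], nrow(trX)),
                    match(grid$weight[a], KNN_WEIGHTS) - 1L, n_classes)
  }
  if (w <= nrow(grid)) {
    pred <- predict_cfg(w)
  } else {
    depth <- (w - nrow(grid)) + 2L # vote over the top depth configurations
    cols <- iv_tr$ix[seq_len(depth)]
    te_pred <- vapply(cols, predict_cfg, integer(nrow(teX)))
    if (is.null(dim(te_pred))) te_pred <- matrix(te_pred, nrow = 1L)
    pred <- as.integer(prefix_modes(te_pred, seq_len(depth), depth,
                                    n_classes))
  }
  list(predictions = pred, winner_index = w)
}

#' Self-organized kNN ensemble under a fold assignment
#'
#' The full ensemble classifier: 90 weighted-kNN parameterizations evaluated
#' under the supplied cross-validation folds, 88 iterative-majority-voting
#' aggregates of the accuracy-sorted pool, and greedy selection of the most
#' accurate of the 178 candidates.
#'
#' Two selection protocols are available. In `"paper"` mode (default) the
#' pooled test predictions themselves are scored to sort the pool and pick
#' the winner — the ensemble organizes itself on the very predictions being
#' reported, which is optimistic; it reproduces the method's published
#' protocol and its accuracy should be read accordingly. In `"honest"` mode
#' each fold picks its winner using leave-one-out accuracy on that fold's
#' training data only, then applies it to the fold's test set, so the
#' reported accuracy is untouched by test labels.
#'
#' @param X Sample matrix.
#' @param y Labels.
#' @param folds_vec Integer fold assignment per row.
#' @param mode `"paper"` or `"honest"`.
#' @param grid Configuration grid (default [knn_grid()]).
#' @return An object of class `tknn_result`: `predictions` (factor, one per
#'   row of `X`), `mode`, and for paper mode `pot`, `vot`, `ca` (178),
#'   `winner_index`; for honest mode `fold_winners`.
#' @export
tknn_cv <- function(X, y, folds_vec, mode = c("paper", "honest"),
                    grid = knn_grid()) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  y <- factor(y)
  n_classes <- nlevels(y)
  y_codes <- as.integer(y)
  if (mode == "paper") {
    po <- generate_parameter_outcomes(X, y, folds_vec, grid)
    iv <- imv_vote(po$pot, po$ca, n_classes)
    gs <- greedy_select(po$pot, iv$vot, y_codes)
    res <- list(predictions = factor(levels(y)[gs$final], levels = levels(y)),
                mode = mode, pot = po$pot, vot = iv$vot, ca = gs$ca,
                winner_index = gs$winner_index, grid = grid,
                levels = levels(y))
  } else {
    final <- integer(length(y))
    fold_winners <- integer(0)
    for (f in sort(unique(folds_vec))) {
      te <- folds_vec == f
      hp <- honest_fold_predict(X[!te, , drop = FALSE], y_codes[!te],
                                X[te, , drop = FALSE], grid, n_classes)
      final[te] <- hp$predictions
      fold_winners <- c(fold_winners, hp$winner_index)
    }
    res <- list(predictions = factor(levels(y)[final], levels = levels(y)),
                mode = mode, fold_winners = fold_winners, grid = grid,
                levels = levels(y))
  }
  class(res) <- "tknn_result"
  res
}

#' @export
print.tknn_result <- function(x, ...) {
  cat(sprintf("<tknn_result> mode = %s, %d predictions", x$mode,
              length(x$predictions)))
  if (!is.null(x$winner_index)) {
    cat(sprintf(", winner = %d/%d (accuracy %.4f)", x$winner_index,
                length(x$ca), x$ca[x$winner_index]))
  }
  cat("\n")
  invisible(x)
}

#' Summarize a paper-mode outcome pool as a data frame
#'
#' One row per candidate outcome: the 90 grid configurations followed by the
#' 88 vote depths, each with its pooled accuracy and a winner flag.
#'
#' @param x A `tknn_result` from paper mode.
#' @return Data frame with columns `outcome`, `distance`, `k`, `weight`,
#'   `vote_depth`, `accuracy`, `winner`.
#' @export
outcome_pool_table <- function(x) {
  stopifnot(inherits(x, "tknn_result"), !is.null(x$ca))
  n_cfg <- nrow(x$grid)
  n_vot <- length(x$ca) - n_cfg
  data.frame(
    outcome = seq_along(x$ca),
    distance = c(x$grid$distance, rep(NA, n_vot)),
    k = c(x$grid$k, rep(NA, n_vot)),
    weight = c(x$grid$weight, rep(NA, n_vot)),
    vote_depth = c(rep(NA, n_cfg), seq_len(n_vot) + 2L),
    accuracy = x$ca,
    winner = seq_along(x$ca) == x$winner_index
  )
}
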