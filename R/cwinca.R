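#' Smallest prefix reaching a cumulative-weight threshold
#'
#' With features sorted by descending weight, returns the smallest `m` such
#' that the top-`m` weights hold at least a fraction `t` of the total weight
#' mass. Used to derive the start and stop of the iterative selection loop
#' from the weight profile itself, which is what makes the selector
#' self-organized.
#'
#' @param fw A `feature_weights` object (or a nonnegative numeric vector,
#'   taken as already-sorted weights).
#' @param t Threshold in (0, 1].
#' @return Integer prefix size.
#' @examples
#' cumulative_weight_bound(rep(1, 10), t = 0.80)  # 8
#' @export
cumulative_weight_bound <- function(fw, t) {
  stopifnot(t > 0, t <= 1)
  w_sorted <- if (inherits(fw, "feature_weights")) fw$w[fw$id] else
    sort(as.numeric(fw), decreasing = TRUE)
  total <- sum(w_sorted)
  if (total <= 0) stop("cumulative_weight_bound: all weights are zero")
  cw <- cumsum(w_sorted) / total
  as.integer(which(cw >= t - 1e-12)[1])
}

# Stratified fold assignment: per class, shuffle then deal round-robin, so
# per-class fold sizes differ by at most one. RNG state is restored.
make_folds_stratified <- function(y, k, seed) {
  y <- factor(y)
  if (min(table(y)) < k) {
    stop("stratified folds: a class has fewer than ", k,
         " members; reduce the number of folds")
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# One fold per unique record id, in first-appearance order.
make_folds_loro <- function(record_ids) {
  match(record_ids, unique(record_ids))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Pooled CV accuracy of the loss classifier (default 1-NN, city-block) on a
# feature subset; the selection loop's figure of merit.
loss_classifier_accuracy <- function(X, y, eval_scheme, folds_vec,
                                     distance, k_nn, weight) {
  y <- factor(y)
  if (eval_scheme == "resub") {
    pred <- knn_predict(X, y, X, distance = distance, k = k_nn,
                        weight = weight, levels = levels(y))
    return(mean(pred == y))
  }
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in sort(unique(folds_vec))) {
    te <- folds_vec == f
    pred[te] <- knn_predict(X[!te, , drop = FALSE], y[!te],
                            X[te, , drop = FALSE], distance = distance,
                            k = k_nn, weight = weight, levels = levels(y))
  }
  mean(pred == y)
}

#' Greedy prefix search over weight-ranked feature subsets
#'
#' For each candidate size `r` in `start..stop`, evaluates the accuracy of a
#' loss classifier (default: 1-NN with city-block distance under seeded
#' stratified cross-validation) on the top-`r` features of the weight
#' ranking, and keeps the most accurate prefix. Accuracy ties resolve to the
#' smallest `r` (parsimony). Candidate subsets are always prefixes of the
#' weight order, never arbitrary subsets.
#'
#' @param X Sample matrix (samples x features).
#' @param y Labels.
#' @param fw A `feature_weights` object providing the ranking `id`.
#' @param start,stop Inclusive candidate-size range, `1 <= start <= stop <=
#'   ncol(X)`.
#' @param loss_cv_folds Folds for the internal loss evaluation (default 10;
#'   capped at the smallest class size).
#' @param eval_scheme `"cv"` (default) or `"resub"` (resubstitution).
#' @param loss_distance,loss_k,loss_weight Loss-classifier parameters
#'   (defaults: city-block, 1, equal).
#' @param seed Seed for the internal fold assignment (default 42).
#' @return A `selection_result`: `selected` (feature indices, a prefix of
#'   `fw$id`), `r_star`, `accuracies` (one per candidate `r`), `start`,
#'   `stop`.
#' @export
iterative_select <- function(X, y, fw, start, stop, loss_cv_folds = 10L,
                             eval_scheme = c("cv", "resub"),
                             loss_distance = "cityblock", loss_k = 1L,
                             loss_weight = "equal", seed = 42L) {
  eval_scheme <- match.arg(eval_scheme)
  X <- as.matrix(X)
  if (start > stop) stop("iterative_select: start (", start,
                         ") exceeds stop (", stop, ")")
  stopifnot(start >= 1, stop <= ncol(X))
  y <- factor(y)
  folds_vec <- NULL
  if (eval_scheme == "cv") {
    k_folds <- min(loss_cv_folds, min(table(y)))
    folds_vec <- make_folds_stratified(y, k_folds, seed)
  }
  rs <- start:stop
  acc <- vapply(rs, function(r) {
    loss_classifier_accuracy(X[, fw$id[seq_len(r)], drop = FALSE], y,
                             eval_scheme, folds_vec, loss_distance, loss_k,
                             loss_weight)
  }, numeric(1))
  r_star <- rs[which.max(acc)] # which.max takes the first max: smallest r
  structure(list(selected = fw$id[seq_len(r_star)], r_star = r_star,
                 accuracies = acc, start = as.integer(start),
                 stop = as.integer(stop)),
            class = "selection_result")
}

#' Cumulative-weight iterative NCA feature selection
#'
#' The full self-organized selector: learn NCA feature weights, derive the
#' candidate-size range from cumulative-weight thresholds (`t_start`,
#' `t_stop`), then greedily pick the most accurate weight-ranked prefix via
#' [iterative_select()]. The defaults (0.85 / 0.99) follow the method's
#' declared parameter table; 0.80 is a documented alternative for the start
#' threshold. Deterministic given the seeds in `settings` and `seed`.
#'
#' @param X Sample matrix or `feature_matrix`.
#' @param y Labels (ignored for a `feature_matrix`).
#' @param t_start,t_stop Cumulative-weight thresholds in (0, 1] with
#'   `t_start <= t_stop` (defaults 0.85 and 0.99).
#' @param settings [nca_settings()] for the weight-learning stage.
#' @param seed Seed for the internal loss cross-validation (default 42).
#' @param ... Further arguments passed to [iterative_select()].
#' @return A `selection_result` (see [iterative_select()]) with the
#'   additional fields `weights` (the `feature_weights`) and `thresholds`.
#' @export
cwinca_select <- function(X, y = NULL, t_start = 0.85, t_stop = 0.99,
                          settings = nca_settings(), seed = 42L, ...) {
  if (inherits(X, "feature_matrix")) { y <- X$y; X <- X$X }
  stopifnot(t_start <= t_stop)
  fw <- nca_weights(X, y, settings)
  start <- cumulative_weight_bound(fw, t_start)
  stop_ <- cumulative_weight_bound(fw, t_stop)
  res <- iterative_select(X, y, fw, start, stop_, seed = seed, ...)
  res$weights <- fw
  res$thresholds <- c(t_start = t_start, t_stop = t_stop)
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("<selection_result> r* = %d of range [%d, %d], ",
                     "best loss-classifier accuracy = %.4f\n"),
              x$r_star, x$start, x$stop, max(x$accuracies)))
  invisible(x)
}

#' Serialize a selection result to a JSON-ready list
#'
#' @param x A `selection_result`.
#' @return A plain list (indices, size, accuracy curve, range, thresholds)
#'   suitable for `jsonlite::write_json()`.
#' @export
selection_as_list <- function(x) {
  stopifnot(inherits(x, "selection_result"))
  list(selected = x$selected, r_star = x$r_star,
       accuracies = x$accuracies, start = x$start, stop = x$stop,
       thresholds = if (!is.null(x$thresholds)) as.list(x$thresholds))
}
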