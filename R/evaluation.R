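#' Confusion matrix with a declared class order
#'
#' Rows are actual classes, columns predicted, in the order of `levels`.
#'
#' @param actual,predicted Label vectors of equal length.
#' @param levels Class order (default: factor levels of `actual`).
#' @return Integer C x C matrix with dimnames `actual` / `predicted`.
#' @export
confusion_matrix <- function(actual, predicted, levels = NULL) {
  if (is.null(levels)) levels <- base::levels(factor(actual))
  a <- factor(actual, levels = levels)
  p <- factor(predicted, levels = levels)
  m <- table(actual = a, predicted = p)
  matrix(as.integer(m), nrow = length(levels),
         dimnames = list(actual = levels, predicted = levels))
}

#' Classification metrics from a confusion matrix
#'
#' Computes the five summary metrics as percentages: accuracy
#' (trace / total), macro-averaged precision and recall (unweighted class
#' means; an empty predicted column contributes precision 0), F1 (harmonic
#' mean of the macro precision and macro recall), and the geometric mean of
#' the per-class recalls (the balance-sensitive "G-mean" used for imbalanced
#' data). Per-class values are returned alongside for transparency.
#'
#' @param cm A square confusion matrix (rows actual, columns predicted).
#' @return List with `accuracy`, `geometric_mean`, `precision`, `recall`,
#'   `f1` (percent), plus `per_class` (data frame of class-wise precision
#'   and recall, percent) and `confusion` (the input matrix).
#' @examples
#' compute_metrics(matrix(c(8, 1, 2, 9), 2))$accuracy  # 85
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total <= 0) stop("compute_metrics: empty confusion matrix")
  d <- diag(cm)
  rows <- rowSums(cm)
  cols <- colSums(cm)
  recall_c <- ifelse(rows > 0, d / rows, 0)
  precision_c <- ifelse(cols > 0, d / cols, 0)
  prec <- mean(precision_c)
  rec <- mean(recall_c)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(
    accuracy = 100 * sum(d) / total,
    geometric_mean = 100 * prod(recall_c)^(1 / nrow(cm)),
    precision = 100 * prec,
    recall = 100 * rec,
    f1 = 100 * f1,
    per_class = data.frame(class = rownames(cm) %||% seq_len(nrow(cm)),
                           precision = 100 * precision_c,
                           recall = 100 * recall_c, row.names = NULL),
    confusion = cm
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

evaluation_report <- function(y, predictions, scheme, mode, seed = NA) {
  cm <- confusion_matrix(y, predictions, levels = levels(factor(y)))
  rep <- compute_metrics(cm)
  rep$scheme <- scheme
  rep$mode <- mode
  rep$seed <- seed
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> scheme = %s, mode = %s\n", x$scheme,
              x$mode))
  cat(sprintf("  accuracy %.2f | g-mean %.2f | precision %.2f | recall %.2f | F1 %.2f\n",
              x$accuracy, x$geometric_mean, x$precision, x$recall, x$f1))
  cat("  confusion matrix (rows = actual):\n")
  print(x$confusion)
  invisible(x)
}

#' Stratified 10-fold cross-validation driver
#'
#' Partitions segments into `n_folds` stratified folds (per-class sizes
#' differ by at most one; assignment seeded and reproducible), obtains
#' pooled out-of-fold predictions from the supplied pipeline, and reports
#' the five metrics from the single pooled confusion matrix. Note that
#' segment-level folding lets segments of one record fall on both sides of
#' a split — that is exactly why the record-grouped scheme [loro_cv()] is
#' reported alongside.
#'
#' @param fm A `feature_matrix` (or a plain matrix with `y` supplied).
#' @param y,record_ids Labels and record ids when `fm` is a plain matrix.
#' @param pipeline Function `(X, y, folds_vec) -> predictions` returning
#'   pooled out-of-fold predictions; default is the paper-mode tkNN ensemble
#'   ([tknn_pipeline()]).
#' @param seed Seed for the fold assignment (default 42).
#' @param n_folds Number of folds (default 10).
#' @return An `evaluation_report`.
#' @export
tenfold_cv <- function(fm, y = NULL, record_ids = NULL,
                       pipeline = tknn_pipeline(), seed = 42L,
                       n_folds = 10L) {
  if (inherits(fm, "feature_matrix")) {
    y <- fm$y; record_ids <- fm$record_ids; fm <- fm$X
  }
  y <- factor(y)
  folds_vec <- make_folds_stratified(y, n_folds, seed)
  pred <- pipeline(as.matrix(fm), y, folds_vec)
  evaluation_report(y, pred, scheme = "tenfold",
                    mode = attr(pipeline, "mode") %||% NA, seed = seed)
}

#' Leave-one-record-out cross-validation driver
#'
#' One fold per unique record id: all segments of that record form the test
#' set while every other record trains the model, so no record ever spans
#' the train/test boundary. Per-fold predictions are pooled into one
#' confusion matrix. If a fold's training records lack the held-out record's
#' class entirely, a warning names the record and the fold is still
#' evaluated.
#'
#' @inheritParams tenfold_cv
#' @return An `evaluation_report`.
#' @export
loro_cv <- function(fm, y = NULL, record_ids = NULL,
                    pipeline = tknn_pipeline()) {
  if (inherits(fm, "feature_matrix")) {
    y <- fm$y; record_ids <- fm$record_ids; fm <- fm$X
  }
  y <- factor(y)
  if (length(unique(record_ids)) < 2L) {
    stop("loro_cv: need at least 2 distinct records")
  }
  folds_vec <- make_folds_loro(record_ids)
  for (f in unique(folds_vec)) {
    te <- folds_vec == f
    if (!any(y[!te] == y[te][1])) {
      warning("loro_cv: class '", y[te][1], "' of record '",
              record_ids[te][1], "' is absent from its training fold")
    }
  }
  pred <- pipeline(as.matrix(fm), y, folds_vec)
  evaluation_report(y, pred, scheme = "loro",
                    mode = attr(pipeline, "mode") %||% NA, seed = NA)
}

#' tkNN ensemble as a cross-validation pipeline
#'
#' Wraps [tknn_cv()] into the `(X, y, folds_vec) -> predictions` interface
#' expected by [tenfold_cv()] and [loro_cv()].
#'
#' @param mode `"paper"` (self-organized on pooled test predictions) or
#'   `"honest"` (winner chosen per fold on training data only); see
#'   [tknn_cv()].
#' @param grid Configuration grid (default [knn_grid()]).
#' @return A pipeline function with a `"mode"` attribute.
#' @export
tknn_pipeline <- function(mode = "paper", grid = knn_grid()) {
  f <- function(X, y, folds_vec) {
    tknn_cv(X, y, folds_vec, mode = mode, grid = grid)$predictions
  }
  attr(f, "mode") <- mode
  f
}
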