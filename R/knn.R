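KNN_DISTANCES <- c("cityblock", "euclidean", "cosine")
KNN_WEIGHTS <- c("equal", "inverse", "squared_inverse")

#' Weighted k-nearest-neighbor prediction
#'
#' Classifies each test row by its `k` nearest training rows under the chosen
#' distance, with class scores summed per neighbor as 1 (`equal`), `1/d`
#' (`inverse`) or `1/d^2` (`squared_inverse`). Rules fixed for
#' reproducibility: neighbor ties at the k-th distance keep the earlier
#' training rows (stable order, exactly `k` neighbors); if any neighbor sits
#' at distance zero under a distance-weighted scheme, the majority label
#' among the zero-distance neighbors wins (the `1/d` limit); score ties go to
#' the first class level.
#'
#' @param train_X,train_y Training matrix and labels.
#' @param test_X Matrix of points to classify.
#' @param distance One of `"cityblock"`, `"euclidean"`, `"cosine"`
#'   (`1 - u.v / (|u||v|)`; rows must be non-zero).
#' @param k Number of neighbors (1..nrow(train_X)).
#' @param weight One of `"equal"`, `"inverse"`, `"squared_inverse"`.
#' @param levels Optional explicit class-level ordering; defaults to the
#'   factor levels of `train_y`.
#' @param loo If `TRUE`, `test_X` must be `train_X` and each row is predicted
#'   with itself excluded from the neighbor pool (leave-one-out).
#' @return Factor of predicted labels, one per test row.
#' @export
knn_predict <- function(train_X, train_y, test_X,
                        distance = "cityblock", k = 1L, weight = "equal",
                        levels = NULL, loo = FALSE) {
  distance <- match.arg(distance, KNN_DISTANCES)
  weight <- match.arg(weight, KNN_WEIGHTS)
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X)
  if (ncol(train_X) != ncol(test_X)) {
    stop("knn_predict: train and test feature dimensions differ")
  }
  if (loo && nrow(train_X) != nrow(test_X)) {
    stop("knn_predict: loo = TRUE requires test_X to be train_X")
  }
  if (k > nrow(train_X) - loo) {
    stop("knn_predict: k = ", k, " exceeds ", nrow(train_X) - loo,
         " available training samples")
  }
  if (distance == "cosine") {
    zt <- which(rowSums(train_X^2) == 0)
    zs <- which(rowSums(test_X^2) == 0)
    if (length(zt)) stop("knn_predict: zero vector under cosine distance ",
                         "in training row ", zt[1])
    if (length(zs)) stop("knn_predict: zero vector under cosine distance ",
                         "in test row ", zs[1])
  }
  yf <- if (is.null(levels)) factor(train_y) else factor(train_y, levels = levels)
  pred <- knn_predict_cpp(train_X, as.integer(yf), test_X,
                          match(distance, KNN_DISTANCES) - 1L, as.integer(k),
                          match(weight, KNN_WEIGHTS) - 1L, nlevels(yf),
                          loo = loo)
  factor(levels(yf)[pred], levels = levels(yf))
}
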