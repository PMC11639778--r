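#' Settings for NCA weight learning
#'
#' @param lambda Ridge penalty on the squared weights; `NULL` (default) means
#'   `1 / n` where `n` is the number of samples.
#' @param max_iter Maximum gradient-ascent iterations (default 200).
#' @param tol Convergence tolerance on the objective increase (default 1e-6).
#' @param seed Integer seed (the default optimizer is full-batch and
#'   deterministic; the seed is kept for provenance and future stochastic
#'   variants).
#' @param standardize Standardize columns to zero mean / unit variance before
#'   learning (default `TRUE`; constant columns become all-zero).
#' @return A list of class `nca_settings`.
#' @export
nca_settings <- function(lambda = NULL, max_iter = 200L, tol = 1e-6,
                         seed = 1L, standardize = TRUE) {
  stopifnot(is.null(lambda) || lambda >= 0, max_iter >= 1, tol > 0)
  structure(list(lambda = lambda, max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), standardize = isTRUE(standardize)),
            class = "nca_settings")
}

standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- Inf # constant columns -> all zeros
  sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
}

encode_labels <- function(y) {
  y <- factor(y)
  list(codes = as.integer(y), levels = levels(y))
}

#' Regularized NCA objective
#'
#' The stochastic leave-one-out nearest-neighbor objective with diagonal
#' weights and a weighted city-block distance:
#' \deqn{F(w) = \frac{1}{n}\sum_i p_i - \lambda \sum_r w_r^2,}
#' where \eqn{p_i = \sum_{j \ne i,\, y_j = y_i} p_{ij}},
#' \eqn{p_{ij} \propto \exp(-\sum_r w_r^2 |x_{ir} - x_{jr}|)} normalized over
#' \eqn{j \ne i}. Exposed as a pure function so that gradient checks and
#' closed-form cases can probe the optimizer independently.
#'
#' @param w Numeric weight vector (one per feature).
#' @param X Numeric sample matrix (rows = samples). Used as given; no
#'   standardization is applied here.
#' @param y Labels.
#' @param lambda Ridge penalty (scalar, >= 0).
#' @return The scalar objective value.
#' @export
nca_objective <- function(w, X, y, lambda) {
  X <- as.matrix(X)
  stopifnot(length(w) == ncol(X), nrow(X) == length(y))
  enc <- encode_labels(y)
  nca_objective_grad_cpp(X, enc$codes, as.numeric(w), lambda,
                         want_grad = FALSE)$value
}

#' Gradient of the regularized NCA objective
#'
#' Analytic gradient of [nca_objective()] with respect to `w`; used by the
#' optimizer and checkable against finite differences.
#'
#' @inheritParams nca_objective
#' @return Numeric vector, same length as `w`.
#' @export
nca_gradient <- function(w, X, y, lambda) {
  X <- as.matrix(X)
  enc <- encode_labels(y)
  as.numeric(nca_objective_grad_cpp(X, enc$codes, as.numeric(w), lambda,
                                    want_grad = TRUE)$grad)
}

#' Learn per-feature NCA relevance weights
#'
#' Maximizes the regularized leave-one-out nearest-neighbor objective (see
#' [nca_objective()]) by full-batch gradient ascent with an adaptive step:
#' a step is accepted only if it increases the objective, so the trajectory
#' of accepted objective values is non-decreasing. The returned weights are
#' the element-wise absolute value of the optimized parameter (the objective
#' depends on `w` only through `w^2`), hence nonnegative. Features are ranked
#' by descending weight; ties break by ascending feature index.
#'
#' @param X Numeric matrix (samples x features) or a `feature_matrix`.
#' @param y Labels (ignored when `X` is a `feature_matrix`).
#' @param settings An [nca_settings()] object.
#' @return List of class `feature_weights` with elements `w` (nonnegative
#'   weights, in standardized space when `settings$standardize`), `id`
#'   (permutation of feature indices, descending weight), `objective`
#'   (accepted objective trajectory), and `settings`.
#' @examples
#' set.seed(1)
#' X <- cbind(informative = rep(0:1, each = 20) * 3 + rnorm(40),
#'            noise = rnorm(40))
#' fw <- nca_weights(X, rep(0:1, each = 20))
#' fw$id[1]  # the informative column ranks first
#' @export
nca_weights <- function(X, y = NULL, settings = nca_settings()) {
  if (inherits(X, "feature_matrix")) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("nca_weights: need at least 3 samples")
  enc <- encode_labels(y)
  if (length(unique(enc$codes)) < 2L) {
    stop("nca_weights: y must contain at least two classes")
  }
  if (min(table(enc$codes)) < 2L) {
    stop("nca_weights: every class needs at least 2 samples")
  }
  lambda <- if (is.null(settings$lambda)) 1 / n else settings$lambda
  Xs <- if (settings$standardize) standardize_columns(X) else X

  w <- rep(1, p)
  eg <- nca_objective_grad_cpp(Xs, enc$codes, w, lambda, want_grad = TRUE)
  f <- eg$value
  trace <- f
  step <- 1
  for (it in seq_len(settings$max_iter)) {
    g <- as.numeric(eg$grad)
    gn <- sqrt(sum(g^2))
    if (!is.finite(gn) || gn < 1e-12) break
    accepted <- FALSE
    while (step > 1e-12) {
      w_new <- w + step * g
      eg_new <- nca_objective_grad_cpp(Xs, enc$codes, w_new, lambda,
                                       want_grad = TRUE)
      if (is.finite(eg_new$value) && eg_new$value > f) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    delta <- eg_new$value - f
    w <- w_new; f <- eg_new$value; eg <- eg_new
    trace <- c(trace, f)
    step <- step * 1.2
    if (delta < settings$tol) break
  }

  w_abs <- abs(w)
  id <- order(-w_abs, seq_len(p)) # descending weight, ties by index
  structure(list(w = w_abs, id = id, objective = trace,
                 lambda = lambda, settings = settings),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("<feature_weights> %d features; top 5: %s\n", length(x$w),
              paste(x$id[seq_len(min(5, length(x$id)))], collapse = ", ")))
  invisible(x)
}

#' Export feature weights as a two-column data frame
#'
#' @param fw A `feature_weights` object.
#' @return Data frame with columns `feature` and `weight`, in descending
#'   weight order.
#' @export
weights_table <- function(fw) {
  stopifnot(inherits(fw, "feature_weights"))
  data.frame(feature = fw$id, weight = fw$w[fw$id])
}
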