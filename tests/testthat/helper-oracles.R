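# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain loops, explicit formulas.

# Reference descriptor: slice each window, scan linearly for the first
# min/max positions, accumulate the histogram one block at a time.
naive_minmaxpat <- function(x, W = 16L) {
  n <- length(x)
  counts <- integer(W * W)
  for (i in seq_len(n - W + 1L)) {
    b <- x[i:(i + W - 1L)]
    mini <- which(b == min(b))[1]
    maxi <- which(b == max(b))[1]
    code <- W * (maxi - 1L) + (mini - 1L)
    counts[code + 1L] <- counts[code + 1L] + 1L
  }
  counts
}

# Reference weighted kNN: explicit all-pairs distances, stable neighbor
# order, the same zero-distance and tie rules the contract specifies.
naive_knn <- function(trX, try, teX, distance, k, weight, lv = NULL) {
  if (is.null(lv)) lv <- levels(factor(try))
  try <- factor(try, levels = lv)
  pred <- character(nrow(teX))
  for (t in seq_len(nrow(teX))) {
    u <- teX[t, ]
    d <- numeric(nrow(trX))
    for (j in seq_len(nrow(trX))) {
      v <- trX[j, ]
      d[j] <- switch(distance,
        cityblock = sum(abs(u - v)),
        euclidean = sqrt(sum((u - v)^2)),
        cosine = max(0, 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))))
    }
    nb <- order(d)[seq_len(k)] # order() is stable: ties keep row order
    score <- setNames(numeric(length(lv)), lv)
    zero <- nb[d[nb] == 0]
    if (weight != "equal" && length(zero) > 0) {
      tab <- table(factor(try[zero], levels = lv))
      score[] <- as.numeric(tab)
    } else {
      for (j in nb) {
        wt <- switch(weight, equal = 1, inverse = 1 / d[j],
                     squared_inverse = 1 / d[j]^2)
        score[as.character(try[j])] <- score[as.character(try[j])] + wt
      }
    }
    pred[t] <- lv[which.max(score)] # first max: smallest class level
  }
  factor(pred, levels = lv)
}

# Central finite differences for gradient checks.
numerical_gradient <- function(f, w, eps = 1e-5) {
  vapply(seq_along(w), function(r) {
    wp <- w; wm <- w
    wp[r] <- wp[r] + eps
    wm[r] <- wm[r] - eps
    (f(wp) - f(wm)) / (2 * eps)
  }, numeric(1))
}

# Small labeled 2-D cluster problem, linearly separable.
two_cluster_data <- function(n_per = 20, gap = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per) + gap, ncol = 2))
  list(X = X, y = factor(rep(c("a", "b"), each = n_per)))
}
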