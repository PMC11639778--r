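test_that("objective at zero weights reduces to the same-class proportion", {
  set.seed(5)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(c("a", "b", "c"), each = 10)
  # w = 0: all distances 0, p_ij uniform over the other n-1 samples
  expected <- mean(vapply(seq_along(y), function(i) {
    sum(y[-i] == y[i]) / (length(y) - 1)
  }, numeric(1)))
  expect_equal(nca_objective(rep(0, 4), X, y, lambda = 0), expected)
})

test_that("objective with no penalty never exceeds 1", {
  set.seed(6)
  for (i in 1:10) {
    X <- matrix(rnorm(20 * 3), 20, 3)
    y <- rep(c("a", "b"), 10)
    w <- runif(3, 0, 2)
    expect_lte(nca_objective(w, X, y, lambda = 0), 1)
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(7)
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- rep(c("a", "b"), 5)
  for (lambda in c(0, 0.1)) {
    w <- runif(5, 0.2, 1.5)
    g <- nca_gradient(w, X, y, lambda)
    g_num <- numerical_gradient(function(v) nca_objective(v, X, y, lambda), w)
    expect_lt(max(abs(g - g_num)) / max(abs(g_num)), 1e-5)
  }
})

test_that("a label-copying feature among noise is ranked first", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 60
    y <- rep(c(1, 2), each = n / 2)
    X <- cbind(y + 0 * rnorm(n), matrix(rnorm(n * 50), n, 50))
    fw <- nca_weights(X, y, nca_settings(seed = seed))
    hits <- hits + (fw$id[1] == 1)
  }
  expect_gte(hits, 19) # >= 95% of 20 seeds
})

test_that("weights are equivariant under feature permutation", {
  set.seed(8)
  dat <- generate_planted_feature_matrix(n = 40, n_features = 6,
                                         n_informative = 2, effect = 2,
                                         seed = 8)
  fw <- nca_weights(dat$X, dat$y)
  perm <- c(3, 1, 6, 2, 5, 4)
  fw_p <- nca_weights(dat$X[, perm], dat$y)
  expect_equal(fw_p$w, fw$w[perm], tolerance = 1e-8)
})

test_that("duplicating every sample preserves the informative top set", {
  dat <- generate_planted_feature_matrix(n = 60, n_features = 10,
                                         n_informative = 2, effect = 3,
                                         seed = 9)
  fw <- nca_weights(dat$X, dat$y)
  dup <- rep(seq_len(nrow(dat$X)), each = 2)
  fw2 <- nca_weights(dat$X[dup, ], dat$y[dup])
  expect_setequal(fw$id[1:2], dat$informative)
  expect_setequal(fw2$id[1:2], dat$informative)
})

test_that("accepted objective values are non-decreasing", {
  dat <- generate_planted_feature_matrix(n = 50, n_features = 8,
                                         n_informative = 2, effect = 2,
                                         seed = 10)
  fw <- nca_weights(dat$X, dat$y)
  expect_true(all(diff(fw$objective) >= 0))
})

test_that("weights are always finite and nonnegative; id is a permutation", {
  for (seed in 1:5) {
    dat <- generate_planted_feature_matrix(n = 30, n_features = 7,
                                           n_informative = 1, effect = 1,
                                           seed = seed)
    fw <- nca_weights(dat$X, dat$y)
    expect_true(all(is.finite(fw$w)) && all(fw$w >= 0))
    expect_setequal(fw$id, seq_len(7))
    expect_true(all(diff(fw$w[fw$id]) <= 0))
  }
})

test_that("standardization makes the ranking scale-invariant", {
  dat <- generate_planted_feature_matrix(n = 80, n_features = 8,
                                         n_informative = 2, effect = 3,
                                         seed = 11)
  X_scaled <- dat$X
  X_scaled[, 5] <- X_scaled[, 5] * 1000
  fw <- nca_weights(dat$X, dat$y)
  fw_s <- nca_weights(X_scaled, dat$y)
  expect_setequal(fw_s$id[1:2], fw$id[1:2])
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(nca_weights(X, rep("a", 10)), "two classes")
  expect_error(nca_weights(X[1:2, ], c("a", "b")), "at least 3")
  expect_error(nca_weights(X, c(rep("a", 9), "b")), "at least 2 samples")
})

test_that("constant features receive (near) zero weight", {
  dat <- generate_planted_feature_matrix(n = 60, n_features = 5,
                                         n_informative = 1, effect = 3,
                                         seed = 12)
  X <- cbind(dat$X, const = 7)
  fw <- nca_weights(X, dat$y)
  # a constant column standardizes to all zeros: zero gradient, and the
  # ridge penalty shrinks it below the informative feature
  expect_lt(fw$w[6], fw$w[1])
})
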