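test_that("cumulative-weight bound returns the smallest qualifying prefix", {
  expect_equal(cumulative_weight_bound(rep(1, 10), 0.80), 8)
  expect_equal(cumulative_weight_bound(c(0.99, rep(0.01 / 9, 9)), 0.80), 1)
  expect_equal(cumulative_weight_bound(rep(1, 10), 0.99), 10)
  expect_error(cumulative_weight_bound(rep(0, 5), 0.8), "zero")
})

test_that("bounds are monotone in the threshold, so start <= stop", {
  set.seed(13)
  for (i in 1:20) {
    w <- runif(30)
    expect_lte(cumulative_weight_bound(w, 0.85),
               cumulative_weight_bound(w, 0.99))
  }
})

test_that("a degenerate range selects exactly the top-r features", {
  dat <- generate_planted_feature_matrix(n = 60, n_features = 12,
                                         n_informative = 2, effect = 2,
                                         seed = 14)
  fw <- nca_weights(dat$X, dat$y)
  res <- iterative_select(dat$X, dat$y, fw, start = 5, stop = 5)
  expect_equal(res$selected, fw$id[1:5])
  expect_equal(res$r_star, 5)
  expect_length(res$accuracies, 1)
})

test_that("prefix accuracies match an exhaustive naive-kNN evaluation", {
  dat <- generate_planted_feature_matrix(n = 40, n_features = 10,
                                         n_informative = 2, effect = 3,
                                         seed = 15)
  fw <- nca_weights(dat$X, dat$y)
  res <- iterative_select(dat$X, dat$y, fw, start = 1, stop = 10, seed = 99)
  folds <- minmaxpat:::make_folds_stratified(dat$y, 10, seed = 99)
  oracle <- vapply(1:10, function(r) {
    Xr <- dat$X[, fw$id[seq_len(r)], drop = FALSE]
    pred <- factor(rep(NA_character_, 40), levels = levels(dat$y))
    for (f in 1:10) {
      te <- folds == f
      pred[te] <- naive_knn(Xr[!te, , drop = FALSE], dat$y[!te],
                            Xr[te, , drop = FALSE], "cityblock", 1, "equal",
                            levels(dat$y))
    }
    mean(pred == dat$y)
  }, numeric(1))
  expect_equal(res$accuracies, oracle)
  expect_equal(max(oracle), max(res$accuracies))
  expect_length(res$accuracies, 10)
})

test_that("accuracy ties resolve to the smallest prefix", {
  # a very easy problem saturates at perfect accuracy for many prefixes
  dat <- generate_planted_feature_matrix(n = 60, n_features = 8,
                                         n_informative = 4, effect = 10,
                                         seed = 16)
  fw <- nca_weights(dat$X, dat$y)
  res <- iterative_select(dat$X, dat$y, fw, start = 1, stop = 8)
  amax <- max(res$accuracies)
  first_r <- which(res$accuracies == amax)[1]
  expect_equal(res$r_star, first_r)
})

test_that("invalid ranges are rejected", {
  dat <- generate_planted_feature_matrix(n = 30, n_features = 5, seed = 17)
  fw <- nca_weights(dat$X, dat$y)
  expect_error(iterative_select(dat$X, dat$y, fw, start = 4, stop = 2),
               "exceeds stop")
})

test_that("the composite selector recovers planted features and is a prefix", {
  dat <- generate_planted_feature_matrix(n = 200, n_features = 20,
                                         n_informative = 3, effect = 3,
                                         seed = 18)
  res <- cwinca_select(dat$X, dat$y, settings = nca_settings(seed = 18))
  expect_true(all(dat$informative %in% res$selected))
  expect_equal(res$selected, res$weights$id[seq_len(res$r_star)])
  expect_true(res$start <= res$r_star && res$r_star <= res$stop)
  expect_equal(unname(res$thresholds), c(0.85, 0.99))
})

test_that("re-evaluating the chosen prefix reproduces its accuracy", {
  dat <- generate_planted_feature_matrix(n = 50, n_features = 10,
                                         n_informative = 2, effect = 3,
                                         seed = 19)
  fw <- nca_weights(dat$X, dat$y)
  res <- iterative_select(dat$X, dat$y, fw, start = 1, stop = 10, seed = 7)
  again <- iterative_select(dat$X, dat$y, fw, start = res$r_star,
                            stop = res$r_star, seed = 7)
  expect_equal(again$accuracies[1], max(res$accuracies))
})

test_that("equal thresholds collapse the loop to a single candidate", {
  dat <- generate_planted_feature_matrix(n = 40, n_features = 8,
                                         n_informative = 2, effect = 3,
                                         seed = 20)
  res <- cwinca_select(dat$X, dat$y, t_start = 0.9, t_stop = 0.9)
  expect_length(res$accuracies, 1)
  expect_equal(res$start, res$stop)
})
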