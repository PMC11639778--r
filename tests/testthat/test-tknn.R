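test_that("nearest-cluster prediction and cosine scale invariance hold", {
  d <- two_cluster_data()
  te <- rbind(c(0, 0), c(10, 10))
  pred <- knn_predict(d$X, d$y, te, "cityblock", k = 1, weight = "equal")
  expect_equal(as.character(pred), c("a", "b"))

  te1 <- matrix(c(9, 11), 1)
  p1 <- knn_predict(d$X, d$y, te1, "cosine", k = 3, weight = "inverse")
  p3 <- knn_predict(d$X, d$y, te1 * 3, "cosine", k = 3, weight = "inverse")
  expect_equal(p1, p3)
})

test_that("kNN guards its preconditions", {
  d <- two_cluster_data(n_per = 3)
  expect_error(knn_predict(d$X, d$y, d$X, k = 7), "exceeds")
  Xz <- rbind(d$X, 0)
  yz <- factor(c(as.character(d$y), "a"))
  expect_error(knn_predict(Xz, yz, d$X[1, , drop = FALSE], "cosine"),
               "training row 7")
  expect_error(knn_predict(d$X, d$y, matrix(0, 1, 2), "cosine"),
               "test row 1")
})

test_that("zero-distance neighbors dominate distance-weighted votes", {
  trX <- rbind(c(0, 0), c(0, 0), c(0.1, 0), c(0.1, 0), c(0.1, 0))
  try <- factor(c("b", "b", "a", "a", "a"))
  te <- matrix(0, 1, 2)
  # k = 5: three 'a' at 0.1 would outvote under equal weights, but the two
  # zero-distance 'b' carry infinite weight under inverse schemes
  expect_equal(as.character(
    knn_predict(trX, try, te, k = 5, weight = "inverse")), "b")
  expect_equal(as.character(
    knn_predict(trX, try, te, k = 5, weight = "squared_inverse")), "b")
  expect_equal(as.character(
    knn_predict(trX, try, te, k = 5, weight = "equal")), "a")
})

test_that("all 90 configurations match the naive all-pairs reference", {
  set.seed(21)
  trX <- matrix(rnorm(40 * 3), 40, 3) + 1 # offset: no zero rows for cosine
  try <- factor(sample(c("a", "b"), 40, replace = TRUE))
  teX <- matrix(rnorm(15 * 3), 15, 3) + 1
  g <- knn_grid()
  expect_equal(nrow(g), 90)
  for (a in seq_len(nrow(g))) {
    expect_equal(
      knn_predict(trX, try, teX, g$distance[a], g$k[a], g$weight[a],
                  levels = levels(try)),
      naive_knn(trX, try, teX, g$distance[a], g$k[a], g$weight[a],
                levels(try)),
      info = sprintf("config %d: %s k=%d %s", a, g$distance[a], g$k[a],
                     g$weight[a]))
  }
})

test_that("the grid enumerates distance-major, then k, then weight", {
  g <- knn_grid()
  expect_equal(g$distance[1:3], rep("cityblock", 3))
  expect_equal(g$weight[1:3], c("equal", "inverse", "squared_inverse"))
  expect_equal(g$k[1:6], c(1, 1, 1, 2, 2, 2))
  expect_equal(g$distance[c(1, 31, 61)],
               c("cityblock", "euclidean", "cosine"))
})

test_that("the parameter pool has 90 outcomes scored against the labels", {
  d <- two_cluster_data(n_per = 30, gap = 8, seed = 22)
  folds <- minmaxpat:::make_folds_stratified(d$y, 5, seed = 1)
  po <- generate_parameter_outcomes(d$X, d$y, folds)
  expect_equal(ncol(po$pot), 90)
  expect_length(po$ca, 90)
  expect_equal(max(po$ca), 1) # perfectly separable clusters
  po2 <- generate_parameter_outcomes(d$X, d$y, folds)
  expect_identical(po$pot, po2$pot) # no randomness anywhere
})

test_that("IMV votes over growing prefixes of the accuracy-sorted pool", {
  set.seed(23)
  n <- 30
  pot <- matrix(sample(1:2, n * 90, replace = TRUE), n, 90)
  ca <- runif(90)
  iv <- imv_vote(pot, ca, 2)
  expect_equal(ncol(iv$vot), 88)
  expect_equal(iv$ix, order(-ca))
  # depth-3 vote recomputed by hand
  top3 <- pot[, iv$ix[1:3]]
  hand <- apply(top3, 1, function(r) {
    tb <- tabulate(r, 2)
    which.max(tb) # ties -> smallest label
  })
  expect_equal(iv$vot[, 1], hand)

  uni <- matrix(1L, n, 90)
  ivu <- imv_vote(uni, rep(0.5, 90), 2)
  expect_true(all(ivu$vot == 1L))
})

test_that("mode ties resolve to the smallest class code", {
  pot <- cbind(rep(1L, 4), rep(2L, 4), c(1L, 2L, 1L, 2L), rep(2L, 4))
  iv <- imv_vote(pot, c(0.9, 0.8, 0.7, 0.6), 2)
  # depth 4: votes split 2-2 on rows 1 and 3 -> class 1 wins there
  expect_equal(iv$vot[, 2], c(1L, 2L, 1L, 2L))
})

test_that("greedy selection scans 178 candidates, parameter pool first", {
  set.seed(24)
  n <- 40
  y <- sample(1:2, n, replace = TRUE)
  pot <- matrix(sample(1:2, n * 90, replace = TRUE), n, 90)
  pot[, 37] <- y # one perfect parameter-based outcome
  ca <- colMeans(pot == y)
  iv <- imv_vote(pot, ca, 2)
  gs <- greedy_select(pot, iv$vot, y)
  expect_length(gs$ca, 178)
  expect_equal(gs$winner_index, 37) # perfect vot candidates rank later
  expect_equal(gs$final, y)
  expect_true(gs$ca[gs$winner_index] >= max(ca))
})

test_that("the ensemble winner is at least as accurate as any single config", {
  d <- two_cluster_data(n_per = 25, gap = 2.5, seed = 25)
  folds <- minmaxpat:::make_folds_stratified(d$y, 5, seed = 2)
  res <- tknn_cv(d$X, d$y, folds, mode = "paper")
  acc_final <- mean(res$predictions == d$y)
  expect_gte(acc_final, max(res$ca[1:90]) - 1e-12)
  expect_equal(length(res$ca), 178)
})

test_that("honest mode never consults test labels and stays deterministic", {
  d <- two_cluster_data(n_per = 25, gap = 6, seed = 26)
  folds <- minmaxpat:::make_folds_stratified(d$y, 5, seed = 3)
  r1 <- tknn_cv(d$X, d$y, folds, mode = "honest")
  r2 <- tknn_cv(d$X, d$y, folds, mode = "honest")
  expect_identical(r1$predictions, r2$predictions)
  expect_length(r1$fold_winners, 5)
  expect_gte(mean(r1$predictions == d$y), 0.95) # well-separated clusters
})
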