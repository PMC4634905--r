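test_that("knn_indices finds exact matches and breaks ties to lower index", {
  train <- rbind(c(0, 0), c(1, 1), c(1, 0))
  expect_equal(knn_indices(train, rbind(c(1, 1)), k = 1)[1, 1], 2L)
  # equidistant neighbours: the middle row ties rows 1 and 3, lower index wins
  train2 <- rbind(c(0, 0), c(0, 1), c(1, 1))
  nb <- knn_indices(train2, train2, k = 1, exclude_self = TRUE)
  expect_equal(as.vector(nb), c(2L, 1L, 2L))
  expect_error(knn_indices(train2, train2, k = 3, exclude_self = TRUE),
               "eligible")
})

test_that("knn_indices agrees with brute-force search on random instances", {
  for (seed in 1:5) {
    inst <- random_instance(n = 9, p = 5, q = 1, seed = seed)
    Q <- matrix(rbinom(20, 1, 0.5), 4, 5)
    k <- sample(1:4, 1)
    expect_identical(knn_indices(inst$X, Q, k),
                     matrix(oracle_knn(inst$X, Q, k), 4, k))
    expect_identical(knn_indices(inst$X, inst$X, k, exclude_self = TRUE),
                     matrix(oracle_knn(inst$X, inst$X, k, TRUE), 9, k))
  }
})

test_that("membership_counts sums neighbour labels", {
  Y <- cbind(c(1, 0, 1), c(0, 0, 0))
  nb <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(membership_counts(nb, Y), cbind(2L, 0L))
  inst <- random_instance(8, 4, 3, seed = 7)
  nb <- knn_indices(inst$X, inst$X, 3, exclude_self = TRUE)
  C <- membership_counts(nb, inst$Y)
  for (i in 1:8) for (l in 1:3)
    expect_equal(C[i, l], sum(inst$Y[nb[i, ], l]))
})

test_that("prior estimates follow the smoothed frequency formula", {
  X <- diag(4L)
  m <- fit_mlknn(X, cbind(c(1, 1, 0, 0)), mlknn_config(k = 1, s = 1))
  expect_equal(unname(m$prior1), (1 + 2) / (2 + 4))  # = 0.5
  m2 <- fit_mlknn(diag(3L), cbind(c(0, 0, 0)), mlknn_config(k = 1, s = 1))
  expect_equal(unname(m2$prior1), 1 / 5)
  # posterior of a hand-built count vector: s=1, k=2, c = [0,1,1]
  expect_equal((1 + 1) / (1 * 3 + 2), 0.4)
  expect_error(fit_mlknn(diag(3L), cbind(c(1, 0, 1)), mlknn_config(k = 3)),
               "smaller than")
})

test_that("posterior rows are normalised and probabilities lie in (0,1)", {
  for (seed in 1:100) {
    inst <- random_instance(n = sample(6:12, 1), p = 4, q = 3, seed = seed)
    m <- fit_mlknn(inst$X, inst$Y,
                   mlknn_config(k = sample(1:4, 1), s = runif(1, 0.2, 2)))
    expect_lt(max(abs(rowSums(m$post_pos) - 1)), 1e-12)
    expect_lt(max(abs(rowSums(m$post_neg) - 1)), 1e-12)
    expect_true(all(m$prior1 > 0 & m$prior1 < 1))
    expect_true(all(m$post_pos > 0 & m$post_pos < 1))
    expect_true(all(m$post_neg > 0 & m$post_neg < 1))
  }
})

test_that("fit + predict reproduces the brute-force Bayes computation", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(6:10, 1); q <- sample(2:4, 1); k <- sample(1:3, 1)
    inst <- random_instance(n, p = 5, q = q)
    Q <- matrix(rbinom(4 * 5, 1, 0.5), 4, 5)
    m <- fit_mlknn(inst$X, inst$Y, mlknn_config(k = k, s = 1))
    expect_equal(unname(predict(m, Q)),
                 oracle_mlknn_scores(inst$X, inst$Y, Q, k, s = 1),
                 tolerance = 1e-12)
  }
})

test_that("scores are invariant under permutation of training rows", {
  # with a tie-free neighbour relation (k = n-1: every other drug is a
  # neighbour) the fit depends only on the set of training drugs
  inst <- random_instance(10, 6, 3, seed = 11)
  m1 <- fit_mlknn(inst$X, inst$Y, mlknn_config(k = 9))
  perm <- sample(10)
  m2 <- fit_mlknn(inst$X[perm, ], inst$Y[perm, ], mlknn_config(k = 9))
  expect_equal(m1$prior1, m2$prior1, tolerance = 1e-12)
  expect_equal(m1$post_pos, m2$post_pos, tolerance = 1e-12)
  expect_equal(m1$post_neg, m2$post_neg, tolerance = 1e-12)
})

test_that("a label carried by every training drug always scores above 0.5", {
  set.seed(3)
  n <- 8
  X <- matrix(rbinom(n * 4, 1, 0.5), n, 4)
  Y <- cbind(rep(1L, n), rbinom(n, 1, 0.5))
  m <- fit_mlknn(X, Y, mlknn_config(k = n - 1))
  Q <- matrix(rbinom(5 * 4, 1, 0.5), 5, 4)
  expect_true(all(predict(m, Q)[, 1] > 0.5))
})

test_that("degenerate and symmetric posteriors give limiting scores", {
  inst <- random_instance(6, 3, 2, seed = 5)
  m <- fit_mlknn(inst$X, inst$Y, mlknn_config(k = 2))
  # symmetric: equal priors and identical posteriors -> score 0.5 everywhere
  m$prior1[] <- 0.5
  m$post_neg <- m$post_pos
  S <- predict(m, inst$X)
  expect_true(all(abs(S - 0.5) < 1e-15))
  # MAP labels follow the score > 0.5 rule
  m2 <- fit_mlknn(inst$X, inst$Y, mlknn_config(k = 2))
  expect_identical(predict(m2, inst$X, type = "label"),
                   (predict(m2, inst$X) > 0.5) * 1L)
  expect_error(predict(m2, matrix(1, 1, 5)), "dims")
})
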