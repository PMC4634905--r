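test_that("micro AUPR matches hand-enumerated and limiting cases", {
  expect_equal(micro_aupr(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0)),
               (1 / 2) * (1 / 1 + 2 / 3))
  expect_equal(micro_aupr(c(0.9, 0.8, 0.3), c(1, 1, 0)), 1)   # perfect
  expect_equal(micro_aupr(c(0.2, 0.9), c(1, 1)), 1)           # all positive
  expect_error(micro_aupr(c(0.2, 0.9), c(0, 0)), "undefined")
  # one fully tied block accrues positives at uniform rate: AUPR = prevalence
  expect_equal(micro_aupr(rep(0.5, 4), c(1, 0, 1, 0)), 0.5)
})

test_that("micro AUC matches concordant-pair counting", {
  expect_equal(micro_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(micro_auc(rep(0.3, 4), c(1, 0, 1, 0)), 0.5)
  for (seed in 1:10) {
    set.seed(seed)
    s <- sample(seq(0, 1, 0.1), 20, replace = TRUE)  # with ties
    y <- rbinom(20, 1, 0.4)
    if (sum(y) %in% c(0, 20)) next
    expect_equal(micro_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("ranking metrics reproduce the worked single-instance examples", {
  r <- ranking_metrics(matrix(c(0.9, 0.1), 1), matrix(c(0, 1), 1))
  expect_equal(r$one_error, 1)
  expect_equal(r$ranking_loss, 1)
  expect_equal(r$coverage, 1)
  expect_equal(r$average_precision, 0.5)
  # relevant label ranked last among 3 -> coverage 2
  r2 <- ranking_metrics(matrix(c(0.9, 0.5, 0.1), 1), matrix(c(0, 0, 1), 1))
  expect_equal(r2$coverage, 2)
  # perfect ranking
  r3 <- ranking_metrics(matrix(c(0.9, 0.5, 0.1), 1), matrix(c(1, 1, 0), 1))
  expect_equal(r3$one_error, 0)
  expect_equal(r3$ranking_loss, 0)
  expect_equal(r3$average_precision, 1)
})

test_that("all seven metrics match brute-force definitions on random data", {
  for (seed in 1:200) {
    set.seed(seed)
    n <- sample(2:10, 1); q <- sample(2:6, 1)
    S <- matrix(runif(n * q), n, q)      # continuous: ties a.s. absent
    Y <- matrix(rbinom(n * q, 1, 0.35), n, q)
    if (sum(Y) == 0 || sum(Y) == n * q) next
    expect_equal(micro_aupr(S, Y), oracle_aupr(as.vector(S), as.vector(Y)),
                 tolerance = 1e-12)
    expect_equal(micro_auc(S, Y), oracle_auc(as.vector(S), as.vector(Y)),
                 tolerance = 1e-12)
    expect_equal(hamming_loss(S, Y), mean((S > 0.5) != (Y == 1)),
                 tolerance = 1e-12)
    got <- ranking_metrics(S, Y)
    want <- oracle_ranking(S, Y)
    for (m in names(want)) expect_equal(got[[m]], want[[m]],
                                        tolerance = 1e-12, label = m)
  }
})

test_that("hamming loss counts elementwise disagreement of MAP labels", {
  expect_equal(hamming_loss(matrix(c(1, 0), 1), matrix(c(0, 1), 1)), 1)
  expect_equal(hamming_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 0)
  expect_error(hamming_loss(matrix(1, 1, 2), matrix(1, 2, 2)), "shapes")
})

test_that("per-label AUPR flags zero-positive labels as undefined", {
  S <- cbind(c(0.9, 0.1), c(0.2, 0.8), c(0.5, 0.6))
  Y <- cbind(c(1, 0), c(0, 0), c(0, 1))
  pl <- per_label_aupr(S, Y)
  expect_equal(unname(pl[1]), 1)
  expect_true(is.na(pl[2]))
  expect_equal(unname(pl[3]), 1)
})

test_that("compare_methods counts wins/ties/losses over defined labels", {
  a <- c(0.5, 0.5, 0.9); b <- c(0.4, 0.5, 1.0)
  expect_equal(unname(compare_methods(a, b)), c(1, 1, 1))
  expect_equal(unname(compare_methods(a, a)), c(0, 3, 0))
  expect_equal(sum(compare_methods(a, b)), 3)
  expect_error(compare_methods(c(1, NA), c(1, 0.5)), "defined label sets")
})

test_that("top-N recall matches brute-force set intersection", {
  S <- matrix(c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05, 0.6, 0.5), 1)
  Y <- matrix(c(1, 1, 0, 1, 0, 0, 1, 0), 1)   # 4 relevant, 3 in top 4
  expect_equal(topn_recall(S, Y, 4)$per_drug[[1]], 0.75)
  expect_equal(topn_recall(S, Y, 8)$mean, 1)
  for (seed in 1:10) {
    set.seed(seed)
    S <- matrix(runif(40), 5, 8)
    Y <- matrix(rbinom(40, 1, 0.3), 5, 8)
    nt <- sample(1:8, 1)
    got <- topn_recall(S, Y, nt)$per_drug
    for (i in 1:5) {
      rel <- which(Y[i, ] == 1)
      if (!length(rel)) expect_true(is.na(got[i]))
      else expect_equal(got[[i]],
                        length(intersect(order(-S[i, ])[1:nt], rel)) /
                          length(rel))
    }
  }
})

test_that("random scores concentrate micro AUPR near positive prevalence", {
  set.seed(99)
  vals <- replicate(100, {
    y <- c(rep(1, 10), rep(0, 90))
    micro_aupr(runif(100), y)
  })
  # random rankings sit slightly above prevalence (finite-sample AP bias)
  expect_gt(mean(vals), 0.1)
  expect_lt(mean(vals), 0.17)
})

test_that("coverage of a perfect ranker equals mean relevant count minus 1", {
  set.seed(12)
  Y <- matrix(rbinom(30, 1, 0.5), 5, 6)
  Y[rowSums(Y) == 0, 1] <- 1
  S <- Y + matrix(runif(30), 5, 6) * 0.5   # relevant always on top
  expect_equal(ranking_metrics(S, Y)$coverage, mean(rowSums(Y)) - 1)
})

test_that("evaluation report collects consistent fields", {
  set.seed(4)
  S <- matrix(runif(40), 5, 8)
  Y <- matrix(rbinom(40, 1, 0.4), 5, 8)
  rep_ <- evaluate_scores(S, Y)
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(rep_$aupr, micro_aupr(S, Y))
  expect_equal(rep_$n_labels_evaluated, sum(colSums(Y) > 0))
  expect_true(rep_$coverage >= 0 && rep_$coverage <= 7)
})
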