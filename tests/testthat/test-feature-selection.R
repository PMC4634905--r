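test_that("mutual information matches hand values and the 2x2 oracle", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(mutual_information(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0)
  expect_error(mutual_information(c(0, 1), c(0, 1, 1)), "length")
  for (seed in 1:20) {
    set.seed(seed)
    x <- rbinom(20, 1, 0.5); y <- rbinom(20, 1, 0.3)
    expect_equal(mutual_information(x, y), oracle_mi(x, y),
                 tolerance = 1e-12)
    # symmetry and entropy bound
    expect_equal(mutual_information(x, y), mutual_information(y, x),
                 tolerance = 1e-12)
    ent <- function(v) {
      p <- mean(v)
      if (p %in% c(0, 1)) 0 else -p * log2(p) - (1 - p) * log2(1 - p)
    }
    expect_lte(mutual_information(x, y), min(ent(x), ent(y)) + 1e-12)
    expect_gte(mutual_information(x, y), 0)
  }
})

test_that("mi_filter selects by strict threshold on the per-dimension max", {
  # three dims engineered to give low / medium / high MI against two labels
  X <- cbind(d1 = c(0, 1, 0, 1, 0, 1), d2 = c(1, 1, 1, 0, 0, 0),
             d3 = c(1, 1, 0, 0, 1, 0))
  Y <- cbind(l1 = c(0, 0, 0, 1, 1, 1), l2 = c(1, 1, 1, 0, 0, 0))
  ms <- mi_filter(X, Y, sigma = 0.001)
  # per-dim score is the max over labels; d2 matches l1/l2 perfectly
  expect_equal(unname(ms$scores["d2"]), 1)
  expect_equal(unname(ms$scores["d1"]),
               max(oracle_mi(X[, 1], Y[, 1]), oracle_mi(X[, 1], Y[, 2])))
  expect_true(all(ms$scores[ms$selected] > 0.001))
  expect_identical(ms$selected, ms$dim_ids[ms$scores > 0.001])
  # vectorised scores equal per-pair oracle maxima
  for (d in 1:3)
    expect_equal(unname(ms$scores[d]),
                 max(sapply(1:2, function(l) oracle_mi(X[, d], Y[, l]))),
                 tolerance = 1e-12)
})

test_that("empty MI selection falls back to the top decile with a warning", {
  X <- matrix(0L, 20, 12)  # constant columns: MI = 0 for every dimension
  colnames(X) <- paste0("d", 1:12)
  Y <- cbind(rbinom(20, 1, 0.5))
  expect_warning(ms <- mi_filter(X, Y, sigma = 0.001), "falling back")
  expect_length(ms$selected, ceiling(12 / 10))
})

test_that("GA wrapper on a single candidate dimension keeps it", {
  set.seed(2)
  X <- matrix(rbinom(40, 1, 0.5), 40, 1, dimnames = list(NULL, "only"))
  Y <- cbind(X[, 1], rbinom(40, 1, 0.2))
  sel <- ga_select_dims(X, Y, ga = ga_config(population_size = 10,
                                             max_generations = 5), seed = 1)
  expect_identical(sel$chosen_dims, "only")
  expect_true(all(diff(sel$trace) >= 0))
})

test_that("fs_mlknn model has five submodels over the chosen dimensions", {
  set.seed(5)
  gen <- generate_dataset(synthetic_spec(
    n_drugs = 60L,
    feature_specs = list(f = list(p = 12L, density = 0.2,
                                  n_informative = 2L)),
    q_labels = 6L), seed = 5)
  b <- gen$bundle
  fit <- fit_fs_mlknn(b$features$f, b$labels,
                      ga = ga_config(population_size = 10,
                                     max_generations = 4),
                      mlknn = mlknn_config(k = 3), seed = 9)
  expect_length(fit$submodels, 5)
  expect_true(all(fit$chosen_dims %in% fit$candidate_dims))
  expect_true(length(fit$chosen_dims) >= 1)
  expect_identical(sort(unique(fit$fold_assignment)), 1:5)
  for (sm in fit$submodels)
    expect_identical(sm$dim_ids, fit$chosen_dims)
  expect_error(fit_fs_mlknn(b$features$f$values[1:8, ],
                            b$labels$values[1:8, ]), "at least 10")
})

test_that("fs_mlknn prediction is the mean of the five submodel scores", {
  set.seed(6)
  gen <- generate_dataset(synthetic_spec(
    n_drugs = 50L,
    feature_specs = list(f = list(p = 10L, density = 0.2,
                                  n_informative = 2L)),
    q_labels = 5L), seed = 6)
  b <- gen$bundle
  fit <- fit_fs_mlknn(b$features$f, b$labels,
                      ga = ga_config(population_size = 8,
                                     max_generations = 3),
                      mlknn = mlknn_config(k = 3), seed = 2)
  Q <- b$features$f$values[1:7, ]
  manual <- Reduce(`+`, lapply(fit$submodels, function(sm)
    predict(sm, Q[, fit$chosen_dims, drop = FALSE]))) / 5
  expect_equal(predict(fit, Q), manual, tolerance = 1e-12)
  expect_error(predict(fit, Q[, 1, drop = FALSE]), "missing chosen")
})

test_that("selection pipeline is reproducible bit-for-bit under a seed", {
  gen <- generate_dataset(synthetic_spec(
    n_drugs = 50L,
    feature_specs = list(f = list(p = 10L, density = 0.2,
                                  n_informative = 2L)),
    q_labels = 5L), seed = 3)
  b <- gen$bundle
  cfg <- ga_config(population_size = 8, max_generations = 3)
  f1 <- fit_fs_mlknn(b$features$f, b$labels, ga = cfg,
                     mlknn = mlknn_config(k = 3), seed = 42)
  f2 <- fit_fs_mlknn(b$features$f, b$labels, ga = cfg,
                     mlknn = mlknn_config(k = 3), seed = 42)
  expect_identical(f1$chosen_dims, f2$chosen_dims)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$fold_assignment, f2$fold_assignment)
})

test_that("dim_frequency counts folds per dimension consistently", {
  mk <- function(cand, chosen) structure(
    list(candidate_dims = cand, chosen_dims = chosen), class = "fs_mlknn")
  models <- list(mk(c("a", "b", "c"), c("a", "b")),
                 mk(c("a", "b", "c"), "a"),
                 mk(c("a", "b", "c"), c("a", "c")))
  df <- dim_frequency(models)
  expect_equal(unname(df$frequency), c(3L, 1L, 1L))
  expect_true(all(df$frequency <= length(models)))
  expect_equal(sum(df$frequency), sum(df$per_fold_count))
})
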