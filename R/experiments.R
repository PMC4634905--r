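#' Cross-validation plan
#'
#' Seeded random partition of the drugs into `n_folds` near-equal subsets,
#' repeated `n_repeats` times (fresh partition per repeat).  Any remainder
#' drugs (`n mod n_folds`) are spread one per fold.
#'
#' @param n_drugs number of drugs to partition.
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats independent repeats (default 1).
#' @param seed integer seed.
#' @return An object of class `cv_plan` with `assignment`, an
#'   `n_drugs x n_repeats` integer matrix of fold labels.
#' @export
cv_plan <- function(n_drugs, n_folds = 5L, n_repeats = 1L, seed = 1L) {
  stopifnot(n_drugs >= n_folds, n_folds >= 2L, n_repeats >= 1L)
  set.seed(seed)
  assignment <- vapply(seq_len(n_repeats),
                       function(r) make_folds(n_drugs, n_folds),
                       integer(n_drugs))
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 assignment = matrix(assignment, n_drugs, n_repeats)),
            class = "cv_plan")
}

#' Run repeated cross-validation of MLKNN, FS-MLKNN or the ensemble
#'
#' The outer evaluation protocol: per repeat, the drugs are split into five
#' subsets; each subset in turn is held out while the model — including any
#' feature selection and ensemble weight fitting — is built on the other
#' four, then scores the held-out drugs.  The out-of-fold scores of a repeat
#' are pooled and evaluated once with the full metric suite; metrics are
#' aggregated as mean and standard deviation across repeats.  Feature
#' selection is re-run independently in every outer fold, so each fold can
#' choose a different dimension subset.
#'
#' @param bundle a [align_bundle()] dataset bundle.
#' @param method `"mlknn"`, `"fs_mlknn"` or `"ensemble"`.
#' @param plan a [cv_plan()] over `nrow` of the bundle.
#' @param feature feature-type name used by `"mlknn"`/`"fs_mlknn"`
#'   (default: the first feature table); ignored by `"ensemble"`.
#' @param sigma,fs_ga,mlknn,weight_ga configs forwarded to the fitters.
#' @return An object of class `run_manifest`: per-repeat
#'   [evaluate_scores()] reports and out-of-fold score matrices, per-fold
#'   chosen dimensions / ensemble weights where applicable, and a `summary`
#'   matrix of metric means and sds across repeats.
#' @export
run_cv <- function(bundle, method = c("mlknn", "fs_mlknn", "ensemble"),
                   plan, feature = NULL, sigma = 0.001,
                   fs_ga = ga_config(), mlknn = mlknn_config(),
                   weight_ga = ga_config()) {
  method <- match.arg(method)
  stopifnot(inherits(bundle, "dataset_bundle"), inherits(plan, "cv_plan"))
  Y <- bundle$labels$values
  n <- nrow(Y)
  stopifnot(nrow(plan$assignment) == n)
  if (is.null(feature)) feature <- names(bundle$features)[1L]
  drug_ids <- bundle$labels$drug_ids
  repeats <- vector("list", plan$n_repeats)
  for (r in seq_len(plan$n_repeats)) {
    folds <- plan$assignment[, r]
    oof <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
    fold_detail <- vector("list", plan$n_folds)
    for (f in seq_len(plan$n_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      if (length(intersect(tr, te)))
        stop("leakage guard: a test drug appears in the training fold",
             call. = FALSE)
      fit_seed <- plan$seed + 7919L * r + 104729L * f
      detail <- list(fold = f, n_train = length(tr), n_test = length(te))
      if (method == "mlknn") {
        X <- bundle$features[[feature]]$values
        fit <- fit_mlknn(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], mlknn)
        oof[te, ] <- predict(fit, X[te, , drop = FALSE])
      } else if (method == "fs_mlknn") {
        X <- bundle$features[[feature]]$values
        fit <- fit_fs_mlknn(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                            sigma = sigma, ga = fs_ga, mlknn = mlknn,
                            seed = fit_seed)
        oof[te, ] <- predict(fit, X[te, , drop = FALSE])
        detail$chosen_dims <- fit$chosen_dims
      } else {
        sub <- structure(list(
          features = lapply(bundle$features, function(ft)
            feature_table(ft$values[tr, , drop = FALSE],
                          drug_ids = drug_ids[tr], dim_ids = ft$dim_ids,
                          feature_name = ft$feature_name)),
          labels = label_table(Y[tr, , drop = FALSE],
                               drug_ids = drug_ids[tr],
                               label_ids = bundle$labels$label_ids)),
          class = "dataset_bundle")
        fit <- fit_ensemble(sub, sigma = sigma, fs_ga = fs_ga,
                            mlknn = mlknn, weight_ga = weight_ga,
                            seed = fit_seed)
        query <- lapply(bundle$features, function(ft)
          ft$values[te, , drop = FALSE])
        oof[te, ] <- predict(fit, query)
        detail$weights <- fit$weights
        detail$chosen_dims <- lapply(fit$base_models, `[[`, "chosen_dims")
      }
      fold_detail[[f]] <- detail
    }
    if (anyNA(oof))
      stop("internal error: out-of-fold scores do not cover every drug",
           call. = FALSE)
    repeats[[r]] <- list(report = evaluate_scores(oof, Y), scores = oof,
                         folds = folds, fold_detail = fold_detail)
  }
  metric_names <- c("aupr", "auc", "hamming_loss", "ranking_loss",
                    "one_error", "coverage", "average_precision")
  M <- vapply(repeats, function(rr)
    unlist(rr$report[metric_names]), numeric(length(metric_names)))
  M <- matrix(M, length(metric_names), plan$n_repeats,
              dimnames = list(metric_names, NULL))
  summary <- cbind(mean = rowMeans(M),
                   sd = apply(M, 1L, stats::sd))
  structure(list(method = method, feature = feature, plan = plan,
                 sigma = sigma, mlknn = mlknn, fs_ga = fs_ga,
                 weight_ga = weight_ga, repeats = repeats,
                 summary = summary),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: %s, %d repeat(s) of %d-fold CV (seed %d)\n",
              x$method, x$plan$n_repeats, x$plan$n_folds, x$plan$seed))
  print(round(x$summary, 4))
  invisible(x)
}

#' Independent train/test experiment
#'
#' Emulates the prospective setting: the ensemble is fitted on the training
#' drugs only, then scores a disjoint set of test drugs.  Besides the pooled
#' AUPR/AUC, reports the top-N recall per test drug — the fraction of a
#' drug's known side effects recovered among its N highest-scored terms —
#' which measures how useful the ranked list is for prioritising wet-lab
#' verification.
#'
#' @param train_bundle,test_bundle [align_bundle()] bundles over disjoint
#'   drug sets but identical feature dimensions and label sets.
#' @param n_top integer vector of list sizes for the recall computation.
#' @param sigma,fs_ga,mlknn,weight_ga configs forwarded to [fit_ensemble()].
#' @param seed integer seed.
#' @return An object of class `independent_manifest`: the fitted `model`,
#'   test `scores`, `aupr`, `auc`, `recall` (one [topn_recall()] result per
#'   `n_top`), and `per_drug` counts of known and correctly recovered side
#'   effects at the first `n_top`.
#' @export
run_independent <- function(train_bundle, test_bundle, n_top = c(100L, 200L),
                            sigma = 0.001, fs_ga = ga_config(),
                            mlknn = mlknn_config(), weight_ga = ga_config(),
                            seed = 1L) {
  stopifnot(inherits(train_bundle, "dataset_bundle"),
            inherits(test_bundle, "dataset_bundle"))
  if (length(intersect(train_bundle$labels$drug_ids,
                       test_bundle$labels$drug_ids)))
    stop("training and testing drug sets overlap", call. = FALSE)
  if (!identical(train_bundle$labels$label_ids,
                 test_bundle$labels$label_ids))
    stop("training and testing label sets differ", call. = FALSE)
  n_top <- pmin(as.integer(n_top), ncol(test_bundle$labels$values))
  model <- fit_ensemble(train_bundle, sigma = sigma, fs_ga = fs_ga,
                        mlknn = mlknn, weight_ga = weight_ga, seed = seed)
  scores <- predict(model, test_bundle$features)
  Yte <- test_bundle$labels$values
  recalls <- lapply(n_top, function(nt) topn_recall(scores, Yte, nt))
  names(recalls) <- paste0("top", n_top)
  known <- rowSums(Yte)
  per_drug <- data.frame(drug_id = test_bundle$labels$drug_ids,
                         n_known = known,
                         n_recovered = round(recalls[[1L]]$per_drug * known),
                         recall = recalls[[1L]]$per_drug,
                         row.names = NULL)
  structure(list(model = model, scores = scores,
                 aupr = micro_aupr(scores, Yte),
                 auc = micro_auc(scores, Yte),
                 recall = recalls, per_drug = per_drug,
                 mean_labels_train = mean(rowSums(train_bundle$labels$values)),
                 mean_labels_test = mean(known), seed = seed),
            class = "independent_manifest")
}

#' @export
print.independent_manifest <- function(x, ...) {
  cat(sprintf("independent_manifest: AUPR %.4f, AUC %.4f\n", x$aupr, x$auc))
  for (nm in names(x$recall))
    cat(sprintf("  mean recall @ %s: %.3f\n", sub("top", "", nm),
                x$recall[[nm]]$mean))
  invisible(x)
}
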