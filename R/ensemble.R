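#' Weighted combination of base score matrices
#'
#' The weighted-scoring ensemble rule: the final score matrix is the linear
#' combination `sum_i w_i S_i` of the base predictors' score matrices.
#'
#' @param weights numeric vector of non-negative weights (one per base
#'   predictor); callers normally supply simplex weights summing to 1.
#' @param base_scores list of numeric score matrices of identical shape.
#' @return Numeric matrix of the combined scores.
#' @export
weighted_score <- function(weights, base_scores) {
  stopifnot(is.list(base_scores), length(base_scores) >= 1L)
  if (length(weights) != length(base_scores))
    stop("one weight per base score matrix required", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  d <- dim(base_scores[[1L]])
  for (S in base_scores)
    if (!identical(dim(S), d))
      stop("base score matrices differ in shape", call. = FALSE)
  out <- matrix(0, d[1L], d[2L], dimnames = dimnames(base_scores[[1L]]))
  for (i in seq_along(weights)) out <- out + weights[i] * base_scores[[i]]
  out
}

#' Fit a weighted-scoring ensemble of FS-MLKNN base predictors
#'
#' Fits one FS-MLKNN model per feature type on the training drugs (all base
#' models share the same seeded internal 5-fold partition), then tunes the
#' combination weights with a simplex-encoded GA.  The GA fitness of a
#' weight vector is the micro-AUPR of the weighted sum of the bases'
#' *out-of-fold* scores — each drug scored by the submodel whose internal
#' fold held it out — so the weights reward generalisation rather than
#' resubstitution fit.  With a single feature type the weight is 1 and no
#' GA runs.
#'
#' @param bundle a [align_bundle()] dataset bundle (training drugs).
#' @param sigma MI filter threshold passed to [fit_fs_mlknn()].
#' @param fs_ga [ga_config()] for the dimension-selection GA.
#' @param mlknn [mlknn_config()] for the base learners.
#' @param weight_ga [ga_config()] for the weight-tuning GA.
#' @param seed integer seed.
#' @return An object of class `se_ensemble`: `base_models` (named list of
#'   `fs_mlknn`), `weights` (named, on the simplex), `fold_assignment`,
#'   `oof_aupr` (fitness of the chosen weights).
#' @export
fit_ensemble <- function(bundle, sigma = 0.001, fs_ga = ga_config(),
                         mlknn = mlknn_config(), weight_ga = ga_config(),
                         seed = NULL) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  m <- length(bundle$features)
  Y <- bundle$labels$values
  n <- nrow(Y)
  if (!is.null(seed)) set.seed(seed)
  folds <- make_folds(n)
  feature_seeds <- sample.int(2^30, m)
  ga_seed <- sample.int(2^30, 1L)
  base_models <- vector("list", m)
  names(base_models) <- names(bundle$features)
  oof <- vector("list", m)
  for (i in seq_len(m)) {
    ft <- bundle$features[[i]]
    base_models[[i]] <- fit_fs_mlknn(ft, bundle$labels, sigma = sigma,
                                     ga = fs_ga, mlknn = mlknn,
                                     seed = feature_seeds[i],
                                     fold_assignment = folds)
    # out-of-fold base scores: submodel f scores the drugs of fold f
    chosen <- base_models[[i]]$chosen_dims
    S <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
    for (f in seq_len(5L)) {
      te <- folds == f
      S[te, ] <- predict(base_models[[i]]$submodels[[f]],
                         ft$values[te, chosen, drop = FALSE])
    }
    oof[[i]] <- S
  }
  if (m == 1L) {
    w <- 1
    oof_aupr <- micro_aupr(oof[[1L]], Y)
  } else {
    fitness <- function(w) micro_aupr(weighted_score(w, oof), Y)
    res <- ga_maximize(fitness, length = m, encoding = "simplex",
                       config = weight_ga, seed = ga_seed)
    w <- res$best_chromosome
    oof_aupr <- res$best_fitness
  }
  names(w) <- names(bundle$features)
  structure(list(base_models = base_models, weights = w,
                 fold_assignment = folds, oof_aupr = oof_aupr),
            class = "se_ensemble")
}

#' @export
print.se_ensemble <- function(x, ...) {
  cat(sprintf("se_ensemble: %d base predictor(s); out-of-fold AUPR %.4f\n",
              length(x$base_models), x$oof_aupr))
  for (nm in names(x$weights))
    cat(sprintf("  %-14s w = %.3f (%d dims)\n", nm, x$weights[nm],
                length(x$base_models[[nm]]$chosen_dims)))
  invisible(x)
}

#' Predict with a weighted-scoring ensemble
#'
#' @param object fitted `se_ensemble`.
#' @param query named list of [feature_table()] (or binary matrices), one
#'   per feature type in the model, over identical drugs in identical order.
#' @param ... unused.
#' @return Numeric score matrix, query drugs x labels.
#' @export
predict.se_ensemble <- function(object, query, ...) {
  if (inherits(query, "dataset_bundle")) query <- query$features
  if (inherits(query, "feature_table")) query <- list(query)
  miss <- setdiff(names(object$base_models), names(query))
  if (length(miss))
    stop("query is missing feature type(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  scores <- lapply(names(object$base_models), function(nm)
    predict(object$base_models[[nm]], query[[nm]]))
  weighted_score(object$weights, scores)
}
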