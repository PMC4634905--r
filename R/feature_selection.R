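#' Mutual information between two binary vectors
#'
#' Plug-in mutual information over the empirical 2x2 joint distribution,
#' `I = sum_{x,y} p(x,y) log p(x,y) / (p(x) p(y))`; cells with `p(x,y) = 0`
#' contribute 0.  Symmetric and non-negative.
#'
#' @param x,y binary vectors of equal length.
#' @param base logarithm base (2 = bits, the default).
#' @return Non-negative scalar.
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
#' mutual_information(c(0, 1, 0, 1), c(0, 0, 1, 1))  # 0
#' @export
mutual_information <- function(x, y, base = 2) {
  if (length(x) != length(y))
    stop("vectors differ in length", call. = FALSE)
  if (length(x) < 1L) stop("vectors must be nonempty", call. = FALSE)
  if (any(!(x %in% c(0, 1))) || any(!(y %in% c(0, 1))))
    stop("inputs must be binary", call. = FALSE)
  n <- length(x)
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1) - n11
  n01 <- sum(y == 1) - n11; n00 <- n - n11 - n10 - n01
  joint <- c(n00, n01, n10, n11) / n
  px <- c(n00 + n01, n00 + n01, n10 + n11, n10 + n11) / n
  py <- c(n00 + n10, n01 + n11, n00 + n10, n01 + n11) / n
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / (px[nz] * py[nz]), base = base))
}

#' Mutual-information filter over feature dimensions
#'
#' Stage 1 of FS-MLKNN.  Scores each feature dimension v by its strongest
#' pairwise association with any side-effect term,
#' `I(v; D) = max_j I(v; d_j)`, and selects the dimensions whose score
#' strictly exceeds the threshold `sigma` (0.001 in the reference protocol).
#' If no dimension passes, the top ceiling(p/10) dimensions by score are
#' retained instead, with a warning.
#'
#' @param features [feature_table()] aligned with `labels`.
#' @param labels [label_table()].
#' @param sigma selection threshold on the MI score.
#' @param base logarithm base for the MI (default 2).
#' @return An object of class `mi_scores`: `dim_ids`, `scores` (named, in
#'   dimension order), `sigma`, `selected` (dimension ids, order preserved).
#' @export
mi_filter <- function(features, labels, sigma = 0.001, base = 2) {
  X <- table_values(features); Y <- table_values(labels)
  if (nrow(X) != nrow(Y))
    stop("features and labels are not aligned", call. = FALSE)
  n <- nrow(X)
  a <- colSums(X); b <- colSums(Y)
  n11 <- crossprod(X, Y)                       # p x q
  n10 <- a - n11
  n01 <- matrix(b, ncol(X), ncol(Y), byrow = TRUE) - n11
  n00 <- n - n11 - n10 - n01
  mi_term <- function(nxy, nx, ny) {
    out <- nxy / n * log((nxy * n) / (nx * ny), base = base)
    out[!is.finite(out) | nxy == 0] <- 0
    out
  }
  rx1 <- matrix(a, ncol(X), ncol(Y)); rx0 <- n - rx1
  cy1 <- matrix(b, ncol(X), ncol(Y), byrow = TRUE); cy0 <- n - cy1
  MI <- mi_term(n00, rx0, cy0) + mi_term(n01, rx0, cy1) +
        mi_term(n10, rx1, cy0) + mi_term(n11, rx1, cy1)
  scores <- apply(MI, 1L, max)
  names(scores) <- colnames(X)
  sel <- names(scores)[scores > sigma]
  if (length(sel) == 0L) {
    n_keep <- ceiling(ncol(X) / 10)
    warning("no dimension exceeds sigma = ", sigma, "; falling back to the ",
            n_keep, " highest-scoring dimension(s)", call. = FALSE)
    keep <- order(-scores, seq_along(scores))[seq_len(n_keep)]
    sel <- names(scores)[sort(keep)]
  }
  structure(list(dim_ids = colnames(X), scores = scores, sigma = sigma,
                 selected = sel),
            class = "mi_scores")
}

#' @export
print.mi_scores <- function(x, ...) {
  cat(sprintf("mi_scores: %d/%d dimensions selected at sigma = %g\n",
              length(x$selected), length(x$dim_ids), x$sigma))
  invisible(x)
}

make_folds <- function(n, n_folds = 5L) {
  sample(rep(seq_len(n_folds), length.out = n))
}

cv_oof_aupr <- function(X, Y, folds, config) {
  n_folds <- max(folds)
  oof <- matrix(NA_real_, nrow(X), ncol(Y))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    m <- fit_mlknn(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], config)
    oof[!tr, ] <- predict(m, X[!tr, , drop = FALSE])
  }
  micro_aupr(oof, Y)
}

#' GA-wrapper selection of feature dimensions
#'
#' Stage 2 of FS-MLKNN.  Dimension subsets of the MI-filtered candidate set
#' are encoded as binary chromosomes; the fitness of a chromosome is the
#' internal 5-fold cross-validated micro-AUPR of an MLKNN model restricted
#' to its dimensions (folds drawn once per run, so fitness is deterministic
#' within the run).  The all-zero chromosome has fitness 0.
#'
#' @param features [feature_table()] already restricted to the candidate
#'   dimensions (e.g. `mi_filter(...)$selected`).
#' @param labels [label_table()] aligned with `features`.
#' @param ga a [ga_config()]; the reference protocol uses population 100,
#'   max 60 generations, tolerance 1e-6.
#' @param mlknn an [mlknn_config()].
#' @param seed integer seed controlling folds and GA randomness.
#' @param fold_assignment optional integer vector of internal fold labels
#'   (1..5) per drug; drawn from `seed` when omitted.
#' @return List of class `ga_selection`: `chosen_dims` (ids), `trace`
#'   (best fitness per generation), `best_fitness`, `fold_assignment`,
#'   `candidate_dims`, `generations_run`.
#' @export
ga_select_dims <- function(features, labels, ga = ga_config(),
                           mlknn = mlknn_config(), seed = NULL,
                           fold_assignment = NULL) {
  X <- table_values(features); Y <- table_values(labels)
  p <- ncol(X)
  if (p < 1L) stop("no candidate dimensions", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fold_assignment)) fold_assignment <- make_folds(nrow(X))
  fitness <- function(chrom) {
    sel <- which(chrom > 0.5)
    if (length(sel) == 0L) return(0)
    cv_oof_aupr(X[, sel, drop = FALSE], Y, fold_assignment, mlknn)
  }
  res <- ga_maximize(fitness, length = p, encoding = "binary", config = ga)
  chosen <- colnames(X)[res$best_chromosome > 0.5]
  if (length(chosen) == 0L) chosen <- colnames(X)  # all-zero optimum: degenerate
  structure(list(chosen_dims = chosen, trace = res$trace,
                 best_fitness = res$best_fitness,
                 fold_assignment = fold_assignment,
                 candidate_dims = colnames(X),
                 generations_run = res$generations_run),
            class = "ga_selection")
}

#' Fit an FS-MLKNN model
#'
#' The full two-stage feature-selection MLKNN: (1) the mutual-information
#' filter keeps dimensions with `I(v; D) > sigma`; (2) a GA wrapper searches
#' subsets of the candidates, scoring each by internal 5-fold
#' cross-validated micro-AUPR of MLKNN.  The final model consists of five
#' MLKNN submodels, one per internal fold, each fitted on that fold's 4/5
#' training portion restricted to the chosen dimensions; predictions are the
#' average of the five submodels' scores.  The same internal folds drive the
#' GA fitness and the submodels.
#'
#' @param features training [feature_table()].
#' @param labels training [label_table()] aligned with `features`.
#' @param sigma MI filter threshold (default 0.001).
#' @param ga a [ga_config()].
#' @param mlknn an [mlknn_config()].
#' @param seed integer seed (internal folds + GA).
#' @param fold_assignment optional internal fold labels (1..5) per drug,
#'   e.g. to share folds across the base models of an ensemble; drawn from
#'   `seed` when omitted.
#' @return An object of class `fs_mlknn`: `candidate_dims`, `chosen_dims`,
#'   `submodels` (five `mlknn` fits), `fold_assignment`, `mi` (the
#'   [mi_filter()] result), `trace`, `best_fitness`, configs.
#' @export
fit_fs_mlknn <- function(features, labels, sigma = 0.001, ga = ga_config(),
                         mlknn = mlknn_config(), seed = NULL,
                         fold_assignment = NULL) {
  X <- table_values(features); Y <- table_values(labels)
  n <- nrow(X)
  if (n < 10L)
    stop("need at least 10 drugs to form 5 internal folds", call. = FALSE)
  mi <- mi_filter(features, labels, sigma = sigma)
  cand <- mi$selected
  Xc <- X[, cand, drop = FALSE]
  sel <- ga_select_dims(Xc, Y, ga = ga, mlknn = mlknn, seed = seed,
                        fold_assignment = fold_assignment)
  chosen <- sel$chosen_dims
  folds <- sel$fold_assignment
  submodels <- lapply(seq_len(5L), function(f) {
    tr <- folds != f
    fit_mlknn(X[tr, chosen, drop = FALSE], Y[tr, , drop = FALSE], mlknn)
  })
  structure(list(candidate_dims = cand, chosen_dims = chosen,
                 submodels = submodels, fold_assignment = folds,
                 mi = mi, trace = sel$trace, best_fitness = sel$best_fitness,
                 sigma = sigma, ga = ga, mlknn = mlknn,
                 feature_name = if (inherits(features, "feature_table"))
                   features$feature_name else "feature"),
            class = "fs_mlknn")
}

#' @export
print.fs_mlknn <- function(x, ...) {
  cat(sprintf("fs_mlknn model ('%s'): %d candidate dims -> %d chosen; internal 5-CV AUPR %.4f\n",
              x$feature_name, length(x$candidate_dims),
              length(x$chosen_dims), x$best_fitness))
  invisible(x)
}

#' Predict with an FS-MLKNN model
#'
#' Scores are the elementwise mean of the five internal-fold MLKNN
#' submodels' scores, computed on the query restricted to the chosen
#' dimensions.
#'
#' @param object fitted `fs_mlknn` model.
#' @param query [feature_table()] (or binary matrix) containing at least the
#'   chosen dimensions as named columns.
#' @param ... unused.
#' @return Numeric score matrix, query drugs x labels.
#' @export
predict.fs_mlknn <- function(object, query, ...) {
  Q <- table_values(query)
  miss <- setdiff(object$chosen_dims, colnames(Q))
  if (length(miss))
    stop("query is missing chosen dimension(s): ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  Qc <- Q[, object$chosen_dims, drop = FALSE]
  preds <- lapply(object$submodels, predict, query = Qc)
  Reduce(`+`, preds) / length(preds)
}

#' Selection frequency of dimensions across outer folds
#'
#' Given the FS-MLKNN models fitted in each outer cross-validation fold,
#' counts for every original dimension in how many folds it was chosen, and
#' reports the per-fold chosen-dimension counts.
#'
#' @param models list of `fs_mlknn` models (one per outer fold).
#' @param all_dims optional character vector of all original dimension ids;
#'   defaults to the union of the models' candidate dimensions.
#' @return List with `frequency` (named integer vector, 0..n_folds) and
#'   `per_fold_count` (chosen dimensions per fold).
#' @export
dim_frequency <- function(models, all_dims = NULL) {
  stopifnot(length(models) >= 1L)
  for (m in models) stopifnot(inherits(m, "fs_mlknn"))
  if (is.null(all_dims))
    all_dims <- unique(unlist(lapply(models, `[[`, "candidate_dims")))
  freq <- stats::setNames(integer(length(all_dims)), all_dims)
  for (m in models) {
    hit <- all_dims %in% m$chosen_dims
    freq[hit] <- freq[hit] + 1L
  }
  list(frequency = freq,
       per_fold_count = vapply(models, function(m)
         length(m$chosen_dims), 0L))
}
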