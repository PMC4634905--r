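#' MLKNN configuration
#'
#' @param k number of nearest neighbours (must stay below the number of
#'   training drugs at fit time).
#' @param s additive (Laplace-style) smoothing factor used in the prior and
#'   posterior frequency estimators; must be positive.
#' @param distance distance between binary drug vectors: `"euclidean"`
#'   (the original MLKNN convention; for binary data it orders pairs exactly
#'   as Hamming distance), `"jaccard"` or `"cosine"`.
#' @return An object of class `mlknn_config`.
#' @export
mlknn_config <- function(k = 5L, s = 1,
                         distance = c("euclidean", "jaccard", "cosine")) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (!is.numeric(s) || s <= 0) stop("s must be > 0", call. = FALSE)
  structure(list(k = k, s = s, distance = match.arg(distance)),
            class = "mlknn_config")
}

pairwise_distance <- function(query, train, distance) {
  query <- as.matrix(query); train <- as.matrix(train)
  cross <- tcrossprod(query, train)               # n_query x n_train
  rq <- rowSums(query); rt <- rowSums(train)
  switch(distance,
    euclidean = {
      d2 <- outer(rq, rt, `+`) - 2 * cross        # squared, binary: a+b-2ab
      d2[d2 < 0] <- 0
      sqrt(d2)
    },
    jaccard = {
      un <- outer(rq, rt, `+`) - cross
      d <- 1 - cross / un
      d[un == 0] <- 0                             # two empty vectors coincide
      d
    },
    cosine = {
      nn <- outer(sqrt(rq), sqrt(rt))
      d <- 1 - cross / nn
      d[nn == 0] <- 1
      d
    })
}

#' k-nearest-neighbour indices under a binary-vector distance
#'
#' Returns, for every query drug, the indices of its `k` nearest training
#' drugs.  Ties between equidistant training drugs are broken
#' deterministically in favour of the lower training-row index.  With
#' `exclude_self = TRUE` (used during fitting, when the query set *is* the
#' training set) row i never returns itself.
#'
#' @param train,query binary matrices with identical column count (rows =
#'   drugs).  [feature_table()] objects are accepted.
#' @param k neighbours to return; must not exceed the number of eligible
#'   training rows.
#' @param exclude_self logical; requires `nrow(query) == nrow(train)`.
#' @param distance see [mlknn_config()].
#' @return Integer matrix `nrow(query)` x `k` of training-row indices.
#' @export
knn_indices <- function(train, query, k, exclude_self = FALSE,
                        distance = "euclidean") {
  train <- table_values(train); query <- table_values(query)
  if (ncol(train) != ncol(query))
    stop("train and query dimension counts differ", call. = FALSE)
  k <- as.integer(k)
  eligible <- nrow(train) - as.integer(exclude_self)
  if (k < 1L || k > eligible)
    stop(sprintf("k = %d but only %d eligible training rows", k, eligible),
         call. = FALSE)
  D <- pairwise_distance(query, train, distance)
  if (exclude_self) {
    if (nrow(query) != nrow(train))
      stop("exclude_self requires query and train to be the same set",
           call. = FALSE)
    D[cbind(seq_len(nrow(D)), seq_len(nrow(D)))] <- Inf
  }
  nt <- ncol(D)
  res <- apply(D, 1L, function(d) order(d, seq_len(nt))[seq_len(k)])
  if (k == 1L) matrix(as.integer(res), ncol = 1L) else t(res)
}

#' Neighbour label membership counts
#'
#' For each query drug and each side-effect term, counts how many of the
#' drug's k nearest training neighbours carry the term: the membership
#' counting vector C_x(l) of MLKNN.
#'
#' @param neighbor_indices integer matrix from [knn_indices()].
#' @param train_labels binary matrix (or [label_table()]) of the training
#'   drugs' side effects.
#' @return Integer matrix n_query x q with values in 0..k.
#' @export
membership_counts <- function(neighbor_indices, train_labels) {
  Y <- table_values(train_labels)
  if (max(neighbor_indices) > nrow(Y) || min(neighbor_indices) < 1L)
    stop("neighbor index out of range", call. = FALSE)
  C <- matrix(0L, nrow(neighbor_indices), ncol(Y))
  for (j in seq_len(ncol(neighbor_indices)))
    C <- C + Y[neighbor_indices[, j], , drop = FALSE]
  C
}

#' Fit an MLKNN model
#'
#' The Bayesian multi-label k-nearest-neighbour learner.  For each
#' side-effect term l it estimates a smoothed prior
#' `P(H1_l) = (s + sum_i y_i(l)) / (2 s + n)` and, from the training drugs'
#' own neighbourhoods (each drug excluded from its own neighbour list),
#' smoothed likelihoods `P(Ej_l | H1_l)` / `P(Ej_l | H0_l)` of observing
#' exactly j label-positive drugs among the k nearest neighbours, given that
#' the drug does / does not carry the term:
#' `P(Ej_l | Hb_l) = (s + c_b[j]) / (s (k+1) + sum_j c_b[j])`,
#' where `c_1[j]` counts training drugs carrying l with exactly j
#' label-positive neighbours and `c_0[j]` the same among drugs lacking l.
#'
#' @param features training [feature_table()] (or binary matrix).
#' @param labels training [label_table()] (or binary matrix), rows aligned
#'   with `features`.
#' @param config an [mlknn_config()].
#' @return An object of class `mlknn` holding the smoothed priors, the two
#'   q x (k+1) posterior matrices, the raw counts, and the training features
#'   for neighbour search at prediction time.
#' @export
fit_mlknn <- function(features, labels, config = mlknn_config()) {
  X <- table_values(features); Y <- table_values(labels)
  if (nrow(X) != nrow(Y))
    stop("features and labels have different drug counts", call. = FALSE)
  if (inherits(features, "feature_table") && inherits(labels, "label_table") &&
      !identical(features$drug_ids, labels$drug_ids))
    stop("features and labels are not aligned on the same drugs",
         call. = FALSE)
  n <- nrow(X); q <- ncol(Y); k <- config$k; s <- config$s
  if (k >= n)
    stop(sprintf("k = %d must be smaller than the number of training drugs (%d)",
                 k, n), call. = FALSE)
  prior1 <- (s + colSums(Y)) / (s * 2 + n)
  nb <- knn_indices(X, X, k, exclude_self = TRUE, distance = config$distance)
  C <- membership_counts(nb, Y)
  c_pos <- c_neg <- matrix(0, q, k + 1L)
  for (j in 0:k) {
    hit <- (C == j)
    c_pos[, j + 1L] <- colSums(hit & (Y == 1L))
    c_neg[, j + 1L] <- colSums(hit & (Y == 0L))
  }
  post_pos <- (s + c_pos) / (s * (k + 1L) + rowSums(c_pos))
  post_neg <- (s + c_neg) / (s * (k + 1L) + rowSums(c_neg))
  structure(list(config = config, train_features = X, train_labels = Y,
                 prior1 = prior1, post_pos = post_pos, post_neg = post_neg,
                 c_pos = c_pos, c_neg = c_neg,
                 dim_ids = colnames(X), label_ids = colnames(Y)),
            class = "mlknn")
}

#' @export
print.mlknn <- function(x, ...) {
  cat(sprintf("mlknn model: n = %d drugs, p = %d dims, q = %d labels, k = %d, s = %g\n",
              nrow(x$train_features), ncol(x$train_features),
              length(x$prior1), x$config$k, x$config$s))
  invisible(x)
}

#' Predict side-effect scores with an MLKNN model
#'
#' For each query drug the model finds its k nearest training drugs, counts
#' label-positive neighbours C_t(l), and returns the normalised posterior
#' `P(H1) P(E_C | H1) / (P(H1) P(E_C | H1) + P(H0) P(E_C | H0))` as a
#' real-valued score in (0, 1).  The MAP label of the printed decision rule
#' is recoverable as score > 0.5 (an exact posterior tie maps to label 0).
#'
#' @param object fitted `mlknn` model.
#' @param query [feature_table()] (or binary matrix) over the same feature
#'   dimensions as the training data.
#' @param type `"score"` for the posterior scores, `"label"` for MAP 0/1
#'   labels.
#' @param ... unused.
#' @return Numeric (or integer for `"label"`) matrix, query drugs x labels.
#' @export
predict.mlknn <- function(object, query, type = c("score", "label"), ...) {
  type <- match.arg(type)
  Q <- table_values(query)
  if (ncol(Q) != ncol(object$train_features))
    stop(sprintf("query has %d dims but the model was trained on %d",
                 ncol(Q), ncol(object$train_features)), call. = FALSE)
  k <- object$config$k
  nb <- knn_indices(object$train_features, Q, k, exclude_self = FALSE,
                    distance = object$config$distance)
  C <- membership_counts(nb, object$train_labels)
  q <- length(object$prior1)
  m <- nrow(Q)
  idx <- cbind(rep(seq_len(q), each = m), as.vector(C) + 1L)
  pe1 <- matrix(object$post_pos[idx], m, q)
  pe0 <- matrix(object$post_neg[idx], m, q)
  num <- rep(object$prior1, each = m) * pe1
  den <- num + rep(1 - object$prior1, each = m) * pe0
  S <- matrix(num / den, m, q,
              dimnames = list(rownames(Q), object$label_ids))
  if (type == "label") (S > 0.5) * 1L else S
}

table_values <- function(x) {
  if (inherits(x, c("feature_table", "label_table"))) x$values else as.matrix(x)
}
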