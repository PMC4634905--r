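#' Micro-averaged area under the precision-recall curve
#'
#' Pools every drug-label pair into a single ranking and computes the
#' non-interpolated step AUPR (average-precision form): the sum, over
#' positives in descending-score order, of precision at that rank, divided by
#' the number of positives.  With severe label imbalance this is the primary
#' metric for side-effect prediction, because ROC AUC is inflated by the
#' overwhelming number of negative pairs.
#'
#' Tied scores are handled by treating each tied block as accumulating true
#' positives at a uniform rate, which reduces to the usual step formula when
#' scores are distinct.
#'
#' @param scores numeric matrix (or vector) of predicted scores.
#' @param truth binary matrix/vector of the same shape, or a [label_table()].
#' @return AUPR in \[0, 1\].
#' @examples
#' micro_aupr(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))  # 0.8333...
#' @export
micro_aupr <- function(scores, truth) {
  y <- as.vector(truth_matrix(truth, scores))
  s <- as.vector(as_score_input(scores))
  P <- sum(y)
  if (P == 0L) stop("micro_aupr is undefined: no positive drug-label pair",
                    call. = FALSE)
  ord <- order(-s)
  s <- s[ord]; y <- y[ord]
  # per tied block: gp positives among g items entering at uniform rate
  blk <- cumsum(!duplicated(s))
  g <- tabulate(blk)
  gp <- as.vector(rowsum(y, blk))
  tp0 <- c(0, cumsum(gp))[seq_along(g)]
  n0 <- c(0, cumsum(g))[seq_along(g)]
  ap <- 0
  for (b in seq_along(g)) {
    if (gp[b] == 0) next
    j <- seq_len(g[b])
    rate <- gp[b] / g[b]
    ap <- ap + sum(rate * (tp0[b] + j * rate) / (n0[b] + j))
  }
  ap / P
}

#' Micro-averaged area under the ROC curve
#'
#' Pools all drug-label pairs and computes the rank-sum (Wilcoxon) AUC with
#' midrank tie correction.
#'
#' @inheritParams micro_aupr
#' @return AUC in \[0, 1\].
#' @export
micro_auc <- function(scores, truth) {
  y <- as.vector(truth_matrix(truth, scores))
  s <- as.vector(as_score_input(scores))
  np <- sum(y); nn <- length(y) - np
  if (np == 0L || nn == 0L)
    stop("micro_auc is undefined: needs at least one positive and one negative",
         call. = FALSE)
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Instance-wise multi-label ranking metrics
#'
#' Computes the classic multi-label ranking metrics over per-drug score
#' vectors: one-error (fraction of drugs whose top-ranked label is not
#' relevant), coverage (mean number of steps down the ranked label list
#' needed to reach all relevant labels, i.e. max relevant rank minus 1,
#' unnormalised), ranking loss (mean fraction of relevant/irrelevant label
#' pairs ordered wrongly; ties count half), and average precision (mean, over
#' relevant labels, of the fraction of relevant labels at or above that
#' label's rank).
#'
#' Ranks are deterministic: ties are broken by label index.  Drugs with no
#' relevant label are skipped for one-error, ranking loss and average
#' precision (and drugs with all labels relevant are skipped for ranking
#' loss, which has no pairs there); they contribute a coverage of 0.
#'
#' @param scores numeric matrix, drugs x labels.
#' @param truth binary matrix of the same shape, or a [label_table()].
#' @return List with `one_error`, `coverage`, `ranking_loss`,
#'   `average_precision`.
#' @export
ranking_metrics <- function(scores, truth) {
  S <- as_score_input(scores)
  Y <- truth_matrix(truth, S)
  n <- nrow(S); q <- ncol(S)
  one_err <- rl <- ap <- numeric(0)
  cov <- numeric(n)
  for (i in seq_len(n)) {
    s <- S[i, ]; rel <- which(Y[i, ] == 1)
    nr <- length(rel)
    if (nr == 0L) { cov[i] <- 0; next }
    ord <- order(-s, seq_len(q))
    rnk <- integer(q); rnk[ord] <- seq_len(q)
    cov[i] <- max(rnk[rel]) - 1
    one_err <- c(one_err, as.numeric(!(ord[1L] %in% rel)))
    ap <- c(ap, mean(vapply(rel, function(u)
      sum(rnk[rel] <= rnk[u]) / rnk[u], 0)))
    if (nr < q) {
      irr <- setdiff(seq_len(q), rel)
      d <- outer(s[rel], s[irr], `-`)
      rl <- c(rl, (sum(d < 0) + 0.5 * sum(d == 0)) / (nr * (q - nr)))
    }
  }
  list(one_error = mean(one_err), coverage = mean(cov),
       ranking_loss = mean(rl), average_precision = mean(ap))
}

#' Hamming loss of hard label assignments
#'
#' Fraction of drug-label cells where the predicted binary label disagrees
#' with the truth.  Predicted labels follow the MAP rule: score > 0.5.
#'
#' @param predicted binary matrix of predicted labels, or a numeric score
#'   matrix (thresholded at > 0.5).
#' @param truth binary matrix of the same shape, or a [label_table()].
#' @export
hamming_loss <- function(predicted, truth) {
  P <- as_score_input(predicted)
  Y <- truth_matrix(truth, P)
  if (any(P < 0) || any(P > 1)) stop("predicted values outside [0,1]",
                                     call. = FALSE)
  Pb <- (P > 0.5) * 1L
  mean(Pb != Y)
}

#' Per-label AUPR
#'
#' AUPR of each side-effect term's score column against its truth column.
#' Terms observed for no drug have no positive instance, so their AUPR is
#' undefined and reported as `NA`.
#'
#' @inheritParams ranking_metrics
#' @return Named numeric vector, one entry per label (`NA` where undefined).
#' @export
per_label_aupr <- function(scores, truth) {
  S <- as_score_input(scores)
  Y <- truth_matrix(truth, S)
  out <- rep(NA_real_, ncol(S))
  names(out) <- colnames(Y)
  for (l in seq_len(ncol(S)))
    if (any(Y[, l] == 1)) out[l] <- micro_aupr(S[, l], Y[, l])
  out
}

#' Three-way per-label comparison of two methods
#'
#' Counts, over labels where both per-label scores are defined, how often
#' method A beats method B, ties it, or loses (exact equality for ties).
#'
#' @param per_label_a,per_label_b numeric vectors from [per_label_aupr()]
#'   over the same labels.
#' @return Named integer vector `c(a_gt_b, equal, b_gt_a)`.
#' @export
compare_methods <- function(per_label_a, per_label_b) {
  if (length(per_label_a) != length(per_label_b))
    stop("per-label vectors differ in length", call. = FALSE)
  if (!identical(is.na(per_label_a), is.na(per_label_b)))
    stop("defined label sets differ between methods", call. = FALSE)
  a <- per_label_a[!is.na(per_label_a)]
  b <- per_label_b[!is.na(per_label_b)]
  c(a_gt_b = sum(a > b), equal = sum(a == b), b_gt_a = sum(b > a))
}

#' Top-N recall per drug
#'
#' For each drug, takes the `n_top` highest-scored side-effect terms as the
#' predicted set and reports the fraction of the drug's known side effects
#' recovered.  Ties at the cutoff are broken by label index.  Drugs with no
#' known side effect are skipped (NA).
#'
#' @inheritParams ranking_metrics
#' @param n_top size of the predicted set (<= number of labels).
#' @return List with `per_drug` (named numeric, NA where undefined) and
#'   `mean` over defined drugs.
#' @export
topn_recall <- function(scores, truth, n_top) {
  S <- as_score_input(scores)
  Y <- truth_matrix(truth, S)
  q <- ncol(S)
  if (n_top < 1L || n_top > q) stop("n_top must be in 1..q", call. = FALSE)
  per <- rep(NA_real_, nrow(S))
  names(per) <- rownames(S)
  for (i in seq_len(nrow(S))) {
    rel <- which(Y[i, ] == 1)
    if (!length(rel)) next
    top <- order(-S[i, ], seq_len(q))[seq_len(n_top)]
    per[i] <- length(intersect(top, rel)) / length(rel)
  }
  list(per_drug = per, mean = mean(per, na.rm = TRUE))
}

#' Full multi-label evaluation report
#'
#' Runs the complete metric suite on one score matrix: micro AUPR and AUC
#' over pooled drug-label pairs, Hamming loss of the thresholded labels, and
#' the instance-wise ranking metrics.
#'
#' @inheritParams ranking_metrics
#' @return An `evaluation_report` list: `aupr`, `auc`, `hamming_loss`,
#'   `ranking_loss`, `one_error`, `coverage`, `average_precision`,
#'   `n_labels_evaluated` (labels with at least one positive).
#' @export
evaluate_scores <- function(scores, truth) {
  S <- as_score_input(scores)
  Y <- truth_matrix(truth, S)
  rm_ <- ranking_metrics(S, Y)
  structure(list(aupr = micro_aupr(S, Y), auc = micro_auc(S, Y),
                 hamming_loss = hamming_loss(S, Y),
                 ranking_loss = rm_$ranking_loss,
                 one_error = rm_$one_error, coverage = rm_$coverage,
                 average_precision = rm_$average_precision,
                 n_labels_evaluated = sum(colSums(Y) > 0)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("AUPR %.4f | AUC %.4f | Hamming %.4f | RankLoss %.4f | ",
                     "OneError %.4f | Coverage %.2f | AvgPrec %.4f\n"),
              x$aupr, x$auc, x$hamming_loss, x$ranking_loss, x$one_error,
              x$coverage, x$average_precision))
  invisible(x)
}

as_score_input <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("scores must be finite numeric", call. = FALSE)
  x
}

truth_matrix <- function(truth, scores) {
  if (inherits(truth, "label_table")) truth <- truth$values
  if (is.null(dim(truth))) truth <- matrix(truth, nrow = 1L)
  truth <- as.matrix(truth)
  sc <- if (is.null(dim(scores))) matrix(scores, nrow = 1L) else scores
  if (!all(dim(truth) == dim(sc)))
    stop(sprintf("scores (%dx%d) and truth (%dx%d) shapes differ",
                 nrow(sc), ncol(sc), nrow(truth), ncol(truth)), call. = FALSE)
  if (any(!(truth %in% c(0, 1)))) stop("truth must be binary", call. = FALSE)
  truth
}
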