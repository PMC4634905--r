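# Independent brute-force reference implementations used to validate the
# package's vectorised code paths. Everything here is written as plain loops
# straight from the defining formulas, with no code shared with R/.

oracle_knn <- function(train, query, k, exclude_self = FALSE) {
  out <- matrix(0L, nrow(query), k)
  for (i in seq_len(nrow(query))) {
    d <- numeric(nrow(train))
    for (j in seq_len(nrow(train)))
      d[j] <- sqrt(sum((query[i, ] - train[j, ])^2))
    if (exclude_self) d[i] <- Inf
    out[i, ] <- order(d, seq_len(nrow(train)))[seq_len(k)]
  }
  out
}

# Full MLKNN fit + predict from the four estimator equations:
#   P(H1_l) = (s + sum_i y_i(l)) / (2 s + n)
#   c_l[j]  = #{i : y_i(l)=1, C_i(l)=j},  c'_l[j] = #{i : y_i(l)=0, C_i(l)=j}
#   P(Ej|Hb) = (s + c_b[j]) / (s (k+1) + sum_j c_b[j])
#   score(t,l) = P(H1)P(E_C|H1) / [P(H1)P(E_C|H1) + P(H0)P(E_C|H0)]
oracle_mlknn_scores <- function(X, Y, Q, k, s) {
  n <- nrow(X); q <- ncol(Y)
  nb <- oracle_knn(X, X, k, exclude_self = TRUE)
  C <- matrix(0L, n, q)
  for (i in seq_len(n)) for (l in seq_len(q))
    C[i, l] <- sum(Y[nb[i, ], l])
  scores <- matrix(0, nrow(Q), q)
  nbq <- oracle_knn(X, Q, k, exclude_self = FALSE)
  for (l in seq_len(q)) {
    p1 <- (s + sum(Y[, l])) / (s * 2 + n)
    p0 <- 1 - p1
    cpos <- cneg <- numeric(k + 1)
    for (j in 0:k) {
      cpos[j + 1] <- sum(Y[, l] == 1 & C[, l] == j)
      cneg[j + 1] <- sum(Y[, l] == 0 & C[, l] == j)
    }
    for (t in seq_len(nrow(Q))) {
      ct <- sum(Y[nbq[t, ], l])
      e1 <- (s + cpos[ct + 1]) / (s * (k + 1) + sum(cpos))
      e0 <- (s + cneg[ct + 1]) / (s * (k + 1) + sum(cneg))
      scores[t, l] <- p1 * e1 / (p1 * e1 + p0 * e0)
    }
  }
  scores
}

# step AUPR for distinct scores: precision at each positive's rank
oracle_aupr <- function(s, y) {
  ord <- order(-s)
  y <- y[ord]
  sum((cumsum(y) / seq_along(y))[y == 1]) / sum(y)
}

# AUC by concordant-pair counting with half credit for ties
oracle_auc <- function(s, y) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

oracle_ranking <- function(S, Y) {
  one_err <- rl <- ap <- numeric(0)
  cov <- numeric(nrow(S))
  for (i in seq_len(nrow(S))) {
    s <- S[i, ]; rel <- which(Y[i, ] == 1); q <- length(s)
    if (length(rel) == 0) { cov[i] <- 0; next }
    ord <- order(-s, seq_len(q))
    rnk <- match(seq_len(q), ord)
    cov[i] <- max(rnk[rel]) - 1
    one_err <- c(one_err, as.numeric(!(ord[1] %in% rel)))
    ap_i <- 0
    for (u in rel) ap_i <- ap_i + sum(rnk[rel] <= rnk[u]) / rnk[u]
    ap <- c(ap, ap_i / length(rel))
    irr <- which(Y[i, ] == 0)
    if (length(irr)) {
      bad <- 0
      for (u in rel) for (v in irr)
        bad <- bad + (s[u] < s[v]) + 0.5 * (s[u] == s[v])
      rl <- c(rl, bad / (length(rel) * length(irr)))
    }
  }
  list(one_error = mean(one_err), coverage = mean(cov),
       ranking_loss = mean(rl), average_precision = mean(ap))
}

oracle_mi <- function(x, y) {
  tab <- table(factor(x, c(0, 1)), factor(y, c(0, 1)))
  n <- sum(tab)
  mi <- 0
  for (a in 1:2) for (b in 1:2) {
    pxy <- tab[a, b] / n
    if (pxy > 0)
      mi <- mi + pxy * log2(pxy / (sum(tab[a, ]) / n * sum(tab[, b]) / n))
  }
  mi
}

random_instance <- function(n, p, q, seed = NULL, density = 0.4,
                            label_density = 0.4) {
  if (!is.null(seed)) set.seed(seed)
  list(X = matrix(rbinom(n * p, 1, density), n, p),
       Y = matrix(rbinom(n * q, 1, label_density), n, q))
}

# shared desk-scale study conditions for the cross-validation level checks
acceptance_cv_spec <- function() {
  synthetic_spec(
    n_drugs = 100L,
    feature_specs = list(
      substructure = list(p = 25L, density = 0.1, n_informative = 5L),
      target = list(p = 25L, density = 0.1, n_informative = 5L),
      indication = list(p = 25L, density = 0.1, n_informative = 5L)),
    q_labels = 15L)
}

acceptance_mixed_spec <- function() {
  synthetic_spec(
    n_drugs = 100L,
    feature_specs = list(
      informative = list(p = 25L, density = 0.1, n_informative = 5L),
      noise_a = list(p = 25L, density = 0.1, n_informative = 0L),
      noise_b = list(p = 25L, density = 0.1, n_informative = 0L)),
    q_labels = 15L)
}

acceptance_cv_ga <- function() {
  ga_config(population_size = 30L, max_generations = 15L)
}
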