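#' Specification of a synthetic side-effect dataset
#'
#' Describes a seeded generator that emulates the structure of the drug
#' side-effect benchmarks: several sparse binary feature tables (hundreds of
#' dimensions), a sparse binary label matrix with many labels and severe
#' positive/negative imbalance, and a planted subset of feature dimensions
#' that are statistically associated with the labels so that selection
#' methods have a recoverable ground truth.
#'
#' Each feature type is described by a list with `p` (dimensions), `density`
#' (Bernoulli rate of 1s) and `n_informative` (planted dimensions).  Every
#' planted dimension is wired to `labels_per_dim` randomly drawn side-effect
#' terms: a drug carrying the dimension fires each wired label with
#' probability `association_strength`; otherwise the label fires at
#' `label_base_rate`.  Every cell is finally flipped with probability
#' `noise_rate`.
#'
#' The defaults are a desk-scale instance — 200 drugs, three feature types
#' of 50 dimensions (5 planted each), 30 labels, base rate 0.05, strength
#' 0.6, noise 0.02 — on which the full FS-MLKNN + GA pipeline completes in
#' minutes.
#'
#' @param n_drugs number of drugs.
#' @param feature_specs named list of per-feature-type lists
#'   (`p`, `density`, `n_informative`).
#' @param q_labels number of side-effect terms.
#' @param label_base_rate baseline label firing probability.
#' @param association_strength label firing probability when an associated
#'   planted dimension is present.
#' @param noise_rate symmetric flip probability applied to the labels.
#' @param labels_per_dim labels wired to each planted dimension.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 200L,
                           feature_specs = list(
                             substructure = list(p = 50L, density = 0.1,
                                                 n_informative = 5L),
                             target = list(p = 50L, density = 0.1,
                                           n_informative = 5L),
                             indication = list(p = 50L, density = 0.1,
                                               n_informative = 5L)),
                           q_labels = 30L, label_base_rate = 0.05,
                           association_strength = 0.6, noise_rate = 0.02,
                           labels_per_dim = 3L) {
  stopifnot(n_drugs >= 1L, q_labels >= 1L, length(feature_specs) >= 1L)
  rates <- c(label_base_rate, association_strength, noise_rate,
             vapply(feature_specs, `[[`, 0, "density"))
  if (any(rates < 0 | rates > 1))
    stop("densities and rates must lie in [0,1]", call. = FALSE)
  for (nm in names(feature_specs)) {
    fs <- feature_specs[[nm]]
    if (fs$n_informative > fs$p)
      stop("n_informative exceeds p for feature '", nm, "'", call. = FALSE)
  }
  if (labels_per_dim > q_labels)
    stop("labels_per_dim exceeds q_labels", call. = FALSE)
  structure(list(n_drugs = as.integer(n_drugs),
                 feature_specs = feature_specs,
                 q_labels = as.integer(q_labels),
                 label_base_rate = label_base_rate,
                 association_strength = association_strength,
                 noise_rate = noise_rate,
                 labels_per_dim = as.integer(labels_per_dim)),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset bundle with planted informative dimensions
#'
#' Draws the dataset described by a [synthetic_spec()]: independent
#' Bernoulli feature dimensions, with the planted dimensions additionally
#' wired to their associated labels.  Deterministic given `seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return List with `bundle` (a `dataset_bundle`) and `truth`, a record of
#'   the planted dimensions per feature type and the dimension-to-label
#'   association map, sufficient to score selection precision/recall.
#' @export
generate_dataset <- function(spec = synthetic_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- spec$n_drugs; q <- spec$q_labels
  drug_ids <- sprintf("D%04d", seq_len(n))
  label_ids <- sprintf("SE%03d", seq_len(q))
  features <- list(); planted <- list(); assoc <- list()
  active <- matrix(FALSE, n, q)  # drug x label: any wired planted dim present
  for (nm in names(spec$feature_specs)) {
    fs <- spec$feature_specs[[nm]]
    X <- matrix(stats::rbinom(n * fs$p, 1L, fs$density), n, fs$p)
    dim_ids <- sprintf("%s_%03d", nm, seq_len(fs$p))
    colnames(X) <- dim_ids
    pl <- sort(sample.int(fs$p, fs$n_informative))
    planted[[nm]] <- dim_ids[pl]
    for (d in pl) {
      wired <- sort(sample.int(q, spec$labels_per_dim))
      assoc[[dim_ids[d]]] <- label_ids[wired]
      active[X[, d] == 1L, wired] <- TRUE
    }
    features[[nm]] <- feature_table(X, drug_ids = drug_ids,
                                    dim_ids = dim_ids, feature_name = nm)
  }
  p_fire <- ifelse(active, spec$association_strength, spec$label_base_rate)
  Y <- matrix(stats::rbinom(n * q, 1L, as.vector(p_fire)), n, q)
  flip <- matrix(stats::rbinom(n * q, 1L, spec$noise_rate), n, q)
  Y <- abs(Y - flip)
  labels <- label_table(Y, drug_ids = drug_ids, label_ids = label_ids)
  bundle <- suppressWarnings(align_bundle(features, labels))
  list(bundle = bundle,
       truth = list(planted = planted, association = assoc, seed = seed,
                    spec = spec))
}

#' Analytic expected label prevalence of a synthetic spec
#'
#' For each label, the expected fraction of drugs carrying it under the
#' generator: `a = 1 - prod_d (1 - density_d)` over the planted dimensions
#' wired to the label, prevalence `= a * strength + (1 - a) * base`, then
#' attenuated by the symmetric noise flip.  Used for generator calibration
#' checks.
#'
#' @param spec a [synthetic_spec()].
#' @param truth the `truth` record returned by [generate_dataset()].
#' @return Named numeric vector of expected prevalences per label.
#' @export
expected_label_prevalence <- function(spec, truth) {
  label_ids <- sprintf("SE%03d", seq_len(spec$q_labels))
  dens <- stats::setNames(
    unlist(lapply(names(spec$feature_specs), function(nm)
      rep(spec$feature_specs[[nm]]$density,
          length(truth$planted[[nm]])))),
    unlist(truth$planted))
  out <- stats::setNames(numeric(spec$q_labels), label_ids)
  for (l in label_ids) {
    dims <- names(truth$association)[vapply(truth$association,
                                            function(w) l %in% w, TRUE)]
    a <- 1 - prod(1 - dens[dims])  # empty -> a = 0
    prev <- a * spec$association_strength + (1 - a) * spec$label_base_rate
    out[l] <- prev * (1 - spec$noise_rate) + (1 - prev) * spec$noise_rate
  }
  out
}
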