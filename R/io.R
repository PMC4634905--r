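#' Construct a binary feature table
#'
#' A feature table holds one binary drug representation: rows are drugs,
#' columns are the dimensions of one feature type (e.g. the 881 PubChem
#' substructure keys, or target proteins), and a cell is 1 when the drug
#' carries that component.
#'
#' @param values binary matrix (drugs x dimensions); coerced to integer.
#' @param drug_ids,dim_ids unique identifiers for rows / columns. Default to
#'   the matrix dimnames.
#' @param feature_name free-text name of the feature type
#'   (e.g. `"substructure"`).
#' @return An object of class `feature_table` with elements `values`,
#'   `drug_ids`, `dim_ids`, `feature_name`.
#' @examples
#' ft <- feature_table(matrix(c(1, 0, 0, 0, 1, 1), 3, 2),
#'                     drug_ids = c("a", "b", "c"),
#'                     dim_ids = c("s1", "s2"), feature_name = "substructure")
#' dim(ft$values)
#' @export
feature_table <- function(values, drug_ids = rownames(values),
                          dim_ids = colnames(values),
                          feature_name = "feature") {
  values <- as.matrix(values)
  check_binary_matrix(values, "feature table")
  if (is.null(drug_ids)) drug_ids <- paste0("drug", seq_len(nrow(values)))
  if (is.null(dim_ids)) dim_ids <- paste0("dim", seq_len(ncol(values)))
  check_unique_ids(drug_ids, nrow(values), "drug_ids")
  check_unique_ids(dim_ids, ncol(values), "dim_ids")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(drug_ids, dim_ids)
  structure(list(values = values, drug_ids = as.character(drug_ids),
                 dim_ids = as.character(dim_ids),
                 feature_name = feature_name),
            class = "feature_table")
}

#' Construct a binary label (side-effect) table
#'
#' Rows are drugs, columns are side-effect terms; a cell is 1 when the drug
#' is known to induce the side effect.
#'
#' @param values binary matrix (drugs x labels).
#' @param drug_ids,label_ids unique identifiers; default to dimnames.
#' @return An object of class `label_table`.
#' @export
label_table <- function(values, drug_ids = rownames(values),
                        label_ids = colnames(values)) {
  values <- as.matrix(values)
  check_binary_matrix(values, "label table")
  if (is.null(drug_ids)) drug_ids <- paste0("drug", seq_len(nrow(values)))
  if (is.null(label_ids)) label_ids <- paste0("se", seq_len(ncol(values)))
  check_unique_ids(drug_ids, nrow(values), "drug_ids")
  check_unique_ids(label_ids, ncol(values), "label_ids")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(drug_ids, label_ids)
  structure(list(values = values, drug_ids = as.character(drug_ids),
                 label_ids = as.character(label_ids)),
            class = "label_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table '%s': %d drugs x %d dimensions (density %.3f)\n",
              x$feature_name, nrow(x$values), ncol(x$values),
              mean(x$values)))
  invisible(x)
}

#' @export
print.label_table <- function(x, ...) {
  cat(sprintf("label_table: %d drugs x %d side-effect terms (density %.3f)\n",
              nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

check_binary_matrix <- function(values, what) {
  if (length(values) == 0L || nrow(values) < 1L || ncol(values) < 1L)
    stop(what, " must have at least one row and one column", call. = FALSE)
  bad <- which(!(values %in% c(0L, 1L)) | is.na(values))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    stop(sprintf("%s has a non-binary cell at row %d, column %d: '%s'",
                 what, i, j, as.character(values[bad[1L]])), call. = FALSE)
  }
  invisible(TRUE)
}

check_unique_ids <- function(ids, n, what) {
  if (length(ids) != n)
    stop(what, " length does not match matrix dimension", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate identifier in ", what, ": '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  invisible(TRUE)
}

read_binary_tsv <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) < 1L || ncol(df) < 2L)
    stop(what, " file '", path,
         "' has no data rows or no data columns", call. = FALSE)
  ids <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.integer(body), nrow(body), ncol(body)))
  if (anyNA(num) || any(!(num %in% c(0L, 1L)))) {
    bad <- which(is.na(num) | !(num %in% c(0L, 1L)))[1L]
    i <- ((bad - 1L) %% nrow(num)) + 1L
    j <- ((bad - 1L) %/% nrow(num)) + 1L
    stop(sprintf("%s file '%s': cell at row '%s', column '%s' is not 0/1: '%s'",
                 what, path, ids[i], colnames(body)[j], body[bad]),
         call. = FALSE)
  }
  list(ids = ids, col_ids = colnames(body), values = num)
}

#' Read / write feature and label tables as TSV
#'
#' The on-disk dialect is tab-separated text: one header row holding the
#' dimension (or side-effect) identifiers, the first column holding drug
#' identifiers, and every cell strictly `0` or `1`.
#'
#' @param path file path.
#' @param feature_name feature-type name attached to the returned table.
#' @return `read_feature_table()` a [feature_table()]; `read_label_table()` a
#'   [label_table()]; the writers return `path` invisibly.
#' @seealso [align_bundle()], [dataset_stats()]
#' @export
read_feature_table <- function(path, feature_name = "feature") {
  raw <- read_binary_tsv(path, "feature table")
  feature_table(raw$values, drug_ids = raw$ids, dim_ids = raw$col_ids,
                feature_name = feature_name)
}

#' @rdname read_feature_table
#' @export
read_label_table <- function(path) {
  raw <- read_binary_tsv(path, "label table")
  label_table(raw$values, drug_ids = raw$ids, label_ids = raw$col_ids)
}

write_binary_tsv <- function(values, row_ids, col_ids, path, id_header) {
  df <- data.frame(row_ids, values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_header, col_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_feature_table
#' @param x table to write.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  write_binary_tsv(x$values, x$drug_ids, x$dim_ids, path, "drug_id")
}

#' @rdname read_feature_table
#' @export
write_label_table <- function(x, path) {
  stopifnot(inherits(x, "label_table"))
  write_binary_tsv(x$values, x$drug_ids, x$label_ids, path, "drug_id")
}

#' Align feature tables and a label table into a dataset bundle
#'
#' Restricts every table to the drugs common to all of them, reordered to the
#' label table's order, so that row i of every matrix refers to the same drug.
#' Drugs missing from any table are dropped with a warning, since benchmark
#' files for different feature types do not always cover the same compounds.
#'
#' @param features a single [feature_table()] or a (optionally named) list of
#'   them, one per feature type.
#' @param labels a [label_table()].
#' @return An object of class `dataset_bundle`: list with `features` (named
#'   list of aligned feature tables) and `labels`.
#' @export
align_bundle <- function(features, labels) {
  if (inherits(features, "feature_table")) features <- list(features)
  stopifnot(length(features) >= 1L, inherits(labels, "label_table"))
  for (f in features) stopifnot(inherits(f, "feature_table"))
  nms <- names(features)
  if (is.null(nms) || any(!nzchar(nms)))
    names(features) <- vapply(features, `[[`, "", "feature_name")
  common <- labels$drug_ids
  for (f in features) common <- intersect(common, f$drug_ids)
  if (length(common) == 0L)
    stop("no drugs shared by all tables; cannot align", call. = FALSE)
  keep <- labels$drug_ids[labels$drug_ids %in% common]  # label-table order
  dropped <- setdiff(unique(c(labels$drug_ids,
                              unlist(lapply(features, `[[`, "drug_ids")))),
                     keep)
  if (length(dropped))
    warning(length(dropped), " drug(s) not shared by all tables dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...", call. = FALSE)
  labels <- label_table(labels$values[keep, , drop = FALSE],
                        drug_ids = keep, label_ids = labels$label_ids)
  features <- lapply(features, function(f) {
    feature_table(f$values[keep, , drop = FALSE], drug_ids = keep,
                  dim_ids = f$dim_ids, feature_name = f$feature_name)
  })
  structure(list(features = features, labels = labels),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("dataset_bundle: %d drugs, %d side-effect terms, %d feature type(s)\n",
              nrow(x$labels$values), ncol(x$labels$values),
              length(x$features)))
  for (nm in names(x$features))
    cat(sprintf("  %-14s p = %d\n", nm, ncol(x$features[[nm]]$values)))
  invisible(x)
}

#' Descriptive statistics of a dataset bundle
#'
#' @param bundle a [align_bundle()] result.
#' @return A list with `n_drugs`, `n_labels`, `n_dims` (named, per feature
#'   type), `n_zero_labels` (side-effect terms observed for no drug, whose
#'   per-label AUPR is undefined), `n_observed_labels`, `mean_labels_per_drug`
#'   and its rounded value `mean_labels_per_drug_int`.
#' @export
dataset_stats <- function(bundle) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  Y <- bundle$labels$values
  pos <- colSums(Y)
  per_drug <- rowSums(Y)
  list(n_drugs = nrow(Y),
       n_labels = ncol(Y),
       n_dims = vapply(bundle$features, function(f) ncol(f$values), 0L),
       n_zero_labels = sum(pos == 0L),
       n_observed_labels = sum(pos > 0L),
       mean_labels_per_drug = mean(per_drug),
       mean_labels_per_drug_int = as.integer(round(mean(per_drug))))
}
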