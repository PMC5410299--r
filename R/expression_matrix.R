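#' Feature-by-sample expression matrix with group and biotype metadata
#'
#' The central data container of the package: an intensity matrix (features in
#' rows, samples in columns) together with a case/control label per sample, a
#' biotype (lncRNA or mRNA) per feature, and a scale marker recording whether
#' values are linear intensities or log2 intensities. Missing values are an
#' input error (never imputed); linear-scale values must be strictly positive;
#' both groups must be non-empty.
#'
#' @param values numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids).
#' @param groups character or factor, one of `"case"`/`"control"` per sample;
#'   either named by sample id or in column order.
#' @param biotypes character or factor, one of `"lncRNA"`/`"mRNA"` per feature;
#'   either named by feature id or in row order.
#' @param scale `"linear"` (default) or `"log2"`.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, groups, biotypes,
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    input_error("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    input_error("`values` must have unique rownames (feature ids)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    input_error("`values` must have unique colnames (sample ids)")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    input_error(sprintf(
      "missing value at feature '%s', sample '%s' (missing entries are an input error)",
      rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  if (scale == "linear" && any(values <= 0)) {
    idx <- which(values <= 0, arr.ind = TRUE)[1, ]
    input_error(sprintf(
      "non-positive linear intensity at feature '%s', sample '%s'",
      rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }

  groups <- align_labels(groups, colnames(values), c("case", "control"),
                         "groups", "sample")
  biotypes <- align_labels(biotypes, rownames(values), c("lncRNA", "mRNA"),
                           "biotypes", "feature")
  if (!all(c("case", "control") %in% as.character(groups)))
    input_error("both groups (case and control) must be non-empty")

  structure(
    list(values = values, groups = groups, biotypes = biotypes, scale = scale),
    class = "expr_matrix")
}

# match a label vector to ids, accepting names or positional order
align_labels <- function(x, ids, levels, what, unit) {
  nm <- names(x)
  x <- stats::setNames(as.character(x), nm)
  if (!is.null(nm)) {
    if (!setequal(nm, ids))
      input_error(sprintf("names of `%s` do not match %s ids", what, unit))
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    input_error(sprintf("`%s` must have one entry per %s", what, unit))
  }
  if (!all(x %in% levels))
    input_error(sprintf("`%s` entries must be one of: %s",
                        what, paste(levels, collapse = ", ")))
  factor(stats::setNames(x, ids), levels = levels)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "expr_matrix: %d features (%d lncRNA, %d mRNA) x %d samples (%d case, %d control), %s scale\n",
    nrow(x$values), sum(x$biotypes == "lncRNA"), sum(x$biotypes == "mRNA"),
    ncol(x$values), sum(x$groups == "case"), sum(x$groups == "control"),
    x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset helpers for expression matrices
#'
#' `em_values` returns the numeric matrix restricted to a biotype and/or
#' group; `em_samples` returns sample ids of a group.
#'
#' @param em an `expr_matrix`.
#' @param biotype optional `"lncRNA"` or `"mRNA"`.
#' @param group optional `"case"` or `"control"`.
#' @return numeric matrix (`em_values`) or character vector (`em_samples`).
#' @export
em_values <- function(em, biotype = NULL, group = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  v <- em$values
  if (!is.null(biotype)) v <- v[em$biotypes == biotype, , drop = FALSE]
  if (!is.null(group)) v <- v[, em$groups == group, drop = FALSE]
  v
}

#' @rdname em_values
#' @export
em_samples <- function(em, group) {
  stopifnot(inherits(em, "expr_matrix"))
  colnames(em$values)[em$groups == group]
}

#' Write an expression matrix to tab-separated files
#'
#' Serializes the intensity matrix (first column `feature_id`, then one column
#' per sample), a two-column sample-to-group sidecar, and a two-column
#' feature-to-biotype table.
#'
#' @param em an `expr_matrix`.
#' @param matrix_file,groups_file,features_file output paths.
#' @return `em`, invisibly.
#' @export
write_expression_matrix <- function(em, matrix_file, groups_file, features_file) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(feature_id = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(em$groups), group = as.character(em$groups)),
    groups_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = names(em$biotypes),
               biotype = as.character(em$biotypes)),
    features_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(em)
}

#' Read an expression matrix from tab-separated files
#'
#' @inheritParams write_expression_matrix
#' @param scale scale of the stored values, `"linear"` or `"log2"`.
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(matrix_file, groups_file, features_file,
                                   scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  df <- utils::read.table(matrix_file, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  grp <- utils::read.table(groups_file, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  bio <- utils::read.table(features_file, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expression_matrix(values,
                    stats::setNames(grp$group, grp$sample_id),
                    stats::setNames(bio$biotype, bio$feature_id),
                    scale = scale)
}
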