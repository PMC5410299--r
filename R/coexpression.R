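#' Pearson correlation with a t-transform p-value
#'
#' Sample Pearson coefficient of two expression profiles plus the two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. `|r| = 1` returns p = 0 by convention. Zero variance in either
#' vector is an input error (pair-level callers skip such features and log a
#' count instead).
#'
#' @param x,y numeric vectors of equal length `n >= 3` (log2 intensities).
#' @return list with elements `r` and `p_corr`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) input_error("x and y must have the same length")
  if (n < 3) input_error("correlation p-value needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    input_error("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  list(r = r, p_corr = cor_pvalue(r, n))
}

# two-sided p for a sample Pearson r at n observations (t-transform);
# preserves the shape (vector or matrix) of r
cor_pvalue <- function(r, n) {
  out <- r
  rc <- pmin(1, pmax(-1, as.vector(r)))
  out[] <- ifelse(abs(rc) >= 1, 0,
                  2 * stats::pt(abs(rc) * sqrt((n - 2) / (1 - rc^2)),
                                df = n - 2, lower.tail = FALSE))
  out
}

#' Build the lncRNA-mRNA coexpression edge table
#'
#' Evaluates every lncRNA x mRNA pair across all pooled samples and retains
#' edges with `|r| > r_threshold` and `p < p_threshold` (both strict; the
#' canonical thresholds are 0.8 and 0.01). Rows must share an identical
#' sample ordering — a mismatch is an error, never silently reordered.
#' Zero-variance features are skipped with a logged count.
#'
#' @param lnc_matrix,mrna_matrix numeric matrices, features x samples, with
#'   matching column names; typically the DE-passing subsets of the
#'   normalized log2 matrix.
#' @param r_threshold,p_threshold edge thresholds.
#' @param keep_all if `TRUE` the full edge table is returned with a `passes`
#'   column; otherwise only passing edges.
#' @return data.frame `lnc_id`, `mrna_id`, `r`, `p_corr` (and `passes` when
#'   `keep_all`), ordered by (`lnc_id`, `mrna_id`).
#' @export
build_coexpression <- function(lnc_matrix, mrna_matrix,
                               r_threshold = 0.8, p_threshold = 0.01,
                               keep_all = FALSE) {
  stopifnot(is.matrix(lnc_matrix), is.matrix(mrna_matrix))
  if (!identical(colnames(lnc_matrix), colnames(mrna_matrix)))
    input_error("sample orderings differ between the two matrices")
  n <- ncol(lnc_matrix)
  if (n < 3) input_error("coexpression needs >= 3 samples")
  if (nrow(lnc_matrix) == 0 || nrow(mrna_matrix) == 0)
    return(empty_edge_table(keep_all))

  lnc_ok <- apply(lnc_matrix, 1, stats::sd) > 0
  mrna_ok <- apply(mrna_matrix, 1, stats::sd) > 0
  n_skip <- sum(!lnc_ok) + sum(!mrna_ok)
  if (n_skip > 0)
    message(sprintf("build_coexpression: skipped %d zero-variance feature(s)",
                    n_skip))
  lnc_matrix <- lnc_matrix[lnc_ok, , drop = FALSE]
  mrna_matrix <- mrna_matrix[mrna_ok, , drop = FALSE]
  if (nrow(lnc_matrix) == 0 || nrow(mrna_matrix) == 0)
    return(empty_edge_table(keep_all))

  R <- stats::cor(t(lnc_matrix), t(mrna_matrix))
  P <- cor_pvalue(R, n)
  pass <- abs(R) > r_threshold & P < p_threshold
  idx <- if (keep_all) which(!is.na(R), arr.ind = TRUE) else
    which(pass, arr.ind = TRUE)
  out <- data.frame(
    lnc_id = rownames(R)[idx[, 1]],
    mrna_id = colnames(R)[idx[, 2]],
    r = R[idx], p_corr = P[idx],
    stringsAsFactors = FALSE)
  if (keep_all) out$passes <- pass[idx]
  out <- out[order(out$lnc_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_edge_table <- function(keep_all) {
  out <- data.frame(lnc_id = character(0), mrna_id = character(0),
                    r = numeric(0), p_corr = numeric(0),
                    stringsAsFactors = FALSE)
  if (keep_all) out$passes <- logical(0)
  out
}
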