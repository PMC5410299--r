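#' Relative quantification by the 2^-deltaCt method
#'
#' `delta_ct = ct_target - ct_reference` (the reference is the housekeeping
#' control, e.g. beta-actin) and the relative quantity is
#' `rq = 2^(-delta_ct)`, so a target one cycle later than the reference has
#' half its expression.
#'
#' @param ct_target,ct_reference finite Ct values in cycles (vectorized).
#' @return data.frame with columns `delta_ct`, `rq`.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    input_error("Ct values must be finite")
  d <- ct_target - ct_reference
  data.frame(delta_ct = d, rq = 2^(-d))
}

#' Per-record relative quantities from a Ct table
#'
#' Appends `delta_ct` and `rq` to a Ct table; records with a missing Ct are
#' excluded with a logged count.
#'
#' @param records data.frame with columns `sample_id`, `group`, `target_id`,
#'   `ct_target`, `ct_reference`.
#' @return the table with `delta_ct` and `rq` columns added.
#' @export
compute_rq <- function(records) {
  need <- c("sample_id", "group", "target_id", "ct_target", "ct_reference")
  if (!all(need %in% names(records)))
    input_error(paste("Ct table needs columns:", paste(need, collapse = ", ")))
  ok <- is.finite(records$ct_target) & is.finite(records$ct_reference)
  if (any(!ok))
    message(sprintf("compute_rq: excluded %d record(s) with missing Ct",
                    sum(!ok)))
  records <- records[ok, , drop = FALSE]
  cbind(records, delta_ct(records$ct_target, records$ct_reference))
}

#' Group-level signed fold change for one qPCR target
#'
#' Ratio of group mean relative quantities (case over control) on the linear
#' `rq` scale by default, converted to the signed fold-change convention
#' (`r` if `>= 1`, else `-1/r`). `scale = "delta_ct"` averages on the
#' delta-Ct scale instead (a geometric mean of `rq`).
#'
#' @param records output of [compute_rq()].
#' @param target_id which target to summarize.
#' @param scale `"linear"` (default) or `"delta_ct"`.
#' @return signed fold change (scalar).
#' @export
group_fold_change <- function(records, target_id,
                              scale = c("linear", "delta_ct")) {
  scale <- match.arg(scale)
  d <- records[records$target_id == target_id, , drop = FALSE]
  case <- d[d$group == "case", , drop = FALSE]
  ctrl <- d[d$group == "control", , drop = FALSE]
  if (nrow(case) == 0 || nrow(ctrl) == 0)
    input_error(sprintf("target '%s' needs >= 1 record per group", target_id))
  ratio <- if (scale == "linear") mean(case$rq) / mean(ctrl$rq) else
    2^(-(mean(case$delta_ct) - mean(ctrl$delta_ct)))
  signed_ratio(ratio)
}

#' Per-target qPCR summary
#'
#' @param records output of [compute_rq()].
#' @param scale passed to [group_fold_change()].
#' @return data.frame `target_id`, `mean_rq_case`, `mean_rq_control`,
#'   `fc_signed`, `direction`.
#' @export
qpcr_summary <- function(records, scale = c("linear", "delta_ct")) {
  scale <- match.arg(scale)
  targets <- sort(unique(records$target_id))
  fc <- vapply(targets, function(t)
    group_fold_change(records, t, scale = scale), numeric(1))
  data.frame(
    target_id = targets,
    mean_rq_case = vapply(targets, function(t)
      mean(records$rq[records$target_id == t & records$group == "case"]),
      numeric(1)),
    mean_rq_control = vapply(targets, function(t)
      mean(records$rq[records$target_id == t & records$group == "control"]),
      numeric(1)),
    fc_signed = fc,
    direction = ifelse(fc >= 1, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL)
}
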