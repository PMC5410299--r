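#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N_universe, K_term, n_draw)`: the
#' chance of drawing at least `k` term members when `n_draw` genes are drawn
#' without replacement from a universe of `N_universe` genes of which
#' `K_term` belong to the term. `k = 0` returns exactly 1.
#'
#' @param k overlap count.
#' @param n_draw number of drawn genes (coexpressed mRNAs of one lncRNA).
#' @param K_term number of universe genes carrying the term.
#' @param N_universe universe size.
#' @return upper-tail probability (vectorized over its arguments).
#' @export
hypergeometric_pvalue <- function(k, n_draw, K_term, N_universe) {
  bad <- k < 0 | K_term < 0 | n_draw < 0 | N_universe < 0 |
    k > pmin(n_draw, K_term) | K_term > N_universe | n_draw > N_universe
  if (any(bad))
    input_error("hypergeometric counts violate 0 <= k <= min(n_draw, K_term) <= N_universe")
  stats::phyper(k - 1, K_term, N_universe - K_term, n_draw,
                lower.tail = FALSE)
}

#' Guilt-by-association annotation of lncRNAs
#'
#' For each lncRNA, its coexpressed mRNAs (the passing edges) are tested for
#' over-representation in every term they touch (`k >= 1`; empty overlaps
#' would only inflate the family). BH adjustment is applied within each
#' lncRNA's family of tested terms by default, or over all tests jointly
#' with `family = "global"`. Significance is `fdr < fdr_threshold` (strict;
#' canonical threshold 0.01).
#'
#' @param edges passing coexpression edge table (`lnc_id`, `mrna_id`).
#' @param term_sets named list of term member vectors.
#' @param universe character vector of annotatable genes; must contain every
#'   term member and every coexpressed mRNA.
#' @param fdr_threshold significance cut on the adjusted p.
#' @param family `"per_lncrna"` (default) or `"global"` BH family.
#' @return data.frame with columns `lnc_id`, `term_id`, `k`, `n_draw`,
#'   `K_term`, `N_universe`, `p_hyper`, `fdr`, `significant`, sorted by
#'   (`lnc_id`, `fdr`, `p_hyper`, `term_id`).
#' @export
annotate_lncrnas <- function(edges, term_sets, universe,
                             fdr_threshold = 0.01,
                             family = c("per_lncrna", "global")) {
  family <- match.arg(family)
  if (length(universe) == 0) input_error("empty universe")
  if (anyDuplicated(universe)) input_error("universe ids must be unique")
  members_all <- unique(unlist(term_sets, use.names = FALSE))
  if (!all(members_all %in% universe))
    input_error("universe must contain every term member")
  if (nrow(edges) && !all(edges$mrna_id %in% universe))
    input_error("universe must contain every coexpressed mRNA")

  N <- length(universe)
  K <- vapply(term_sets, length, integer(1))
  draws <- split(edges$mrna_id, edges$lnc_id)
  n_empty <- 0L

  rows <- lapply(names(draws), function(lnc) {
    draw <- unique(draws[[lnc]])
    n_draw <- length(draw)
    k <- vapply(term_sets, function(s) length(intersect(draw, s)), integer(1))
    keep <- k >= 1L
    if (!any(keep)) { n_empty <<- n_empty + 1L; return(NULL) }
    data.frame(
      lnc_id = lnc, term_id = names(term_sets)[keep],
      k = k[keep], n_draw = n_draw, K_term = K[keep], N_universe = N,
      p_hyper = hypergeometric_pvalue(k[keep], n_draw, K[keep], N),
      stringsAsFactors = FALSE)
  })
  if (n_empty > 0)
    message(sprintf("annotate_lncrnas: %d lncRNA(s) with no term overlap",
                    n_empty))
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(lnc_id = character(0), term_id = character(0),
                      k = integer(0), n_draw = integer(0),
                      K_term = integer(0), N_universe = integer(0),
                      p_hyper = numeric(0), fdr = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  out$fdr <- if (family == "global") bh_fdr(out$p_hyper) else
    stats::ave(out$p_hyper, out$lnc_id, FUN = bh_fdr)
  out$significant <- out$fdr < fdr_threshold
  out <- out[order(out$lnc_id, out$fdr, out$p_hyper, out$term_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global ranking of annotation terms
#'
#' Summarizes enrichment results across all lncRNAs: terms are ranked by
#' their minimum `p_hyper` over lncRNAs (ascending), ties broken by the
#' number of supporting lncRNAs (descending), then term id; truncated to
#' `top_n` (the canonical report keeps the 200 most significant terms).
#'
#' @param all_results data.frame from [annotate_lncrnas()].
#' @param top_n maximum number of terms returned.
#' @return data.frame `term_id`, `min_p`, `n_lnc`, `rank`.
#' @export
rank_terms_global <- function(all_results, top_n = 200) {
  if (nrow(all_results) == 0) input_error("no enrichment results to rank")
  agg <- do.call(rbind, lapply(split(all_results, all_results$term_id),
    function(d) data.frame(term_id = d$term_id[1],
                           min_p = min(d$p_hyper),
                           n_lnc = length(unique(d$lnc_id)),
                           stringsAsFactors = FALSE)))
  agg <- agg[order(agg$min_p, -agg$n_lnc, agg$term_id), , drop = FALSE]
  agg <- utils::head(agg, top_n)
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}
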