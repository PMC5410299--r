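#' TF-lncRNA pairing by promoter binding and expression correlation
#'
#' A (TF, lncRNA) pair is tested only when the lncRNA promoter carries at
#' least one motif site for the TF (`n_sites >= 1` — the binding gate).
#' The regulatory ability is then measured by the Pearson correlation
#' between the TF's expression proxy (its own mRNA row) and the lncRNA's
#' expression, with the t-transform p-value; BH adjustment is applied across
#' all tested pairs jointly and a pair passes when `fdr < fdr_threshold`
#' (canonical threshold 0.01). TFs absent from the expression data are
#' skipped with a logged count.
#'
#' @param binding_counts data.frame `tf_id`, `lnc_id`, `n_sites` (from
#'   [scan_promoters()]).
#' @param tf_expression,lnc_expression numeric matrices (features x
#'   samples) with identical column ordering; rownames are TF mRNA ids /
#'   lncRNA ids.
#' @param fdr_threshold cut on the adjusted p.
#' @return data.frame `tf_id`, `lnc_id`, `n_sites`, `r`, `p_corr`, `fdr`,
#'   `passes`.
#' @export
tf_lnc_pairs <- function(binding_counts, tf_expression, lnc_expression,
                         fdr_threshold = 0.01) {
  stopifnot(all(c("tf_id", "lnc_id", "n_sites") %in% names(binding_counts)))
  if (!identical(colnames(tf_expression), colnames(lnc_expression)))
    input_error("sample orderings differ between TF and lncRNA matrices")
  n <- ncol(tf_expression)
  gated <- binding_counts[binding_counts$n_sites >= 1L, , drop = FALSE]
  empty <- data.frame(tf_id = character(0), lnc_id = character(0),
                      n_sites = integer(0), r = numeric(0),
                      p_corr = numeric(0), fdr = numeric(0),
                      passes = logical(0), stringsAsFactors = FALSE)
  if (nrow(gated) == 0) return(empty)
  have_tf <- gated$tf_id %in% rownames(tf_expression)
  have_lnc <- gated$lnc_id %in% rownames(lnc_expression)
  n_skip <- sum(!(have_tf & have_lnc))
  if (n_skip > 0)
    message(sprintf("tf_lnc_pairs: skipped %d pair(s) without expression rows",
                    n_skip))
  gated <- gated[have_tf & have_lnc, , drop = FALSE]
  if (nrow(gated) == 0) return(empty)
  # zero-variance rows (possible after quantile normalization) have no
  # defined correlation: skip those pairs with a logged count
  sd_tf <- apply(tf_expression, 1, stats::sd)
  sd_lnc <- apply(lnc_expression, 1, stats::sd)
  usable <- sd_tf[gated$tf_id] > 0 & sd_lnc[gated$lnc_id] > 0
  if (any(!usable))
    message(sprintf("tf_lnc_pairs: skipped %d pair(s) with zero variance",
                    sum(!usable)))
  gated <- gated[usable, , drop = FALSE]
  if (nrow(gated) == 0) return(empty)
  r <- vapply(seq_len(nrow(gated)), function(i)
    stats::cor(tf_expression[gated$tf_id[i], ],
               lnc_expression[gated$lnc_id[i], ]), numeric(1))
  out <- data.frame(gated, r = r, p_corr = cor_pvalue(r, n),
                    stringsAsFactors = FALSE)
  out$fdr <- bh_fdr(out$p_corr)
  out$passes <- out$fdr < fdr_threshold
  out <- out[order(out$tf_id, out$lnc_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Typed regulatory network container
#'
#' A light S3 container over a node table (`id`, `type` in
#' \{TF, lncRNA, gene\}) and an undirected edge table (`from`, `to`,
#' `relation` in \{binds, coexpressed\}, `score`). Self-edges and duplicate
#' edges are rejected; degrees are recomputed from the edge table on
#' construction.
#'
#' @param nodes data.frame `id`, `type`.
#' @param edges data.frame `from`, `to`, `relation`, `score`.
#' @return object of class `regulatory_network` with elements `nodes`,
#'   `edges`, `degrees` (named integer vector).
#' @export
regulatory_network <- function(nodes, edges) {
  stopifnot(all(c("id", "type") %in% names(nodes)),
            all(c("from", "to", "relation", "score") %in% names(edges)))
  if (anyDuplicated(nodes$id)) input_error("duplicate node ids")
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) input_error("self-edges are not allowed")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
                 edges$relation)
    if (anyDuplicated(key)) input_error("duplicate edges are not allowed")
    if (!all(c(edges$from, edges$to) %in% nodes$id))
      input_error("edge endpoints missing from the node table")
  }
  deg <- stats::setNames(integer(nrow(nodes)), nodes$id)
  if (nrow(edges)) {
    tab <- table(c(edges$from, edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  structure(list(nodes = nodes, edges = edges, degrees = deg),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  tt <- table(x$nodes$type)
  cat(sprintf("regulatory_network: %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("%s %s", as.integer(tt), names(tt)),
                    collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Two-element TF-lncRNA network
#'
#' Bipartite network over the passing TF-lncRNA pairs; the edge score is
#' `|r|`. The maximum-degree TF is flagged as the core TF (the most
#' connected hub of the network); ties resolve to the lexicographically
#' first id.
#'
#' @param pairs data.frame from [tf_lnc_pairs()] (passing rows are used; a
#'   table without a `passes` column is taken as already filtered).
#' @return a `regulatory_network` with attribute `core_tf`.
#' @export
build_two_element_network <- function(pairs) {
  if (!is.null(pairs$passes)) pairs <- pairs[pairs$passes, , drop = FALSE]
  nodes <- data.frame(
    id = c(unique(pairs$tf_id), unique(pairs$lnc_id)),
    type = rep(c("TF", "lncRNA"),
               c(length(unique(pairs$tf_id)), length(unique(pairs$lnc_id)))),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = pairs$tf_id, to = pairs$lnc_id,
                      relation = rep("binds", nrow(pairs)),
                      score = abs(pairs$r), stringsAsFactors = FALSE)
  net <- regulatory_network(nodes, edges)
  tf_deg <- net$degrees[nodes$id[nodes$type == "TF"]]
  attr(net, "core_tf") <- if (length(tf_deg))
    sort(names(tf_deg)[tf_deg == max(tf_deg)])[1] else NA_character_
  net
}

#' Three-element TF-lncRNA-gene network
#'
#' A triple (TF, lncRNA, gene) exists when the TF-lncRNA pair passes, the
#' (lncRNA, gene) coexpression edge passes, and the gene is a known target
#' of the TF. The triple score is `min(|r_TF,lnc|, |r_lnc,gene|)` — a chain
#' is only as strong as its weaker link.
#'
#' @param pairs passing TF-lncRNA pairs (see [build_two_element_network()]).
#' @param coexpression_edges passing edge table (`lnc_id`, `mrna_id`, `r`).
#' @param tf_targets named list: TF id -> character vector of target genes.
#' @return list with `triples` (data.frame `tf_id`, `lnc_id`, `gene_id`,
#'   `r_tf_lnc`, `r_lnc_gene`, `score`) and `network` (a
#'   `regulatory_network` over all three node types).
#' @export
build_three_element_network <- function(pairs, coexpression_edges, tf_targets) {
  if (!is.null(pairs$passes)) pairs <- pairs[pairs$passes, , drop = FALSE]
  if (length(tf_targets) == 0)
    message("build_three_element_network: empty tf_targets, zero triples")
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    tf <- pairs$tf_id[i]; lnc <- pairs$lnc_id[i]
    genes <- coexpression_edges[coexpression_edges$lnc_id == lnc, ,
                                drop = FALSE]
    genes <- genes[genes$mrna_id %in% tf_targets[[tf]], , drop = FALSE]
    if (!nrow(genes)) next
    rows[[length(rows) + 1]] <- data.frame(
      tf_id = tf, lnc_id = lnc, gene_id = genes$mrna_id,
      r_tf_lnc = pairs$r[i], r_lnc_gene = genes$r,
      score = pmin(abs(pairs$r[i]), abs(genes$r)),
      stringsAsFactors = FALSE)
  }
  triples <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf_id = character(0), lnc_id = character(0),
               gene_id = character(0), r_tf_lnc = numeric(0),
               r_lnc_gene = numeric(0), score = numeric(0),
               stringsAsFactors = FALSE)
  triples <- triples[order(triples$tf_id, triples$lnc_id, triples$gene_id), ,
                     drop = FALSE]
  rownames(triples) <- NULL
  list(triples = triples, network = triples_to_network(triples))
}

# node typing priority: TF > lncRNA > gene (a TF mRNA stays a TF node)
triples_to_network <- function(triples) {
  tfs <- unique(triples$tf_id)
  lncs <- unique(triples$lnc_id)
  genes <- setdiff(unique(triples$gene_id), c(tfs, lncs))
  nodes <- data.frame(
    id = c(tfs, lncs, genes),
    type = rep(c("TF", "lncRNA", "gene"),
               c(length(tfs), length(lncs), length(genes))),
    stringsAsFactors = FALSE)
  bind <- unique(triples[, c("tf_id", "lnc_id", "r_tf_lnc")])
  coex <- unique(triples[, c("lnc_id", "gene_id", "r_lnc_gene")])
  edges <- rbind(
    data.frame(from = bind$tf_id, to = bind$lnc_id,
               relation = rep("binds", nrow(bind)),
               score = abs(bind$r_tf_lnc), stringsAsFactors = FALSE),
    data.frame(from = coex$lnc_id, to = coex$gene_id,
               relation = rep("coexpressed", nrow(coex)),
               score = abs(coex$r_lnc_gene), stringsAsFactors = FALSE))
  regulatory_network(nodes, edges)
}

#' Extract the top-N core of a network or triple table
#'
#' Edges (or triples) are sorted by score descending — ties broken by the
#' stronger correlation component, then lexicographic ids — and the top
#' `top_n` kept with their induced nodes; degrees are recomputed on the
#' core. The canonical cores keep the top 100 TF-lncRNA pairs and the top
#' 500 TF-lncRNA-gene triples. Asking for more than is available returns
#' everything with a notice.
#'
#' @param x a `regulatory_network` or a triples data.frame.
#' @param top_n number of edges/triples to keep (>= 1).
#' @return same shape as the input: a core `regulatory_network`, or a list
#'   with the core `triples` and their `network`.
#' @export
extract_core <- function(x, top_n) {
  stopifnot(top_n >= 1)
  if (inherits(x, "regulatory_network")) {
    e <- x$edges
    if (top_n > nrow(e)) {
      message(sprintf("extract_core: top_n = %d exceeds %d available edges",
                      top_n, nrow(e)))
      top_n <- nrow(e)
    }
    e <- e[order(-e$score, e$from, e$to), , drop = FALSE]
    core_e <- utils::head(e, top_n)
    keep <- x$nodes$id %in% c(core_e$from, core_e$to)
    net <- regulatory_network(x$nodes[keep, , drop = FALSE], core_e)
    attr(net, "core_tf") <- attr(x, "core_tf")
    return(net)
  }
  tr <- x
  if (top_n > nrow(tr)) {
    message(sprintf("extract_core: top_n = %d exceeds %d available triples",
                    top_n, nrow(tr)))
    top_n <- nrow(tr)
  }
  tr <- tr[order(-tr$score, -pmax(abs(tr$r_tf_lnc), abs(tr$r_lnc_gene)),
                 tr$tf_id, tr$lnc_id, tr$gene_id), , drop = FALSE]
  core <- utils::head(tr, top_n)
  rownames(core) <- NULL
  list(triples = core, network = triples_to_network(core))
}

#' Export / import a regulatory network for Cytoscape
#'
#' SIF carries one `source<TAB>relation<TAB>target` line per edge (scores
#' and node types are not part of the format); GraphML (via `igraph`)
#' carries node types and edge relations/scores, so a GraphML round trip
#' reconstructs the network exactly.
#'
#' @param network a `regulatory_network`.
#' @param file output/input path.
#' @param format `"sif"` or `"graphml"`.
#' @return `export_network` returns `network` invisibly. `read_network`
#'   returns a `regulatory_network` (from GraphML) or an edge data.frame
#'   `from`, `relation`, `to` (from SIF).
#' @export
export_network <- function(network, file, format = c("sif", "graphml")) {
  stopifnot(inherits(network, "regulatory_network"))
  format <- match.arg(format)
  if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", network$edges$from,
                       network$edges$relation, network$edges$to), file)
  } else {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("from", "to", "relation", "score")],
      directed = FALSE,
      vertices = network$nodes[, c("id", "type")])
    igraph::write_graph(g, file, format = "graphml")
  }
  invisible(network)
}

#' @rdname export_network
#' @export
read_network <- function(file, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    df <- utils::read.table(file, sep = "\t", header = FALSE,
                            col.names = c("from", "relation", "to"),
                            stringsAsFactors = FALSE)
    return(df)
  }
  g <- igraph::read_graph(file, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name, type = igraph::V(g)$type,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      relation = igraph::E(g)$relation,
                      score = igraph::E(g)$score,
                      stringsAsFactors = FALSE)
  regulatory_network(nodes, edges)
}
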