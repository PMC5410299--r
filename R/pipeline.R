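#' Generate a complete synthetic study
#'
#' Runs every generator stage — expression matrix, coordinates, term sets,
#' promoters/motifs, TF targets, qPCR Ct table — and assembles the combined
#' ground-truth record. The qPCR validation panel picks up to five planted
#' lncRNAs (module hubs first) with true relative expressions derived from
#' their planted fold changes against a low-abundance baseline. With
#' `outdir` set, all artifacts are written as plain-text files (TSV, BED,
#' GMT, FASTA, YAML).
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory (created if missing).
#' @return list with `em` (linear-scale expression matrix), `coords`,
#'   `term_sets` (`sets`, `universe`), `promoters`, `motifs`, `tf_targets`,
#'   `ct_table`, `truth`, `config`.
#' @export
simulate_all <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ge <- generate_expression(config)
  truth <- ge$truth
  feat <- rownames(ge$em$values)

  co <- generate_coordinates(config, feat, truth)
  truth$cis_pairs <- co$cis_pairs

  ts <- generate_term_sets(config, truth)
  truth$enriched_terms <- ts$enriched_terms

  pm <- generate_promoters_and_motifs(config, truth)
  truth$site_only_pairs <- pm$site_pairs[!pm$site_pairs$coupled,
                                         c("tf_id", "lnc_id")]
  rownames(truth$site_only_pairs) <- NULL

  tf_targets <- generate_tf_targets(config, truth)
  truth$tf_targets <- tf_targets

  # qPCR panel: planted lncRNAs, truth fold change from the planted effect
  panel <- utils::head(unique(c(names(truth$module_members),
                                truth$de_features$feature_id)), 5)
  panel <- intersect(panel, truth$de_features$feature_id)
  dirs <- truth$de_features$direction[match(panel,
                                            truth$de_features$feature_id)]
  rel_control <- 0.05 # lncRNA abundance relative to the reference gene
  tre <- data.frame(
    target_id = panel,
    rel_case = rel_control * 2^(ifelse(dirs == "up", 1, -1) *
                                  config$effect_log2fc),
    rel_control = rel_control,
    stringsAsFactors = FALSE)
  ct_table <- if (nrow(tre)) generate_ct_table(config, tre) else NULL
  truth$qpcr_panel <- if (nrow(tre))
    data.frame(target_id = panel, direction = dirs,
               stringsAsFactors = FALSE) else NULL

  sim <- list(em = ge$em, coords = co$coords, term_sets = ts,
              promoters = pm$promoters, motifs = pm$motifs,
              tf_targets = tf_targets, ct_table = ct_table,
              truth = truth, config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outdir, x)
    write_expression_matrix(ge$em, fp("expression_matrix.tsv"),
                            fp("sample_groups.tsv"),
                            fp("feature_biotypes.tsv"))
    write_bed(co$coords, fp("features.bed"))
    write_gmt(ts$sets, fp("term_sets.gmt"))
    write_fasta(pm$promoters, fp("promoters.fasta"))
    write_motifs(pm$motifs, fp("motifs.tsv"))
    write_tsv(data.frame(
      tf_id = rep(names(tf_targets), lengths(tf_targets)),
      gene_id = unlist(tf_targets, use.names = FALSE),
      stringsAsFactors = FALSE), fp("tf_targets.tsv"))
    if (!is.null(ct_table)) write_tsv(ct_table, fp("ct_table.tsv"))
    write_ground_truth(truth, fp("ground_truth.yaml"))
  }
  sim
}

#' Run the full inference workflow on a simulated (or loaded) study
#'
#' Chains every analysis stage at the canonical thresholds: log2 transform
#' and quantile normalization; differential expression (`|FC| > 1.5`,
#' `FDR < 0.05`); lncRNA-mRNA coexpression over the DE-passing features
#' (`|PCC| > 0.8`, `p < 0.01`); guilt-by-association term enrichment
#' (`FDR < 0.01`) with the global top-200 term ranking; cis candidates
#' within the genomic window; TF-lncRNA pairing (binding gate + correlation,
#' `FDR < 0.01`) with the top-100 pair core; the TF-lncRNA-gene triple
#' network with the top-500 triple core; and the qPCR 2^-deltaCt summary.
#'
#' @param sim a study as returned by [simulate_all()].
#' @param fc_threshold,de_fdr DE thresholds.
#' @param r_threshold,p_threshold coexpression thresholds.
#' @param enrich_fdr enrichment significance threshold.
#' @param tf_fdr TF-lncRNA pair threshold.
#' @param top_terms,top_pairs,top_triples report/core sizes.
#' @param de_method location-test strategy, see [de_test()].
#' @return list with elements `de` (full table), `de_up`, `de_down`,
#'   `edges`, `enrichment`, `top_terms`, `cis_candidates`, `cis`,
#'   `tf_pairs`, `tf_network`, `tf_core`, `triples`, `triple_core`,
#'   `qpcr`, and the normalized matrix `em_norm`.
#' @export
run_lncnet <- function(sim,
                       fc_threshold = 1.5, de_fdr = 0.05,
                       r_threshold = 0.8, p_threshold = 0.01,
                       enrich_fdr = 0.01, tf_fdr = 0.01,
                       top_terms = 200, top_pairs = 100, top_triples = 500,
                       de_method = "common") {
  em <- sim$em
  if (em$scale == "linear") em <- log2_transform(em)
  em <- quantile_normalize(em)

  de <- de_results(em, method = de_method, fc_threshold = fc_threshold,
                   fdr_threshold = de_fdr)
  parts <- filter_de(de, fc_threshold, de_fdr)
  de_lnc <- de$feature_id[de$passes & de$biotype == "lncRNA"]
  de_mrna <- de$feature_id[de$passes & de$biotype == "mRNA"]

  vals <- em$values
  edges <- build_coexpression(vals[de_lnc, , drop = FALSE],
                              vals[de_mrna, , drop = FALSE],
                              r_threshold, p_threshold)

  universe <- names(em$biotypes)[em$biotypes == "mRNA"]
  enrichment <- annotate_lncrnas(edges, sim$term_sets$sets, universe,
                                 fdr_threshold = enrich_fdr)
  top_terms_tab <- if (nrow(enrichment))
    rank_terms_global(enrichment, top_n = top_terms) else NULL

  coords <- sim$coords
  lnc_coords <- coords[coords$feature_id %in% de_lnc, , drop = FALSE]
  gene_coords <- coords[coords$feature_id %in% de_mrna, , drop = FALSE]
  cands <- window_neighbors(lnc_coords, gene_coords,
                            window = sim$config$cis_window_bp)
  cis <- cis_pairs(cands, edges)

  binding <- scan_promoters(sim$promoters, sim$motifs)
  tfp <- tf_lnc_pairs(binding,
                      vals[intersect(sim$motifs$tf_id, rownames(vals)), ,
                           drop = FALSE],
                      vals[names(sim$promoters), , drop = FALSE],
                      fdr_threshold = tf_fdr)
  net2 <- build_two_element_network(tfp)
  core2 <- extract_core(net2, min(top_pairs, max(1, nrow(net2$edges))))
  net3 <- build_three_element_network(tfp, edges, sim$tf_targets)
  core3 <- if (nrow(net3$triples))
    extract_core(net3$triples, min(top_triples, nrow(net3$triples))) else NULL

  qpcr <- if (!is.null(sim$ct_table))
    qpcr_summary(compute_rq(sim$ct_table)) else NULL

  list(em_norm = em, de = de, de_up = parts$up, de_down = parts$down,
       edges = edges, enrichment = enrichment, top_terms = top_terms_tab,
       cis_candidates = cands, cis = cis,
       tf_pairs = tfp, tf_network = net2, tf_core = core2,
       triples = net3$triples, triple_core = core3,
       qpcr = qpcr)
}
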