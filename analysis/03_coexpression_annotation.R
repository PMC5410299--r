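#!/usr/bin/env Rscript
# Stage 3 — lncRNA-mRNA coexpression and guilt-by-association annotation.
#
# For every dysregulated lncRNA, Pearson correlation against every
# dysregulated mRNA across all 8 pooled samples; edges pass at |PCC| > 0.8
# with p < 0.01. Each lncRNA's coexpressed genes are then tested for term
# enrichment with the hypergeometric upper tail (BH within each lncRNA's
# family, FDR < 0.01) and terms are ranked globally by their best p.

library(lncnet)

dir.create("results/coexpression", showWarnings = FALSE, recursive = TRUE)
em <- quantile_normalize(log2_transform(read_expression_matrix(
  "results/study/expression_matrix.tsv",
  "results/study/sample_groups.tsv",
  "results/study/feature_biotypes.tsv")))
de_lnc <- read_tsv("results/de/lncRNA_de.tsv")
de_mrna <- read_tsv("results/de/mRNA_de.tsv")
truth <- read_ground_truth("results/study/ground_truth.yaml")

v <- em$values
edges <- build_coexpression(
  v[de_lnc$feature_id[de_lnc$passes], , drop = FALSE],
  v[de_mrna$feature_id[de_mrna$passes], , drop = FALSE])
write_tsv(edges, "results/coexpression/edges.tsv")

sets <- read_gmt("results/study/term_sets.gmt")
universe <- names(em$biotypes)[em$biotypes == "mRNA"]
enr <- annotate_lncrnas(edges, sets, universe, fdr_threshold = 0.01)
write_tsv(enr, "results/coexpression/enrichment.tsv")
top <- rank_terms_global(enr, top_n = 200)
write_tsv(top, "results/coexpression/top_terms.tsv")

pk <- paste(truth$coexpression_pairs$lnc_id, truth$coexpression_pairs$mrna_id)
cat(sprintf("passing edges: %d; planted module edges recovered: %.2f\n",
            nrow(edges),
            mean(pk %in% paste(edges$lnc_id, edges$mrna_id))))
cat(sprintf("planted terms among the top %d ranks: %d of %d\n",
            nrow(truth$enriched_terms),
            sum(truth$enriched_terms$term_id %in%
                  head(top$term_id, nrow(truth$enriched_terms))),
            nrow(truth$enriched_terms)))
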