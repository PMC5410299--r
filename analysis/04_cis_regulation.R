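#!/usr/bin/env Rscript
# Stage 4 — cis-regulatory candidates.
#
# Dysregulated lncRNAs are intersected with their coexpressed genes lying
# within 300 kbp up- or downstream on the same chromosome (boundary gap,
# strand only labels the side). Writes the cis-pair table and per-lncRNA
# counts, and checks recovery of the planted cis pairs.

library(lncnet)

dir.create("results/cis", showWarnings = FALSE, recursive = TRUE)
coords <- read_bed("results/study/features.bed")
de_lnc <- read_tsv("results/de/lncRNA_de.tsv")
de_mrna <- read_tsv("results/de/mRNA_de.tsv")
edges <- read_tsv("results/coexpression/edges.tsv")
truth <- read_ground_truth("results/study/ground_truth.yaml")

cands <- window_neighbors(
  coords[coords$feature_id %in% de_lnc$feature_id[de_lnc$passes], ],
  coords[coords$feature_id %in% de_mrna$feature_id[de_mrna$passes], ],
  window = 300000)
cp <- cis_pairs(cands, edges)
write_tsv(cp$pairs, "results/cis/cis_pairs.tsv")
write_tsv(cp$counts, "results/cis/cis_counts.tsv")

tk <- paste(truth$cis_pairs$lnc_id, truth$cis_pairs$gene_id)
cat(sprintf("window candidates: %d; cis pairs: %d over %d lncRNAs\n",
            nrow(cands), nrow(cp$pairs), nrow(cp$counts)))
cat(sprintf("planted cis pairs recovered: %.2f (losses are module edges below the PCC cut)\n",
            mean(tk %in% paste(cp$pairs$lnc_id, cp$pairs$gene_id))))
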