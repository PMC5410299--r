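#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic two-group lncRNA/mRNA study.
#
# A desk-scale stand-in for a case-control microarray experiment: 5 case vs
# 3 control samples, 500 lncRNAs + 2000 mRNAs, 10% of features planted as
# differentially expressed at |log2FC| = 2, five lncRNA-mRNA coexpression
# modules (pooled target correlations 0.95 .. -0.85), annotation terms
# enriched for the modules, cis neighbors inside the 300 kbp window,
# promoter motif plants for TF-lncRNA pairs, and a qPCR Ct table for a
# 5-lncRNA validation panel (20 tumors vs 10 controls).
#
# Everything downstream reads the plain-text files written here; the
# ground-truth record makes every plant auditable.

library(lncnet)

outdir <- "results/study"
cfg <- sim_config(seed = 101)
sim <- simulate_all(cfg, outdir = outdir)

cat("study written to", outdir, "\n")
print(sim$em)
cat(sprintf("planted: %d DE features, %d module edges, %d cis pairs, %d TF-lncRNA pairs\n",
            nrow(sim$truth$de_features),
            nrow(sim$truth$coexpression_pairs),
            nrow(sim$truth$cis_pairs),
            nrow(sim$truth$tf_lnc_pairs)))
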