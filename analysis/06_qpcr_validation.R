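#!/usr/bin/env Rscript
# Stage 6 — qPCR validation by 2^-deltaCt.
#
# Relative quantities per record (deltaCt = Ct_target - Ct_reference,
# rq = 2^-deltaCt), group-level signed fold changes, and agreement of the
# fold-change direction with the planted truth for the 5-lncRNA panel.

library(lncnet)

dir.create("results/qpcr", showWarnings = FALSE, recursive = TRUE)
ct <- read_tsv("results/study/ct_table.tsv")
truth <- read_ground_truth("results/study/ground_truth.yaml")

rq <- compute_rq(ct)
write_tsv(rq, "results/qpcr/relative_quantities.tsv")
summ <- qpcr_summary(rq)
write_tsv(summ, "results/qpcr/fold_changes.tsv")
print(summ)

panel <- truth$qpcr_panel
agree <- summ$direction[match(panel$target_id, summ$target_id)] ==
  panel$direction
cat(sprintf("fold-change sign agrees with the planted direction for %d of %d targets\n",
            sum(agree), length(agree)))
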