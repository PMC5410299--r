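# lncnet

Guilt-by-association functional inference for long non-coding RNAs
(lncRNAs) from two-group expression profiles — the analysis chain used in
case–control lncRNA profiling studies (e.g. diffuse large B-cell lymphoma
cell lines vs normal B cells), implemented as a tested, reusable R package
with a synthetic-data generator that plants a known ground truth.

Most lncRNAs carry no functional annotation, so their function is inferred
from the protein-coding genes they co-express with. The package implements
the full chain for researchers who want that workflow reproducible and
auditable end to end:

1. **Differential expression** — log2 transform, quantile normalization,
   a location test per feature (common-variance default; Welch/Student
   pluggable), Benjamini–Hochberg FDR, and the signed fold-change filter
   |FC| > 1.5 with FDR < 0.05, where FC = 2^(x̄_case − x̄_ctrl) reported as
   −1/FC when below 1.
2. **Coexpression** — Pearson correlation of every dysregulated
   lncRNA–mRNA pair over all pooled samples, edges at |PCC| > 0.8 and
   p < 0.01 (t-transform, n − 2 df).
3. **Annotation (guilt by association)** — hypergeometric upper-tail
   P(X ≥ k) enrichment of each lncRNA's coexpressed genes in GMT term
   sets, BH-adjusted per lncRNA, significant at FDR < 0.01; global
   top-200 term ranking.
4. **Cis regulation** — coexpressed genes within 300 kbp (boundary gap,
   up- or downstream) of the lncRNA on the same chromosome.
5. **Trans regulation** — TF–lncRNA pairs gated by promoter motif
   occurrence (IUPAC consensus scan, both strands) and scored by
   TF-mRNA/lncRNA correlation at FDR < 0.01; top-100 two-element core and
   top-500 TF–lncRNA–gene triple core (triple score = weaker link);
   SIF/GraphML export for Cytoscape.
6. **qPCR validation** — 2^−ΔCt relative quantification
   (ΔCt = Ct_target − Ct_reference) and group-level signed fold changes.

Because the study design this models has no public dataset, the package
ships a first-class simulator (`sim_config()`, `simulate_all()`) that
generates the expression matrix, BED coordinates, GMT term sets, promoter
FASTA + motif table, TF-target table and Ct tables with every plant
recorded in a machine-readable ground-truth file.

## Worked example

The `analysis/` directory holds the numbered workflow; each stage reads the
previous stage's plain-text outputs from `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_coexpression_annotation.R
Rscript analysis/04_cis_regulation.R
Rscript analysis/05_trans_network.R
Rscript analysis/06_qpcr_validation.R
```

With the committed seed (101) this prints, stage by stage:

```
expr_matrix: 2500 features (500 lncRNA, 2000 mRNA) x 8 samples (5 case, 3 control), linear scale
planted: 250 DE features, 50 module edges, 10 cis pairs, 10 TF-lncRNA pairs

dysregulated lncRNAs: 44 (15 up, 29 down)
dysregulated mRNAs: 217 (111 up, 106 down)
sensitivity vs planted truth: 0.996; realized FDR: 0.046

passing edges: 4844; planted module edges recovered: 0.76
planted terms among the top 5 ranks: 5 of 5

window candidates: 10; cis pairs: 6 over 4 lncRNAs
planted cis pairs recovered: 0.60 (losses are module edges below the PCC cut)

pairs with >= 1 site: 210; passing at FDR < 0.01: 1

fold-change sign agrees with the planted direction for 5 of 5 targets
```

Reading those numbers: essentially every planted differentially expressed
feature is recovered at a realized FDR under 5%; all five planted
annotation terms rank at the very top of the global term ranking; the
planted modules at pooled correlation 0.95 are recovered reliably while
the weaker plants (|r| = 0.85–0.90) sit near the |PCC| > 0.8 threshold at
n = 8 and are recovered partially — which is why some planted cis pairs
drop out (the cis call requires the coexpression edge). The trans stage at
5 vs 3 samples passes very few pairs, because FDR < 0.01 over 210 tested
pairs demands near-perfect correlations at eight observations; the
vignette discusses this and the core-recovery property is demonstrated at
the 20-vs-10 validation-cohort geometry. The qPCR stage recovers every
planted direction, with group fold changes close to the planted ±4.

See `vignette("lncnet-methods")` for the statistical model, parameter
defaults and design rationale.

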