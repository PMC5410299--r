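test_that("config invariants are enforced", {
  expect_error(small_config(n_case = 1), class = "lncnet_config_error")
  expect_error(small_config(de_fraction = 1.5), class = "lncnet_config_error")
  # planted features must be DE-eligible
  expect_error(small_config(de_fraction = 0.01),
               class = "lncnet_config_error")
  expect_error(small_config(term_size_range = c(2, 4)),
               class = "lncnet_config_error")
  expect_error(small_config(motif_length = 500, promoter_length_bp = 100),
               class = "lncnet_config_error")
})

test_that("nothing is planted under de_fraction = 0", {
  sim <- generate_expression(null_config(seed = 2))
  expect_equal(nrow(sim$truth$de_features), 0)
  expect_null(sim$truth$coexpression_pairs)
})

test_that("a target correlation of exactly 1 gives a sample PCC of exactly 1", {
  cfg <- small_config(module_specs = list(list(lnc = 1, n = 2, r = 1)),
                      tf_lnc_specs = list(), seed = 5)
  sim <- generate_expression(cfg)
  y <- log2(sim$em$values)
  for (m in seq_len(nrow(sim$truth$coexpression_pairs))) {
    p <- sim$truth$coexpression_pairs[m, ]
    expect_identical(cor(y[p$lnc_id, ], y[p$mrna_id, ]), 1)
  }
})

test_that("identical configs give byte-identical serialized studies", {
  cfg <- small_config(seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_all(cfg, outdir = d1)
  simulate_all(cfg, outdir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("every ground-truth plant is verifiable from the generated files", {
  d <- withr::local_tempdir()
  sim <- simulate_all(small_config(seed = 13), outdir = d)
  truth <- read_ground_truth(file.path(d, "ground_truth.yaml"))

  # planted terms contain their whole module
  sets <- read_gmt(file.path(d, "term_sets.gmt"))
  for (i in seq_len(nrow(truth$enriched_terms))) {
    hub <- truth$enriched_terms$lnc_id[i]
    mem <- sim$truth$module_members[[hub]]
    expect_true(all(mem %in% sets[[truth$enriched_terms$term_id[i]]]))
  }

  # planted cis gaps are exactly as recorded in the BED intervals
  coords <- read_bed(file.path(d, "features.bed"))
  rownames(coords) <- coords$feature_id
  for (i in seq_len(nrow(truth$cis_pairs))) {
    cp <- truth$cis_pairs[i, ]
    g <- interval_gap(coords[cp$lnc_id, ], coords[cp$gene_id, ])
    expect_identical(g, as.integer(cp$distance))
  }

  # planted TF sites occur; unplanted pairs are site-free on both strands
  prom <- read_fasta(file.path(d, "promoters.fasta"))
  motifs <- read_motifs(file.path(d, "motifs.tsv"))
  cons <- setNames(motifs$consensus, motifs$tf_id)
  planted <- rbind(truth$tf_lnc_pairs[, c("tf_id", "lnc_id")],
                   truth$site_only_pairs)
  for (i in seq_len(nrow(planted)))
    expect_gte(scan_motif(prom[[planted$lnc_id[i]]],
                          cons[[planted$tf_id[i]]]), 1L)
  key <- paste(planted$tf_id, planted$lnc_id)
  for (tf in names(cons)) {
    for (lnc in names(prom)) {
      if (paste(tf, lnc) %in% key) next
      expect_identical(scan_motif(prom[[lnc]], cons[[tf]]), 0L)
    }
  }
})

test_that("planted effects are recovered by the fold-change estimate", {
  # one planted feature at |log2FC| = 2: the estimated signed FC should sit
  # within +/-1.5 of the true +/-4 in at least 95% of seeds
  hits <- vapply(1:200, function(s) {
    cfg <- sim_config(n_case = 5, n_control = 3, n_lnc = 5, n_mrna = 15,
                      de_fraction = 0.05, effect_log2fc = 2, noise_sd = 0.3,
                      module_specs = list(), tf_lnc_specs = list(),
                      n_site_only_pairs = 0, seed = s)
    sim <- generate_expression(cfg)
    tr <- sim$truth$de_features
    y <- log2(sim$em$values)
    est <- signed_fold_change(
      mean(y[tr$feature_id, sim$em$groups == "case"]),
      mean(y[tr$feature_id, sim$em$groups == "control"]))
    abs(est - tr$true_fc) <= 1.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("coordinate decoys are separated beyond the cis window", {
  sim <- simulate_all(small_config(seed = 17))
  cands <- window_neighbors(
    sim$coords[sim$coords$feature_id %in% names(sim$em$biotypes)[sim$em$biotypes == "lncRNA"], ],
    sim$coords[sim$coords$feature_id %in% names(sim$em$biotypes)[sim$em$biotypes == "mRNA"], ],
    window = sim$config$cis_window_bp)
  # the only window neighbors are the planted cis pairs
  expect_setequal(paste(cands$lnc_id, cands$gene_id),
                  paste(sim$truth$cis_pairs$lnc_id,
                        sim$truth$cis_pairs$gene_id))
})

test_that("Ct tables encode the planted relative expression", {
  cfg <- small_config(seed = 19)
  tre <- data.frame(target_id = "T1", rel_case = 0.5, rel_control = 0.5)
  ct <- generate_ct_table(cfg, tre, n_case = 20, n_control = 10,
                          noise_sd = 0.2)
  rq <- compute_rq(ct)
  expect_equal(mean(rq$rq), 0.5, tolerance = 0.15)

  # noise-free: relative expression 0.5 means delta Ct of exactly 1
  ct0 <- generate_ct_table(cfg, tre, n_case = 3, n_control = 2,
                           noise_sd = 0)
  expect_equal(ct0$ct_target - ct0$ct_reference, rep(1, 5), tolerance = 1e-12)

  expect_error(generate_ct_table(cfg, data.frame(target_id = "T1",
                                                 rel_case = -1,
                                                 rel_control = 1)),
               class = "lncnet_input_error")
})
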