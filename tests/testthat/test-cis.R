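iv <- function(chrom, start, end) list(chrom = chrom, start = start, end = end)

test_that("interval gap: overlap, touch, separation, incomparability", {
  expect_identical(interval_gap(iv("chr1", 100, 200), iv("chr1", 150, 250)), 0L)
  expect_identical(interval_gap(iv("chr1", 100, 200), iv("chr1", 200, 300)), 0L)
  expect_identical(interval_gap(iv("chr1", 100, 200), iv("chr1", 500, 600)), 300L)
  expect_identical(interval_gap(iv("chr1", 100, 200), iv("chr2", 100, 200)),
                   NA_integer_)
  expect_error(interval_gap(iv("chr1", 200, 100), iv("chr1", 1, 2)),
               class = "lncnet_input_error")
  # symmetry on random pairs
  set.seed(2)
  for (i in 1:25) {
    a <- iv("chr1", s <- sample(1e6, 1), s + sample(1e4, 1))
    b <- iv("chr1", s2 <- sample(1e6, 1), s2 + sample(1e4, 1))
    expect_identical(interval_gap(a, b), interval_gap(b, a))
  }
})

random_coords <- function(n, prefix, chroms = 4, span = 3e6) {
  data.frame(
    feature_id = sprintf("%s%04d", prefix, seq_len(n)),
    chrom = paste0("chr", sample(chroms, n, replace = TRUE)),
    start = st <- sample(span, n),
    end = st + sample(5e4, n),
    strand = sample(c("+", "-", "."), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

test_that("window neighbors match the quadratic brute force", {
  set.seed(7)
  lnc <- random_coords(50, "L")
  gene <- random_coords(200, "G")
  for (w in c(0, 1e5, 3e5)) {
    fast <- window_neighbors(lnc, gene, window = w)
    slow <- brute_force_neighbors(lnc, gene, window = w)
    expect_identical(pair_key(fast), pair_key(slow))
    m <- match(paste(fast$lnc_id, fast$gene_id),
               paste(slow$lnc_id, slow$gene_id))
    expect_identical(fast$distance, as.integer(slow$distance[m]))
  }
})

test_that("window boundaries are inclusive and monotone", {
  lnc <- data.frame(feature_id = "L1", chrom = "chr1", start = 1000,
                    end = 2000, strand = "+")
  gene <- function(gap) data.frame(feature_id = "G1", chrom = "chr1",
                                   start = 2000 + gap, end = 2000 + gap + 500,
                                   strand = "+")
  expect_equal(nrow(window_neighbors(lnc, gene(250000))), 1)
  expect_equal(nrow(window_neighbors(lnc, gene(300000))), 1) # boundary in
  expect_equal(nrow(window_neighbors(lnc, gene(300001))), 0) # boundary out

  set.seed(13)
  l2 <- random_coords(30, "L"); g2 <- random_coords(100, "G")
  prev <- character(0)
  for (w in c(1e5, 2e5, 3e5, 5e5)) {
    cur <- pair_key(window_neighbors(l2, g2, window = w))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("relative position is strand-aware and inclusion is not", {
  lnc <- data.frame(feature_id = c("Lp", "Lm"), chrom = "chr1",
                    start = c(10000, 10000), end = c(11000, 11000),
                    strand = c("+", "-"))
  gene <- data.frame(feature_id = c("Gleft", "Gright", "Gover"),
                     chrom = "chr1", start = c(1000, 20000, 10500),
                     end = c(2000, 21000, 12000), strand = "+")
  nb <- window_neighbors(lnc, gene, window = 3e5)
  expect_equal(nrow(nb), 6) # inclusion identical for both strands
  get <- function(l, g) nb$relative_position[nb$lnc_id == l & nb$gene_id == g]
  expect_equal(get("Lp", "Gleft"), "upstream")
  expect_equal(get("Lp", "Gright"), "downstream")
  expect_equal(get("Lm", "Gleft"), "downstream")
  expect_equal(get("Lm", "Gright"), "upstream")
  expect_equal(get("Lp", "Gover"), "overlapping")
})

test_that("cis pairs are the neighbor/coexpression intersection", {
  cands <- data.frame(lnc_id = c("l1", "l1", "l2"),
                      gene_id = c("g1", "g2", "g3"),
                      chrom = "chr1", distance = c(100L, 200L, 300L),
                      relative_position = "downstream")
  edges <- data.frame(lnc_id = c("l1", "l2", "l3"),
                      mrna_id = c("g1", "g9", "g3"),
                      r = c(0.9, 0.95, -0.85))
  cp <- cis_pairs(cands, edges)
  expect_equal(cp$pairs$gene_id, "g1") # g2 not coexpressed, g3 wrong lncRNA
  expect_equal(cp$pairs$r, 0.9)
  expect_equal(cp$counts, data.frame(lnc_id = "l1", n_cis_genes = 1L))
})

test_that("planted cis pairs are recovered exactly via the planted edges", {
  sim <- simulate_all(small_config(seed = 47))
  bio <- sim$em$biotypes
  cands <- window_neighbors(
    sim$coords[bio[sim$coords$feature_id] == "lncRNA", ],
    sim$coords[bio[sim$coords$feature_id] == "mRNA", ],
    window = sim$config$cis_window_bp)
  planted_edges <- data.frame(
    lnc_id = sim$truth$coexpression_pairs$lnc_id,
    mrna_id = sim$truth$coexpression_pairs$mrna_id)
  cp <- cis_pairs(cands, planted_edges)
  expect_identical(pair_key(cp$pairs[, c("lnc_id", "gene_id")]),
                   pair_key(sim$truth$cis_pairs[, c("lnc_id", "gene_id")]))
})
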