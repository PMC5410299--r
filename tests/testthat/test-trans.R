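make_pairs <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(tf_id = sprintf("TF%02d", sample(5, n, replace = TRUE)),
             lnc_id = sprintf("L%03d", seq_len(n)),
             n_sites = 1L, r = runif(n, -1, 1), p_corr = runif(n),
             fdr = runif(n), passes = TRUE, stringsAsFactors = FALSE)
}

test_that("the binding gate is sound: no sites, no test, no pass", {
  set.seed(21)
  expr <- matrix(rnorm(6 * 8), 6, 8,
                 dimnames = list(c("TF1", "TF2", "L1", "L2", "L3", "L4"),
                                 paste0("s", 1:8)))
  binding <- expand.grid(tf_id = c("TF1", "TF2"),
                         lnc_id = c("L1", "L2", "L3", "L4"),
                         stringsAsFactors = FALSE)
  binding$n_sites <- c(2L, 0L, 1L, 0L, 0L, 0L, 3L, 1L)
  out <- tf_lnc_pairs(binding, expr[1:2, ], expr[3:6, ])
  gated <- binding[binding$n_sites >= 1, ]
  expect_identical(pair_key(out[, c("tf_id", "lnc_id")]),
                   pair_key(gated[, c("tf_id", "lnc_id")]))
  expect_true(all(out$n_sites >= 1))
  # BH family is all tested pairs jointly
  expect_equal(out$fdr, bh_fdr(out$p_corr))

  # zero TFs / empty gate
  expect_equal(nrow(tf_lnc_pairs(binding[binding$n_sites == 0, ],
                                 expr[1:2, ], expr[3:6, ])), 0)
  # TF without an expression row is skipped with a notice
  binding2 <- data.frame(tf_id = "TF9", lnc_id = "L1", n_sites = 1L)
  expect_message(out2 <- tf_lnc_pairs(binding2, expr[1:2, ], expr[3:6, ]),
                 "skipped")
  expect_equal(nrow(out2), 0)
})

test_that("two-element network has bipartite edges, scores and a core TF", {
  pairs <- data.frame(tf_id = c("TF1", "TF1", "TF2"),
                      lnc_id = c("L1", "L2", "L1"),
                      r = c(0.9, -0.95, 0.85), passes = TRUE)
  net <- build_two_element_network(pairs)
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$edges$score, c(0.9, 0.95, 0.85))
  expect_equal(unname(net$degrees[c("TF1", "TF2", "L1", "L2")]),
               c(2L, 1L, 2L, 1L))
  expect_equal(attr(net, "core_tf"), "TF1")

  one <- build_two_element_network(
    data.frame(tf_id = "TF1", lnc_id = "L1", r = 0.9, passes = TRUE))
  expect_equal(nrow(one$nodes), 2)
  expect_equal(unname(one$degrees), c(1L, 1L))
})

test_that("degrees equal an edge recount on random networks", {
  for (seed in 1:5) {
    pairs <- make_pairs(200, seed)
    net <- build_two_element_network(pairs)
    recount <- table(c(net$edges$from, net$edges$to))
    expect_equal(net$degrees[names(recount)],
                 setNames(as.integer(recount), names(recount)))
    expect_equal(sum(net$degrees), 2L * nrow(net$edges))
  }
})

test_that("network container rejects self-edges and duplicates", {
  nodes <- data.frame(id = c("a", "b"), type = c("TF", "lncRNA"))
  expect_error(regulatory_network(
    nodes, data.frame(from = "a", to = "a", relation = "binds", score = 1)),
    class = "lncnet_input_error")
  dup <- data.frame(from = c("a", "b"), to = c("b", "a"),
                    relation = "binds", score = c(1, 1))
  expect_error(regulatory_network(nodes, dup),
               class = "lncnet_input_error")
})

test_that("triples require all three conditions and match brute force", {
  pairs <- data.frame(tf_id = c("TF1", "TF2"), lnc_id = c("L1", "L2"),
                      r = c(0.9, -0.92), passes = TRUE)
  edges <- data.frame(lnc_id = c("L1", "L1", "L2"),
                      mrna_id = c("g1", "g2", "g3"),
                      r = c(0.85, 0.99, -0.9))
  targets <- list(TF1 = c("g1", "g9"), TF2 = c("g1")) # g2/g3 not targets
  tri <- build_three_element_network(pairs, edges, targets)
  expect_equal(nrow(tri$triples), 1)
  expect_equal(tri$triples$gene_id, "g1")
  expect_equal(tri$triples$score, min(0.9, 0.85))
  expect_setequal(tri$network$nodes$type, c("TF", "lncRNA", "gene"))

  # brute-force enumeration over a random instance
  set.seed(33)
  P <- data.frame(tf_id = sprintf("TF%02d", sample(10, 40, TRUE)),
                  lnc_id = sprintf("L%02d", sample(15, 40, TRUE)),
                  r = runif(40, -1, 1), passes = TRUE)
  P <- P[!duplicated(P[, 1:2]), ]
  E <- data.frame(lnc_id = sprintf("L%02d", sample(15, 120, TRUE)),
                  mrna_id = sprintf("g%03d", sample(60, 120, TRUE)),
                  r = runif(120, -1, 1))
  E <- E[!duplicated(E[, 1:2]), ]
  Tg <- lapply(1:10, function(i) sprintf("g%03d", sample(60, 20)))
  names(Tg) <- sprintf("TF%02d", 1:10)
  got <- build_three_element_network(P, E, Tg)$triples
  want <- list()
  for (i in seq_len(nrow(P))) for (j in seq_len(nrow(E))) {
    if (P$lnc_id[i] == E$lnc_id[j] && E$mrna_id[j] %in% Tg[[P$tf_id[i]]])
      want[[length(want) + 1]] <-
        paste(P$tf_id[i], P$lnc_id[i], E$mrna_id[j])
  }
  expect_setequal(paste(got$tf_id, got$lnc_id, got$gene_id),
                  unlist(want))
  # referential integrity: both component edges exist
  expect_true(all(paste(got$tf_id, got$lnc_id) %in%
                    paste(P$tf_id, P$lnc_id)))
  expect_true(all(paste(got$lnc_id, got$gene_id) %in%
                    paste(E$lnc_id, E$mrna_id)))

  expect_message(z <- build_three_element_network(pairs, edges, list()),
                 "empty tf_targets")
  expect_equal(nrow(z$triples), 0)
})

test_that("core extraction is a sort-and-slice with clean tie-breaks", {
  pairs <- make_pairs(120, seed = 8)
  net <- build_two_element_network(pairs)
  core <- extract_core(net, 25)
  expect_equal(nrow(core$edges), 25)
  # min score inside >= max score outside
  outside <- setdiff(paste(net$edges$from, net$edges$to),
                     paste(core$edges$from, core$edges$to))
  out_scores <- net$edges$score[paste(net$edges$from, net$edges$to) %in% outside]
  expect_gte(min(core$edges$score), max(out_scores))
  # full-sort oracle
  expect_equal(sort(core$edges$score, decreasing = TRUE),
               head(sort(net$edges$score, decreasing = TRUE), 25))
  # induced nodes only
  expect_setequal(core$nodes$id, unique(c(core$edges$from, core$edges$to)))

  expect_message(all_back <- extract_core(net, 10000), "exceeds")
  expect_equal(nrow(all_back$edges), nrow(net$edges))
  top1 <- extract_core(net, 1)
  expect_equal(top1$edges$score, max(net$edges$score))
})

test_that("SIF and GraphML round-trip the network", {
  pairs <- make_pairs(40, seed = 10)
  net <- build_two_element_network(pairs)
  d <- withr::local_tempdir()

  sif <- file.path(d, "net.sif")
  export_network(net, sif, format = "sif")
  expect_equal(length(readLines(sif)), nrow(net$edges))
  back <- read_network(sif, format = "sif")
  expect_equal(back[order(back$from, back$to), c("from", "relation", "to")],
               net$edges[order(net$edges$from, net$edges$to),
                         c("from", "relation", "to")],
               ignore_attr = TRUE)

  gml <- file.path(d, "net.graphml")
  export_network(net, gml, format = "graphml")
  back2 <- read_network(gml, format = "graphml")
  expect_setequal(paste(back2$nodes$id, back2$nodes$type),
                  paste(net$nodes$id, net$nodes$type))
  ek <- function(e) {
    k <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    e <- e[order(k), ]; rownames(e) <- NULL
    e$key <- sort(k); e
  }
  a <- ek(back2$edges); b <- ek(net$edges)
  expect_equal(a$key, b$key)
  expect_equal(a$relation, b$relation)
  expect_equal(a$score, b$score, tolerance = 1e-9)
  expect_equal(back2$degrees[names(net$degrees)], net$degrees)

  # GraphML is well-formed XML with the expected attribute keys
  x <- xml2::read_xml(gml)
  expect_equal(xml2::xml_name(x), "graphml")
  expect_error(export_network(net, file.path(d, "x"), format = "gexf"))
})

test_that("one-edge network exports a single SIF line", {
  net <- build_two_element_network(
    data.frame(tf_id = "TF1", lnc_id = "L1", r = -0.7, passes = TRUE))
  f <- withr::local_tempfile()
  export_network(net, f, format = "sif")
  expect_equal(readLines(f), "TF1\tbinds\tL1")
})
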