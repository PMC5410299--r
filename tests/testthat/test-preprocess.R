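test_that("log2 transform flips the scale marker exactly once", {
  em <- tiny_em(matrix(c(1, 8, 2, 4, 1, 16, 4, 2), 2, 4))
  lg <- log2_transform(em)
  expect_equal(lg$values[1, 1], 0) # log2(1)
  expect_equal(lg$values[2, 1], 3) # log2(8)
  expect_equal(lg$scale, "log2")
  expect_error(log2_transform(lg), class = "lncnet_state_error")
})

test_that("quantile normalization equalizes column distributions and is idempotent", {
  # hand-computed 2x2 case: columns (1,3) and (2,4) both become (1.5, 3.5)
  m <- matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  q <- quantile_normalize(m)
  expect_equal(unname(q), matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))

  set.seed(42)
  x <- matrix(rnorm(300), 30, 10,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:10)))
  q1 <- quantile_normalize(x)
  ref <- sort(q1[, 1])
  for (j in 2:ncol(q1)) expect_equal(sort(q1[, j]), ref, ignore_attr = TRUE)
  # ranks preserved within columns
  for (j in seq_len(ncol(x)))
    expect_equal(rank(q1[, j], ties.method = "first"),
                 rank(x[, j], ties.method = "first"))
  expect_identical(quantile_normalize(q1), q1)
  # already-identical columns are a fixed point
  same <- matrix(rep(c(5, 1, 3), 4), 3, 4,
                 dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_equal(quantile_normalize(same), same)
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(1)
  x <- matrix(rnorm(200), 20, 10)
  dimnames(x) <- list(sprintf("f%d", 1:20), sprintf("s%d", 1:10))
  expect_equal(unname(quantile_normalize(x)),
               unname(limma::normalizeQuantiles(x)), tolerance = 1e-12)
})

test_that("signed fold change follows the +/- ratio convention", {
  expect_equal(signed_fold_change(3, 1), 4)
  expect_equal(signed_fold_change(1, 3), -4)
  expect_equal(signed_fold_change(2, 2), 1)
  # a 52.78-fold down-regulated feature has linear ratio 1/52.78
  expect_equal(signed_fold_change(log2(1 / 52.78), 0), -52.78,
               tolerance = 1e-12)
  # antisymmetry: swapping groups negates every value
  set.seed(9)
  a <- rnorm(50); b <- rnorm(50)
  expect_identical(signed_fold_change(a, b), -signed_fold_change(b, a))
})

test_that("location tests behave at the degenerate corners", {
  # all case values equal all control values: no effect, p = 1
  em <- tiny_em(matrix(c(2, 5, 3, 6, 2, 5, 3, 6), 2, 4), scale = "log2")
  for (m in c("common", "welch", "student")) {
    p <- de_test(em, method = m)$p_raw
    expect_equal(p, c(1, 1), tolerance = 1e-9)
  }
  # complete separation with zero within-group variance: p below any alpha
  em2 <- tiny_em(matrix(c(10, 10, 10, 10, 0, 0, 0, 0), 1, 8,
                        dimnames = list("f1", NULL)),
                 n_case = 4, n_control = 4, scale = "log2")
  expect_lt(de_test(em2, method = "welch")$p_raw, 1e-6)
  em_small <- tiny_em(matrix(1:6, 2, 3), n_case = 2, n_control = 1,
                      scale = "log2")
  expect_error(de_test(em_small), class = "lncnet_input_error")
})

test_that("welch strategy matches stats::t.test row by row", {
  sim <- generate_expression(small_config(seed = 23))
  em <- quantile_normalize(log2_transform(sim$em))
  p <- de_test(em, method = "welch")$p_raw
  ref <- apply(em$values, 1, function(v)
    t.test(v[em$groups == "case"], v[em$groups == "control"])$p.value)
  expect_equal(p, unname(ref), tolerance = 1e-9)
})

test_that("null p-values are uniform (Kolmogorov-Smirnov)", {
  sim <- generate_expression(null_config(seed = 31, n_lnc = 200,
                                         n_mrna = 800))
  em <- log2_transform(sim$em)
  for (m in c("common", "welch")) {
    p <- de_test(em, method = m)$p_raw
    D <- suppressWarnings(ks.test(p, "punif")$statistic)
    expect_lt(unname(D), 0.05)
  }
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "lncnet_input_error")
})

test_that("DE filtering applies strict thresholds and keeps order", {
  res <- data.frame(
    feature_id = c("pass_up", "pass_dn", "boundary_fc", "boundary_fdr"),
    fc_signed = c(61.59, -159.90, 1.5, 4),
    fdr = c(0.01, 0.01, 0.001, 0.05))
  parts <- filter_de(res, fc_threshold = 1.5, fdr_threshold = 0.05)
  expect_equal(parts$up$feature_id, "pass_up")
  expect_equal(parts$down$feature_id, "pass_dn")
})

test_that("fdr never undercuts the raw p and the direction matches the sign", {
  sim <- generate_expression(small_config(seed = 37))
  de <- de_results(quantile_normalize(log2_transform(sim$em)))
  expect_true(all(de$fdr >= de$p_raw - 1e-15))
  expect_true(all(de$fdr <= 1 & de$p_raw >= 0))
  expect_identical(de$direction == "up", de$fc_signed >= 1)
  expect_identical(de$passes, abs(de$fc_signed) > 1.5 & de$fdr < 0.05)
})
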