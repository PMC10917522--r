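make_log2_ab <- function(m, hours = NULL, replicate = NULL) {
  meta <- tibble::tibble(
    sample_id = colnames(m), batch = 1L,
    hours = hours %||% rep(seq_len(ncol(m) / 2), each = 2),
    replicate = replicate %||% rep(1:2, ncol(m) / 2))
  abundance_tbl(dplyr::bind_cols(tibble::tibble(protein_id = rownames(m)),
                                 tibble::as_tibble(m)),
                meta, "log2-centred")
}

test_that("log2 median centring maps (2, 8, 32) to (-2, 0, 2)", {
  vals <- tibble::tibble(protein_id = c("A", "B", "C"),
                         s1 = c(2, 8, 32))
  ab <- toy_abundance(vals)
  out <- transform_log2_centre(ab)
  expect_equal(unname(ab_matrix(out)[, 1]), c(-2, 0, 2))
  expect_equal(attr(out, "centres")$median_log2, 3)
})

test_that("centring zeroes constant samples and preserves missingness", {
  vals <- tibble::tibble(protein_id = c("A", "B", "C"),
                         s1 = c(4, 4, 4), s2 = c(2, NA, 8))
  out <- transform_log2_centre(toy_abundance(vals))
  m <- ab_matrix(out)
  expect_equal(unname(m[, "s1"]), c(0, 0, 0))
  expect_true(is.na(m["B", "s2"]))
  expect_equal(median(m[, "s2"], na.rm = TRUE), 0)
  # non-positive values refuse to transform
  bad <- toy_abundance(tibble::tibble(protein_id = "A", s1 = -1))
  expect_error(transform_log2_centre(bad), "Non-positive")
})

test_that("BH adjustment reproduces the hand-worked step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_adjust(c(0.2, NA, 0.01)), c(0.2, NA, 0.02))
})

test_that("BH matches both the brute-force oracle and p.adjust", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    if (i %% 5 == 0) p <- round(p, 1)  # force ties
    got <- bh_adjust(p)
    expect_equal(got, oracle_bh(p))
    expect_equal(got, stats::p.adjust(p, "BH"))
  }
})

test_that("the vectorized t-test agrees with stats::t.test", {
  set.seed(32)
  for (ve in c(FALSE, TRUE)) {
    a <- matrix(rnorm(20 * 4), 20)
    b <- matrix(rnorm(20 * 5, mean = 0.5), 20)
    got <- brewtrack:::row_t_test(a, b, var_equal = ve)
    for (i in sample(20, 8)) {
      ref <- t.test(a[i, ], b[i, ], var.equal = ve)
      expect_equal(got$p_raw[i], ref$p.value)
      expect_equal(got$statistic[i], unname(ref$statistic))
    }
  }
})

test_that("identical groups yield zero fold change and no DEPs", {
  set.seed(33)
  m <- matrix(rnorm(30 * 4), 30,
              dimnames = list(sprintf("P%02d", 1:30), sprintf("s%d", 1:4)))
  m[, 3:4] <- m[, 1:2]
  ab <- make_log2_ab(m, hours = c(0, 0, 6, 6), replicate = c(1:2, 1:2))
  ct <- suppressMessages(test_contrast(ab, list(hours = 0), list(hours = 6)))
  expect_equal(ct$log2fc, rep(0, 30))
  expect_false(any(ct$is_dep))
})

test_that("a planted 4-fold change is called with the right direction", {
  set.seed(34)
  m <- matrix(rnorm(100 * 8, sd = 0.2), 100,
              dimnames = list(sprintf("P%03d", 1:100), sprintf("s%d", 1:8)))
  m[1:5, 5:8] <- m[1:5, 5:8] + 2
  ab <- make_log2_ab(m, hours = rep(c(0, 6), each = 4),
                     replicate = rep(1:4, 2))
  ct <- test_contrast(ab, list(hours = 6), list(hours = 0))
  top <- ct[ct$protein_id %in% sprintf("P%03d", 1:5), ]
  expect_true(all(top$is_dep))
  expect_true(all(top$direction == "up_in_a"))
  expect_lt(sum(ct$is_dep[!ct$protein_id %in% sprintf("P%03d", 1:5)]), 3)
})

test_that("swapping groups negates fold changes and keeps p-values", {
  set.seed(35)
  m <- matrix(rnorm(40 * 6), 40,
              dimnames = list(sprintf("P%02d", 1:40), sprintf("s%d", 1:6)))
  ab <- make_log2_ab(m, hours = rep(c(0, 6), each = 3),
                     replicate = rep(1:3, 2))
  ab_f <- test_contrast(ab, list(hours = 0), list(hours = 6))
  ab_r <- test_contrast(ab, list(hours = 6), list(hours = 0))
  expect_equal(ab_f$log2fc, -ab_r$log2fc)
  expect_equal(ab_f$p_raw, ab_r$p_raw)
})

test_that("proteins without two values per group are skipped with reasons", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("A", "B", "C"), sprintf("s%d", 1:4)))
  m["B", 1] <- NA
  m["C", 3:4] <- NA
  ab <- make_log2_ab(m, hours = c(0, 0, 6, 6), replicate = c(1:2, 1:2))
  ct <- suppressMessages(test_contrast(ab, list(hours = 0), list(hours = 6)))
  expect_equal(ct$protein_id, "A")
  sk <- attr(ct, "skipped")
  expect_setequal(sk$protein_id, c("B", "C"))
  expect_equal(sk$reason[sk$protein_id == "C"], "missing_in_b")
  expect_equal(glance(ct)$n_skipped, 2)
})

test_that("DEP calls survive per-sample rescaling of raw intensities", {
  sim <- tiny_sim(seed = 36, n_proteins = 80, n_replicates = 4,
                  timepoints_hours = c(0, 6), n_batches = 1,
                  temporal_sd = 0)
  iq <- quantify_intensity(sim$evidence, sim$metadata)
  ct1 <- suppressMessages(test_contrast(transform_log2_centre(iq),
                                        list(hours = 0), list(hours = 6)))
  scaled <- ab_matrix(iq)
  scaled <- sweep(scaled, 2, runif(ncol(scaled), 0.5, 2), `*`)
  ab2 <- abundance_tbl(
    dplyr::bind_cols(tibble::tibble(protein_id = rownames(scaled)),
                     tibble::as_tibble(scaled)),
    ab_metadata(iq), "intensity")
  ct2 <- suppressMessages(test_contrast(transform_log2_centre(ab2),
                                        list(hours = 0), list(hours = 6)))
  expect_equal(ct1$is_dep, ct2$is_dep)
  expect_equal(ct1$log2fc, ct2$log2fc, tolerance = 1e-10)
})

test_that("the DEP count matrix is symmetric with a zero diagonal", {
  set.seed(37)
  m <- matrix(rnorm(60 * 12, sd = 0.3), 60,
              dimnames = list(sprintf("P%03d", 1:60), sprintf("s%d", 1:12)))
  m[1:10, 9:12] <- m[1:10, 9:12] + 3
  ab <- make_log2_ab(m, hours = rep(c(0, 6, 24), each = 4),
                     replicate = rep(1:4, 3))
  dc <- dep_count_matrix(ab)
  mat <- attr(dc, "matrix")
  expect_equal(mat, t(mat))
  expect_equal(unname(diag(mat)), rep(0L, 3))
  expect_equal(nrow(dc), choose(3, 2))
  # duplicated time-point columns give a zero entry for that pair
  expect_equal(mat["b1_h0", "b1_h6"],
               sum(test_contrast(ab, list(hours = 0),
                                 list(hours = 6))$is_dep))
  expect_gt(mat["b1_h0", "b1_h24"], 0)
})
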