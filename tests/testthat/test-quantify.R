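# helper: evidence rows for hand-built cases
ev_row <- function(protein, peptide, sample, psm = 1, intensity = 0) {
  tibble::tibble(protein_id = protein, peptide_seq = peptide,
                 sample_id = sample, psm_count = psm, intensity = intensity)
}

meta1 <- tibble::tibble(sample_id = "s1", batch = 1L, hours = 0,
                        replicate = 1L)

test_that("a sole detected protein carries the full million", {
  prot <- tibble::tibble(protein_id = "A",
                         sequence = "MAAAAAAKDDDDDDDRCCCCCCCK")
  # in-range tryptic peptides: MAAAAAAK, DDDDDDDR, CCCCCCCK (8 each)
  ev <- ev_row("A", "MAAAAAAK", "s1", psm = 3)
  ppm <- quantify_ppm(ev, meta1, prot)
  expect_equal(unname(ab_matrix(ppm)["A", "s1"]), 1e6)
})

test_that("two proteins with identical signal split the million evenly", {
  prot <- tibble::tibble(
    protein_id = c("A", "B"),
    sequence = c("MAAAAAAKDDDDDDDR", "MCCCCCCKEEEEEEER"))
  ev <- dplyr::bind_rows(ev_row("A", "MAAAAAAK", "s1", psm = 2),
                         ev_row("B", "MCCCCCCK", "s1", psm = 2))
  m <- ab_matrix(quantify_ppm(ev, meta1, prot))
  expect_equal(unname(m[, "s1"]), c(5e5, 5e5), ignore_attr = TRUE)
})

test_that("ppm equals a spreadsheet-style recomputation on a toy set", {
  prot <- tibble::tibble(
    protein_id = c("A", "B", "C"),
    sequence = c("MAAAAAAKDDDDDDDRCCCCCCCK",   # 3 in-range peptides, 24 aa
                 "MGGGGGGGGGKEEEEEEER",        # 2 peptides, lengths 11+8
                 "MFFFFFFFFFFFFK"))            # 1 peptide, length 14
  ev <- dplyr::bind_rows(
    ev_row("A", "MAAAAAAK", "s1", psm = 2),
    ev_row("A", "DDDDDDDR", "s1", psm = 1),
    ev_row("B", "MGGGGGGGGGK", "s1", psm = 4),
    ev_row("C", "MFFFFFFFFFFFFK", "s1", psm = 5))
  # by hand: signal_A = (2*8 + 1*8) / 24 = 1
  #          signal_B = (4*11) / 19 (peptides MGGGGGGGGGK=11, EEEEEEER=8)
  #          signal_C = (5*14) / 14    = 5
  sig <- c(A = 1, B = 44 / 19, C = 5)
  expected <- sig * 1e6 / sum(sig)
  m <- ab_matrix(quantify_ppm(ev, meta1, prot))
  expect_equal(m[, "s1"], expected)
})

test_that("ppm sums to one million per sample and resists rescaling", {
  sim <- tiny_sim(seed = 21, n_proteins = 60)
  ppm <- quantify_ppm(sim$evidence, sim$metadata, sim$proteome)
  sums <- colSums(ab_matrix(ppm), na.rm = TRUE)
  expect_equal(unname(sums), rep(1e6, length(sums)), tolerance = 1e-9)
  # multiplying all PSM counts in a sample by a constant changes nothing
  ev2 <- sim$evidence
  s1 <- sim$metadata$sample_id[1]
  ev2$psm_count[ev2$sample_id == s1] <- ev2$psm_count[ev2$sample_id == s1] * 7L
  ppm2 <- quantify_ppm(ev2, sim$metadata, sim$proteome)
  expect_equal(ab_matrix(ppm2)[, s1], ab_matrix(ppm)[, s1])
})

test_that("proteins without in-range theoretical peptides are excluded", {
  prot <- tibble::tibble(protein_id = c("A", "B"),
                         sequence = c("MAAAAAAKDDDDDDDR", "MKAKRK"))
  ev <- dplyr::bind_rows(ev_row("A", "MAAAAAAK", "s1", psm = 1),
                         ev_row("B", "MKAKRK", "s1", psm = 1))
  expect_warning(ppm <- quantify_ppm(ev, meta1, prot, validate = FALSE),
                 "excluded")
  expect_equal(attr(ppm, "excluded_proteins"), "B")
  expect_false("B" %in% ppm$protein_id)
})

test_that("evidence integrity is checked against the proteome", {
  prot <- tibble::tibble(protein_id = "A", sequence = "MAAAAAAK")
  expect_error(quantify_ppm(ev_row("A", "CCCCCCCC", "s1"), meta1, prot),
               "not found in their protein")
  expect_error(quantify_ppm(ev_row("Z", "MAAAAAAK", "s1"), meta1, prot),
               "unknown protein")
})

test_that("iBAQ divides summed intensity by the theoretical peptide count", {
  prot <- tibble::tibble(
    protein_id = "A",
    sequence = paste0("MAAAAAAK", "DDDDDDDR", "CCCCCCCK", "EEEEEEER"))
  ev <- dplyr::bind_rows(
    ev_row("A", "MAAAAAAK", "s1", intensity = 600),
    ev_row("A", "DDDDDDDR", "s1", intensity = 400))
  ib <- quantify_ibaq(ev, meta1, prot)
  expect_equal(unname(ab_matrix(ib)["A", "s1"]), 1000 / 4)
  # linearity: doubling every intensity doubles iBAQ
  ev2 <- dplyr::mutate(ev, intensity = intensity * 2)
  ib2 <- quantify_ibaq(ev2, meta1, prot)
  expect_equal(ab_matrix(ib2), ab_matrix(ib) * 2)
  # zero intensity stays zero
  ev0 <- dplyr::mutate(ev, intensity = 0)
  expect_equal(unname(ab_matrix(quantify_ibaq(ev0, meta1, prot))["A", "s1"]),
               0)
})

test_that("median-ratio normalization recovers planted scale factors", {
  sim <- tiny_sim(seed = 22, n_proteins = 80, detection_limit = -Inf)
  iq <- quantify_intensity(sim$evidence, sim$metadata)
  nq <- normalize_intensities(iq)
  f0 <- attr(nq, "scaling")$scaling_factor
  # identical samples: build a table whose columns are all equal
  m <- ab_matrix(iq)
  same <- m
  same[] <- m[, 1]
  ab_same <- abundance_tbl(
    dplyr::bind_cols(tibble::tibble(protein_id = rownames(same)),
                     tibble::as_tibble(same)),
    ab_metadata(iq), "intensity")
  expect_equal(attr(normalize_intensities(ab_same), "scaling")$scaling_factor,
               rep(1, ncol(same)))
  # doubling one sample halves its factor (up to the pseudo-reference pull)
  dbl <- m
  dbl[, 3] <- dbl[, 3] * 2
  ab_dbl <- abundance_tbl(
    dplyr::bind_cols(tibble::tibble(protein_id = rownames(dbl)),
                     tibble::as_tibble(dbl)),
    ab_metadata(iq), "intensity")
  f <- attr(normalize_intensities(ab_dbl), "scaling")$scaling_factor
  expect_equal(f[3] / f0[3], 0.5, tolerance = 0.05)
  # invariance to protein order
  perm <- sample(nrow(m))
  ab_perm <- abundance_tbl(
    dplyr::bind_cols(tibble::tibble(protein_id = rownames(m)[perm]),
                     tibble::as_tibble(m[perm, ])),
    ab_metadata(iq), "intensity")
  expect_equal(attr(normalize_intensities(ab_perm), "scaling")$scaling_factor,
               f0)
})

test_that("replicate merging sums values and applies the detection rule", {
  vals <- tibble::tibble(protein_id = c("A", "B"),
                         s1 = c(3, 10), s2 = c(5, NA))
  meta <- tibble::tibble(sample_id = c("s1", "s2"), batch = 1L,
                         hours = c(0, 0), replicate = c(1L, 2L))
  ab <- abundance_tbl(vals, meta, "intensity")
  strict <- merge_replicates(ab, strict = TRUE)
  m <- ab_matrix(strict)
  expect_equal(unname(m["A", 1]), 8)
  # B seen in one replicate only: flagged not-detected, value withheld
  expect_true(is.na(m["B", 1]))
  expect_false(ab_detected(strict)["B", 1])
  loose <- merge_replicates(ab, strict = FALSE)
  expect_equal(unname(ab_matrix(loose)["B", 1]), 10)
  expect_true(ab_detected(loose)["B", 1])
})

test_that("unique-peptide filter matches a brute-force evidence scan", {
  sim <- tiny_sim(seed = 23, n_proteins = 60)
  ppm <- quantify_ppm(sim$evidence, sim$metadata, sim$proteome)
  filt <- filter_min_unique_peptides(ppm, 2)
  # brute force: per protein/sample count of distinct peptides from evidence
  counts <- dplyr::count(
    dplyr::distinct(sim$evidence, protein_id, sample_id, peptide_seq),
    protein_id, sample_id)
  fail_everywhere <- setdiff(
    ppm$protein_id,
    unique(counts$protein_id[counts$n >= 2]))
  expect_setequal(setdiff(ppm$protein_id, filt$protein_id), fail_everywhere)
  # spot-check cells: filtered where count < 2
  m <- ab_matrix(filt)
  sub <- counts[counts$protein_id %in% rownames(m), ]
  for (i in sample(nrow(sub), 25)) {
    cell <- m[sub$protein_id[i], sub$sample_id[i]]
    if (sub$n[i] < 2) expect_true(is.na(cell)) else expect_false(is.na(cell))
  }
  expect_error(filter_min_unique_peptides(ppm, 0), ">= 1")
  # k = 1 keeps everything that was detected
  f1 <- filter_min_unique_peptides(ppm, 1)
  expect_equal(ab_matrix(f1), ab_matrix(ppm))
})

test_that("merged ppm preserves the true abundance rank order without noise", {
  cfg <- sim_config(n_proteins = 40, n_batches = 1, n_clusters = 0,
                    prop_clustered = 0, n_replicates = 2,
                    timepoints_hours = c(0, 6),
                    complex_specs = tibble::tibble(size = integer(),
                                                   cor = double()),
                    replicate_cv = 0, temporal_sd = 0, peptide_sd = 0,
                    detection_limit = -Inf, seed = 24)
  prot <- simulate_proteome(cfg)
  sim <- simulate_evidence(cfg, prot)
  ppm <- quantify_ppm(sim$evidence, sim$metadata, prot)
  mg <- merge_replicates(ppm)
  m <- ab_matrix(mg)
  truth <- sim$truth$proteins$base_log_abundance[
    match(rownames(m), sim$truth$proteins$protein_id)]
  # ppm sorted by true abundance is non-decreasing (ties from PSM rounding;
  # epsilon absorbs float jitter between equal correction-factor ratios)
  for (j in seq_len(ncol(m))) {
    expect_true(all(diff(m[order(truth), j]) >= -1e-6))
  }
})
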