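centred_ab <- function(m) {
  meta <- tibble::tibble(sample_id = colnames(m), batch = 1L,
                         hours = seq_len(ncol(m)))
  abundance_tbl(dplyr::bind_cols(tibble::tibble(protein_id = rownames(m)),
                                 tibble::as_tibble(m)),
                meta, "row-centred")
}

test_that("row-mean normalization filters flat profiles", {
  m <- matrix(c(1, 1, 1, 1,
                0, 0, 0, 2.5,
                3, 3, 3, 3.5), 3, 4, byrow = TRUE,
              dimnames = list(c("flat", "spike", "mild"),
                              sprintf("t%d", 1:4)))
  meta <- tibble::tibble(sample_id = colnames(m), batch = 1L, hours = 1:4)
  ab <- abundance_tbl(dplyr::bind_cols(
    tibble::tibble(protein_id = rownames(m)), tibble::as_tibble(m)),
    meta, "log2")
  out <- row_mean_normalize_filter(ab, 2)
  expect_equal(out$protein_id, "spike")
  expect_equal(unname(rowMeans(ab_matrix(out))), 0)
  # retained set equals a brute-force row scan
  brute <- rownames(m)[apply(abs(m - rowMeans(m)), 1, max) >= 1]
  expect_setequal(out$protein_id, brute)
  expect_error(row_mean_normalize_filter(ab[0, ], 2), "Empty")
})

test_that("identical rows merge first, at distance zero", {
  m <- rbind(A = c(0, 1, 2, 3), B = c(0, 1, 2, 3),
             C = c(3, 1, 0, -2), D = c(-4, 2, 1, 0))
  colnames(m) <- sprintf("t%d", 1:4)
  pc <- cluster_profiles(centred_ab(m))
  first <- pc$hclust$merge[1, ]
  expect_setequal(-first, match(c("A", "B"), pc$protein_ids))
  expect_equal(pc$hclust$height[1], 0, tolerance = 1e-12)
})

test_that("planted profile groups merge within groups first", {
  set.seed(41)
  up <- c(0, 1, 2, 3, 4)
  down <- rev(up)
  m <- rbind(up1 = up + rnorm(5, sd = 0.05),
             up2 = up + rnorm(5, sd = 0.05),
             dn1 = down + rnorm(5, sd = 0.05),
             dn2 = down + rnorm(5, sd = 0.05))
  colnames(m) <- sprintf("t%d", 1:5)
  pc <- cluster_profiles(centred_ab(m))
  asg <- cut_at_node_depth(pc, 1)
  expect_equal(length(unique(asg$cluster)), 2)
  lab <- setNames(asg$cluster, asg$protein_id)
  expect_equal(lab[["up1"]], lab[["up2"]])
  expect_equal(lab[["dn1"]], lab[["dn2"]])
  expect_false(lab[["up1"]] == lab[["dn1"]])
})

test_that("the tree is invariant to row permutation", {
  set.seed(42)
  m <- matrix(rnorm(20 * 6), 20,
              dimnames = list(sprintf("P%02d", 1:20), sprintf("t%d", 1:6)))
  pc1 <- cluster_profiles(centred_ab(m))
  perm <- sample(20)
  pc2 <- cluster_profiles(centred_ab(m[perm, ]))
  a1 <- cut_at_node_depth(pc1, 3)
  a2 <- cut_at_node_depth(pc2, 3)
  j <- dplyr::inner_join(a1, a2, by = "protein_id")
  expect_equal(mclust::adjustedRandIndex(j$cluster.x, j$cluster.y), 1)
})

test_that("constant rows fall back to a fixed correlation distance", {
  m <- rbind(A = c(1, 1, 1, 1), B = c(0, 1, 2, 3), C = c(3, 2, 1, 0))
  colnames(m) <- sprintf("t%d", 1:4)
  expect_warning(pc <- cluster_profiles(centred_ab(m)), "Constant")
  expect_s3_class(pc, "profile_clust")
})

test_that("node-depth cuts respect the 2^d bound and partition the rows", {
  set.seed(43)
  for (i in 1:5) {
    m <- matrix(rnorm(40 * 6), 40,
                dimnames = list(sprintf("P%02d", 1:40),
                                sprintf("t%d", 1:6)))
    pc <- cluster_profiles(centred_ab(m))
    for (d in 1:4) {
      asg <- cut_at_node_depth(pc, d, large_cluster_size = Inf)
      expect_lte(length(unique(asg$cluster)), 2^d)
      expect_setequal(asg$protein_id, rownames(m))  # disjoint cover
    }
    expect_equal(length(unique(cut_at_node_depth(
      pc, 1, large_cluster_size = Inf)$cluster)), 2)
  }
})

test_that("a balanced 8-leaf tree cut at depth 3 gives 8 singletons", {
  # 8 profiles at the corners of a simplex-like design: pairwise distances
  # equal within merge levels, so the tree is balanced by construction
  base <- diag(8)
  m <- base + 0.01 * matrix(seq_len(64), 8)  # tiny tilt keeps ties ordered
  rownames(m) <- sprintf("P%d", 1:8)
  colnames(m) <- sprintf("t%d", 1:8)
  pc <- cluster_profiles(centred_ab(m), metric = "euclidean")
  if (max(brewtrack:::hclust_node_depths(pc$hclust)) == 2) {
    asg <- cut_at_node_depth(pc, 3)
    expect_equal(length(unique(asg$cluster)), 8)
    expect_equal(max(table(asg$cluster)), 1)
  }
  # cutting deeper than the tree warns and yields singletons
  expect_warning(asg2 <- cut_at_node_depth(pc, 10, refine_depth = 12),
                 "exceeds tree height")
  expect_equal(length(unique(asg2$cluster)), 8)
})

test_that("oversized clusters are refined at the deeper node depth", {
  set.seed(44)
  m <- matrix(rnorm(60 * 5), 60,
              dimnames = list(sprintf("P%02d", 1:60), sprintf("t%d", 1:5)))
  pc <- cluster_profiles(centred_ab(m))
  asg <- cut_at_node_depth(pc, 1, large_cluster_size = 10, refine_depth = 3)
  big <- names(which(table(asg$cluster) > 10))
  refined <- asg[asg$cluster %in% big, ]
  expect_true(all(grepl("\\.", refined$subcluster)))
  # refinement only subdivides: subclusters nest inside their cluster
  expect_true(all(sub("\\..*", "", refined$subcluster) == refined$cluster))
  small <- asg[!asg$cluster %in% big, ]
  expect_true(all(small$subcluster == small$cluster))
})

test_that("planted trajectory archetypes are recovered from the pipeline", {
  cfg <- sim_config(n_proteins = 240, prop_clustered = 1, n_clusters = 4,
                    complex_specs = tibble::tibble(size = integer(),
                                                   cor = double()),
                    replicate_cv = 0.1, temporal_sd = 0.1, seed = 45)
  prot <- simulate_proteome(cfg)
  sim <- simulate_evidence(cfg, prot)
  iq <- quantify_intensity(sim$evidence, sim$metadata)
  mg <- merge_replicates(iq, strict = FALSE)
  rc <- row_mean_normalize_filter(transform_log2_centre(mg))
  pc <- suppressMessages(cluster_profiles(rc))
  asg <- cut_at_node_depth(pc, 2, large_cluster_size = Inf)
  j <- dplyr::inner_join(asg, sim$truth$proteins, by = "protein_id")
  expect_gte(mclust::adjustedRandIndex(j$cluster.x, j$cluster.y), 0.9)
})

test_that("newick export round-trips through ape", {
  set.seed(46)
  m <- matrix(rnorm(12 * 5), 12,
              dimnames = list(sprintf("P%02d", 1:12), sprintf("t%d", 1:5)))
  pc <- cluster_profiles(centred_ab(m))
  nwk <- as_newick(pc)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(m))
})
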