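#' Simulation configuration for a brewing-style proteomics time course
#'
#' Defines the ground-truth world the synthetic generators draw from: a
#' proteome of random tryptic-digestible sequences, log-normally distributed
#' base abundances, planted temporally co-regulated clusters, protein
#' complexes whose members share a latent temporal component, log-normal
#' replicate noise, and abundance-dependent detection. The defaults mirror
#' the sampling design of a two-batch ale fermentation: 2 batches x 7 time
#' points (0 h through a post-crash 168 h) x 2 replicates.
#'
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param n_batches Number of fermentation batches sampled.
#' @param timepoints_hours Strictly increasing sampling times in hours,
#'   shared across batches.
#' @param n_replicates Independent replicates per batch/time point.
#' @param n_clusters Number of planted temporal clusters (label 0 is the
#'   flat background).
#' @param cluster_profiles Optional `n_clusters x length(timepoints_hours)`
#'   matrix of multiplicative trajectories; `NULL` uses built-in harmonic
#'   archetypes (rise, fall, mid peak, mid dip, and two oscillating shapes)
#'   spanning 4-fold.
#' @param prop_clustered Fraction of proteins assigned to planted clusters;
#'   the rest are flat background.
#' @param complex_specs Tibble with `size` and `cor` columns, one row per
#'   planted complex; `cor` is the target correlation of the members' latent
#'   temporal components. Members are drawn from background proteins so that
#'   complex co-regulation is not confounded with cluster trajectories.
#' @param base_log_mean,base_log_sd Mean and sd of per-protein base log
#'   intensity (natural-log scale).
#' @param replicate_cv Coefficient of variation of multiplicative replicate
#'   noise (0 gives identical replicates).
#' @param temporal_sd Natural-log sd of the per-batch/time biological
#'   component shared by replicates; carries the complex co-regulation.
#' @param detection_limit Peptide log intensity (natural log) at which the
#'   detection probability is 50%; detection follows a logistic curve in log
#'   abundance, so low-copy proteins drop out preferentially.
#' @param detection_scale Logistic scale of the detection curve; larger
#'   values blur the detection limit.
#' @param psm_rate PSMs per natural-log unit of intensity above `psm_floor`;
#'   a detected peptide's PSM count is this expectation rounded, floored
#'   at 1.
#' @param psm_floor Log intensity below which the expected PSM count is 0.
#' @param peptide_sd Natural-log sd of the fixed per-peptide ionization
#'   efficiency; 0 makes all peptides of a protein report identically.
#' @param seed Integer seed; all generators are fully deterministic given it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 600,
                       n_batches = 2,
                       timepoints_hours = c(0, 3, 6, 24, 48, 120, 168),
                       n_replicates = 2,
                       n_clusters = 6,
                       cluster_profiles = NULL,
                       prop_clustered = 0.5,
                       complex_specs = tibble(size = rep(5L, 12), cor = 0.7),
                       base_log_mean = 13,
                       base_log_sd = 1.8,
                       replicate_cv = 0.1,
                       temporal_sd = 0.3,
                       detection_limit = 9,
                       detection_scale = 0.8,
                       psm_rate = 1.2,
                       psm_floor = 7,
                       peptide_sd = 0.8,
                       seed = 1L) {
  counts <- c(n_proteins = n_proteins, n_batches = n_batches,
              n_replicates = n_replicates)
  if (any(counts < 1)) {
    abort(paste0("Counts must be >= 1; got ",
                 paste(names(counts)[counts < 1], collapse = ", "), "."))
  }
  if (n_clusters < 0) abort("`n_clusters` must be >= 0.")
  if (any(diff(timepoints_hours) <= 0) || any(timepoints_hours < 0)) {
    abort("`timepoints_hours` must be non-negative and strictly increasing.")
  }
  if (is.null(cluster_profiles) && n_clusters > 0) {
    cluster_profiles <- default_cluster_profiles(n_clusters,
                                                 length(timepoints_hours))
  }
  if (n_clusters > 0 &&
      !identical(dim(cluster_profiles),
                 c(as.integer(n_clusters), length(timepoints_hours)))) {
    abort("`cluster_profiles` must be n_clusters x n_timepoints.")
  }
  if (n_clusters > 0 && any(cluster_profiles <= 0)) {
    abort("`cluster_profiles` must be strictly positive multipliers.")
  }
  if (prop_clustered < 0 || prop_clustered > 1) {
    abort("`prop_clustered` must be in [0, 1].")
  }
  if (replicate_cv < 0 || temporal_sd < 0) {
    abort("Noise parameters must be >= 0.")
  }
  complex_specs <- as_tibble(complex_specs)
  if (nrow(complex_specs) > 0 &&
      (!all(c("size", "cor") %in% names(complex_specs)) ||
       any(complex_specs$size < 2) ||
       any(complex_specs$cor < 0 | complex_specs$cor > 1))) {
    abort("`complex_specs` needs size >= 2 and cor in [0, 1].")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_batches = as.integer(n_batches),
                 timepoints_hours = timepoints_hours,
                 n_replicates = as.integer(n_replicates),
                 n_clusters = as.integer(n_clusters),
                 cluster_profiles = cluster_profiles,
                 prop_clustered = prop_clustered,
                 complex_specs = complex_specs,
                 base_log_mean = base_log_mean,
                 base_log_sd = base_log_sd,
                 replicate_cv = replicate_cv,
                 temporal_sd = temporal_sd,
                 detection_limit = detection_limit,
                 detection_scale = detection_scale,
                 psm_rate = psm_rate,
                 psm_floor = psm_floor,
                 peptide_sd = peptide_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# archetype trajectories on a normalized time axis, 4-fold span (log2
# amplitude 1), mean-centred in log2 so clusters differ by shape not level
default_cluster_profiles <- function(n_clusters, n_timepoints) {
  x <- seq(0, 1, length.out = n_timepoints)
  # harmonic shapes: mutually near-orthogonal (different harmonics) or
  # anti-correlated (same harmonic, opposite sign), so profile-shape
  # clustering sees well-separated archetypes
  shapes <- list(
    function(x) -cospi(x),      # steady 4-fold rise
    function(x) cospi(x),       # steady 4-fold fall
    function(x) -cospi(2 * x),  # mid-course peak
    function(x) cospi(2 * x),   # mid-course dip
    function(x) -cospi(3 * x),  # early rise, late fall
    function(x) cospi(3 * x)    # early fall, late rise
  )
  prof <- matrix(0, n_clusters, n_timepoints)
  for (k in seq_len(n_clusters)) {
    if (k <= length(shapes)) {
      a <- shapes[[k]](x)
    } else {
      a <- cospi(x * (3 + ceiling((k - 6) / 2))) * (-1)^k
    }
    prof[k, ] <- 2^(a - mean(a))
  }
  prof
}

#' Generate a synthetic proteome
#'
#' Draws `n_proteins` random amino-acid sequences (length 100-1000) over the
#' 20 standard residues with K and R boosted to ~10% combined frequency, so
#' that tryptic digestion yields usable 7-40 residue peptides for virtually
#' every protein. Planted-cluster labels are assigned here (cluster 0 is
#' background).
#'
#' @param config A [sim_config()].
#' @return Tibble with `protein_id`, `sequence`, `length`, and ground-truth
#'   `cluster` label.
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  p <- rep(0.9 / 18, 20)
  p[aa %in% c("K", "R")] <- 0.05
  lens <- sample(100:1000, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(aa, L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  cluster <- integer(n)
  if (config$n_clusters > 0 && config$prop_clustered > 0) {
    n_cl <- round(config$prop_clustered * n)
    idx <- sample.int(n, n_cl)
    cluster[idx] <- rep_len(seq_len(config$n_clusters), n_cl)
  }
  tibble(protein_id = sprintf("P%04d", seq_len(n)),
         sequence = seqs, length = lens, cluster = cluster)
}

#' Generate peptide evidence with known ground truth
#'
#' Simulates per-sample peptide observations for a proteome: each protein's
#' log intensity is base abundance + cluster trajectory + a per-batch/time
#' biological component (shared between replicates, and partially shared
#' within planted complexes) + log-normal replicate noise; each tryptic
#' peptide carries a fixed ionization efficiency. Detection is logistic in
#' peptide log intensity, reproducing the preferential dropout of low-copy
#' proteins; a detected peptide's PSM count is proportional to its log
#' intensity above a floor, rounded and at least 1. Detection draws share a
#' quantile stream between replicates of the same batch/time point so that
#' the zero-noise limit yields identical replicates.
#'
#' @param config A [sim_config()].
#' @param proteome Output of [simulate_proteome()] under the same config.
#' @return List with `evidence` (tibble: `protein_id`, `peptide_seq`,
#'   `sample_id`, `psm_count`, `intensity`), `metadata` (tibble: `sample_id`,
#'   `batch`, `hours`, `replicate`), and `truth` (list: per-protein table,
#'   complex memberships, and the noise-free per-sample log abundances).
#' @export
simulate_evidence <- function(config, proteome) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("protein_id", "sequence", "cluster") %in% names(proteome))) {
    abort("`proteome` must come from simulate_proteome().")
  }
  set.seed(config$seed + 1L)
  n <- nrow(proteome)
  tp <- config$timepoints_hours
  nt <- length(tp)
  nb <- config$n_batches
  nr <- config$n_replicates

  metadata <- tidyr::expand_grid(batch = seq_len(nb), hours = tp,
                                 replicate = seq_len(nr))
  metadata$sample_id <- sprintf("b%d_h%g_r%d", metadata$batch,
                                metadata$hours, metadata$replicate)
  metadata <- metadata[c("sample_id", "batch", "hours", "replicate")]
  ns <- nrow(metadata)
  bt <- (metadata$batch - 1L) * nt + match(metadata$hours, tp)  # batch x time
  nbt <- nb * nt

  # per-protein base abundance and trajectory
  mu <- rnorm(n, config$base_log_mean, config$base_log_sd)
  log_traj <- matrix(0, n, nt)
  planted <- proteome$cluster > 0
  if (any(planted)) {
    log_traj[planted, ] <- log(config$cluster_profiles[proteome$cluster[planted], ,
                                                       drop = FALSE])
  }

  # complex memberships from background proteins
  specs <- config$complex_specs
  complexes <- tibble(complex_id = character(), protein_id = character(),
                      target_cor = double())
  rho <- numeric(n)
  complex_of <- integer(n)  # 0 = none
  if (nrow(specs) > 0) {
    pool <- which(proteome$cluster == 0)
    if (sum(specs$size) > length(pool)) {
      abort("Not enough background proteins for the requested complexes.")
    }
    members <- sample(pool, sum(specs$size))
    stop_at <- cumsum(specs$size)
    start_at <- c(1L, head(stop_at, -1) + 1L)
    for (g in seq_len(nrow(specs))) {
      idx <- members[start_at[g]:stop_at[g]]
      complex_of[idx] <- g
      rho[idx] <- specs$cor[g]
      complexes <- dplyr::bind_rows(complexes,
        tibble(complex_id = sprintf("CPX%02d", g),
               protein_id = proteome$protein_id[idx],
               target_cor = specs$cor[g]))
    }
  }

  # biological component per batch x time: shared-within-complex + private
  u <- matrix(rnorm(max(complex_of) * nbt), ncol = nbt)  # per complex
  v <- matrix(rnorm(n * nbt), n, nbt)                    # per protein
  w <- sqrt(1 - rho) * v
  has_cpx <- complex_of > 0
  if (any(has_cpx)) {
    w[has_cpx, ] <- w[has_cpx, ] +
      sqrt(rho[has_cpx]) * u[complex_of[has_cpx], , drop = FALSE]
  }
  w <- config$temporal_sd * w

  # protein-level log abundance per sample
  sd_rep <- sqrt(log(1 + config$replicate_cv^2))
  eps <- matrix(rnorm(n * ns, sd = sd_rep), n, ns)
  t_of <- match(metadata$hours, tp)
  L_true <- mu + log_traj[, t_of, drop = FALSE] + w[, bt, drop = FALSE]
  L <- L_true + eps
  dimnames(L_true) <- dimnames(L) <- list(proteome$protein_id,
                                          metadata$sample_id)

  # tryptic peptide space with per-peptide ionization efficiency
  pep_list <- lapply(proteome$sequence, function(s) {
    unique(digest_tryptic(s, 0L, 7L, 40L)$peptide)
  })
  peps <- tibble(protein = rep.int(seq_len(n), lengths(pep_list)),
                 peptide_seq = unlist(pep_list, use.names = FALSE))
  np <- nrow(peps)
  log_f <- rnorm(np, mean = -1, sd = config$peptide_sd)

  # shared quantile stream per peptide x batch/time (common to replicates)
  u_det <- matrix(runif(np * nbt), np, nbt)

  log_i <- L[peps$protein, , drop = FALSE] + log_f
  p_det <- stats::plogis((log_i - config$detection_limit) /
                           config$detection_scale)
  detected <- u_det[, bt, drop = FALSE] < p_det
  lambda <- config$psm_rate * pmax(log_i - config$psm_floor, 0)
  psm <- pmax(round(lambda), 1)

  hit <- which(detected, arr.ind = TRUE)
  evidence <- tibble(
    protein_id = proteome$protein_id[peps$protein[hit[, 1]]],
    peptide_seq = peps$peptide_seq[hit[, 1]],
    sample_id = metadata$sample_id[hit[, 2]],
    psm_count = as.integer(psm[hit]),
    intensity = exp(log_i[hit]))
  evidence <- dplyr::arrange(evidence, .data$sample_id, .data$protein_id,
                             .data$peptide_seq)

  truth <- list(
    proteins = tibble(protein_id = proteome$protein_id,
                      cluster = proteome$cluster,
                      complex = dplyr::if_else(
                        complex_of > 0, sprintf("CPX%02d", complex_of),
                        NA_character_),
                      base_log_abundance = mu),
    complexes = complexes,
    log_abundance = L_true)
  list(evidence = evidence, metadata = metadata, truth = truth)
}

#' Generate annotation tables aligned with the simulation ground truth
#'
#' Builds the flat annotation fixtures the downstream modules consume:
#' planted complexes (plus size-matched random decoy groups), subcellular
#' compartments as a random partition with a configurable fraction of
#' multi-localized proteins, enrichment term sets that track the planted
#' clusters plus random background terms, and the within-complex interaction
#' pair list.
#'
#' @param truth The `truth` element returned by [simulate_evidence()].
#' @param n_decoy_groups Random protein groups emitted alongside the planted
#'   complexes (same sizes, resampled members).
#' @param n_compartments Number of compartments in the random partition.
#' @param prop_multilocal Fraction of proteins annotated to a second
#'   compartment.
#' @param n_random_terms Background term sets with no planted signal.
#' @param term_coverage Fraction of each planted cluster included in its
#'   matching term set.
#' @param seed Seed for the annotation draws.
#' @return List of tibbles: `complexes`, `compartments` (both `group_id`,
#'   `protein_id`, `group_type`), `terms` (`term_id`, `protein_id`), and
#'   `interactions` (`protein_a`, `protein_b`).
#' @export
simulate_annotations <- function(truth, n_decoy_groups = 12,
                                 n_compartments = 8,
                                 prop_multilocal = 0.1,
                                 n_random_terms = 20,
                                 term_coverage = 0.8,
                                 seed = 1L) {
  set.seed(seed + 2L)
  prot <- truth$proteins
  ids <- prot$protein_id

  complexes <- dplyr::transmute(truth$complexes,
                                group_id = .data$complex_id,
                                protein_id = .data$protein_id,
                                group_type = "complex")
  decoys <- NULL
  if (n_decoy_groups > 0 && nrow(truth$complexes) > 0) {
    sizes <- rep_len(table(truth$complexes$complex_id), n_decoy_groups)
    decoys <- purrr::map_dfr(seq_len(n_decoy_groups), function(g) {
      tibble(group_id = sprintf("RND%02d", g),
             protein_id = sample(ids, sizes[g]),
             group_type = "random")
    })
  }

  comp_of <- sample.int(n_compartments, length(ids), replace = TRUE)
  compartments <- tibble(group_id = sprintf("LOC%02d", comp_of),
                         protein_id = ids, group_type = "compartment")
  n_multi <- round(prop_multilocal * length(ids))
  if (n_multi > 0) {
    extra <- sample.int(length(ids), n_multi)
    second <- (comp_of[extra] %% n_compartments) + 1L
    compartments <- dplyr::bind_rows(compartments,
      tibble(group_id = sprintf("LOC%02d", second),
             protein_id = ids[extra], group_type = "compartment"))
  }
  compartments <- dplyr::distinct(compartments)

  terms <- purrr::map_dfr(sort(unique(prot$cluster[prot$cluster > 0])),
    function(k) {
      members <- prot$protein_id[prot$cluster == k]
      keep <- sample(members, max(1, round(term_coverage * length(members))))
      extras <- sample(setdiff(ids, members),
                       max(1, round(0.1 * length(keep))))
      tibble(term_id = sprintf("TERM_cluster%02d", k),
             protein_id = c(keep, extras))
    })
  if (n_random_terms > 0) {
    rnd <- purrr::map_dfr(seq_len(n_random_terms), function(j) {
      tibble(term_id = sprintf("TERM_rand%02d", j),
             protein_id = sample(ids, sample(10:40, 1)))
    })
    terms <- dplyr::bind_rows(terms, rnd)
  }

  if (nrow(truth$complexes) > 0) {
    interactions <- truth$complexes |>
      dplyr::group_by(.data$complex_id) |>
      dplyr::reframe({
        pr <- combn(sort(.data$protein_id), 2)
        tibble(protein_a = pr[1, ], protein_b = pr[2, ])
      }) |>
      dplyr::select("protein_a", "protein_b") |>
      dplyr::distinct()
  } else {
    interactions <- tibble(protein_a = character(), protein_b = character())
  }

  list(complexes = dplyr::bind_rows(complexes, decoys),
       compartments = compartments, terms = terms,
       interactions = interactions)
}

#' Generate a synthetic pathway model
#'
#' Emits a pathway -> reaction -> protein mapping over a given protein set.
#' Optionally plants a driver scenario: a small set of shared enzymes is
#' inserted into the first `n_driven` pathways, so that when those enzymes
#' dominate the abundance dynamics, excluding them demotes exactly the
#' driven pathways from the top of the perturbation ranking.
#'
#' @param protein_ids Proteins available to populate reactions.
#' @param n_pathways Number of pathways.
#' @param reactions_range Inclusive range of reactions per pathway.
#' @param enzymes_range Inclusive range of enzymes per reaction.
#' @param driver_proteins Optional character vector of shared driver enzymes.
#' @param n_driven Number of pathways receiving a driver reaction.
#' @param seed Seed for the draws.
#' @return Tibble with `pathway_id`, `reaction_id`, `protein_id`.
#' @export
simulate_pathways <- function(protein_ids, n_pathways = 20,
                              reactions_range = c(3, 6),
                              enzymes_range = c(1, 3),
                              driver_proteins = NULL, n_driven = 5,
                              seed = 1L) {
  set.seed(seed + 3L)
  pool <- setdiff(protein_ids, driver_proteins)
  pw <- purrr::map_dfr(seq_len(n_pathways), function(i) {
    n_rxn <- sample(reactions_range[1]:reactions_range[2], 1)
    purrr::map_dfr(seq_len(n_rxn), function(j) {
      n_enz <- sample(enzymes_range[1]:enzymes_range[2], 1)
      tibble(pathway_id = sprintf("PWY%03d", i),
             reaction_id = sprintf("PWY%03d_R%02d", i, j),
             protein_id = sample(pool, n_enz))
    })
  })
  if (!is.null(driver_proteins) && n_driven > 0) {
    driven <- sprintf("PWY%03d", seq_len(min(n_driven, n_pathways)))
    extra <- purrr::map_dfr(driven, function(p) {
      tibble(pathway_id = p,
             reaction_id = paste0(p, "_Rdrv"),
             protein_id = driver_proteins)
    })
    pw <- dplyr::bind_rows(pw, extra)
  }
  dplyr::arrange(pw, .data$pathway_id, .data$reaction_id, .data$protein_id)
}
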