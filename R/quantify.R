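#' @keywords internal
#' @noRd
check_evidence <- function(evidence, metadata) {
  need <- c("protein_id", "peptide_seq", "sample_id")
  if (!all(need %in% names(evidence))) {
    abort("`evidence` needs protein_id, peptide_seq and sample_id columns.")
  }
  unknown <- setdiff(unique(evidence$sample_id), metadata$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("Evidence samples missing from metadata: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  invisible(evidence)
}

#' @keywords internal
#' @noRd
check_peptides_map <- function(evidence, proteome) {
  pairs <- dplyr::distinct(evidence, .data$protein_id, .data$peptide_seq)
  idx <- match(pairs$protein_id, proteome$protein_id)
  if (anyNA(idx)) {
    abort(paste0("Evidence references unknown protein(s): ",
                 paste(head(unique(pairs$protein_id[is.na(idx)]), 5),
                       collapse = ", ")))
  }
  hit <- stringr::str_detect(proteome$sequence[idx],
                             stringr::fixed(pairs$peptide_seq))
  if (!all(hit)) {
    abort(paste0("Peptide(s) not found in their protein sequence, e.g. ",
                 pairs$peptide_seq[which(!hit)[1]], " in ",
                 pairs$protein_id[which(!hit)[1]], "."))
  }
  invisible(evidence)
}

# unique-peptide count per protein x sample, as a matrix aligned to `wide`
peptide_count_matrix <- function(evidence, protein_ids, sample_ids) {
  counts <- evidence |>
    dplyr::distinct(.data$protein_id, .data$sample_id, .data$peptide_seq) |>
    dplyr::count(.data$protein_id, .data$sample_id)
  m <- matrix(0L, length(protein_ids), length(sample_ids),
              dimnames = list(protein_ids, sample_ids))
  m[cbind(match(counts$protein_id, protein_ids),
          match(counts$sample_id, sample_ids))] <- counts$n
  m
}

# long (protein_id, sample_id, value) -> abundance_tbl over all metadata
# samples, missing cells NA
long_to_abundance <- function(long, metadata, value_kind, n_peptides = NULL) {
  protein_ids <- sort(unique(long$protein_id))
  sample_ids <- metadata$sample_id
  m <- matrix(NA_real_, length(protein_ids), length(sample_ids),
              dimnames = list(protein_ids, sample_ids))
  m[cbind(match(long$protein_id, protein_ids),
          match(long$sample_id, sample_ids))] <- long$value
  values <- dplyr::bind_cols(tibble(protein_id = protein_ids), as_tibble(m))
  abundance_tbl(values, metadata, value_kind, n_peptides = n_peptides)
}

#' Spectral-count ppm quantification
#'
#' Converts per-sample PSM counts into parts-per-million protein abundances.
#' Each protein's theoretical tryptic peptide space (no missed cleavages,
#' 7-40 residues by default) gives a correction factor, the reciprocal of
#' the summed in-range peptide lengths. The per-sample protein signal is
#' `sum(PSM x peptide length) x correction_factor`, scaled to parts per
#' million of the sample total, so every sample's ppm values sum to 1e6.
#' Proteins with no in-range theoretical peptides cannot be normalized and
#' are excluded with a warning (their ids are kept in the
#' `excluded_proteins` attribute).
#'
#' @param evidence Tibble with `protein_id`, `peptide_seq`, `sample_id`,
#'   `psm_count`.
#' @param metadata Sample metadata (`sample_id`, `batch`, `hours`,
#'   `replicate`).
#' @param proteome Tibble with `protein_id`, `sequence`.
#' @param params A [digest_params()] describing the theoretical space.
#' @param validate Check that every evidence peptide occurs in its protein's
#'   sequence (integrity error otherwise).
#' @return An [abundance_tbl()] with `value_kind = "ppm"` and per-cell
#'   unique-peptide counts.
#' @export
quantify_ppm <- function(evidence, metadata, proteome,
                         params = digest_params(), validate = TRUE) {
  check_evidence(evidence, metadata)
  if (!"psm_count" %in% names(evidence)) {
    abort("`evidence` needs a `psm_count` column for ppm quantification.")
  }
  if (validate) check_peptides_map(evidence, proteome)

  space <- theoretical_peptide_space(
    proteome[proteome$protein_id %in% evidence$protein_id, ], params)
  excluded <- space$protein_id[space$total_length == 0]
  if (length(excluded) > 0) {
    warn(paste0(length(excluded), " protein(s) with no in-range theoretical",
                " peptides excluded from ppm quantification."))
    evidence <- evidence[!evidence$protein_id %in% excluded, ]
  }
  cf <- setNames(1 / space$total_length, space$protein_id)

  signal <- evidence |>
    dplyr::mutate(weight = .data$psm_count * nchar(.data$peptide_seq)) |>
    dplyr::group_by(.data$protein_id, .data$sample_id) |>
    dplyr::summarise(value = sum(.data$weight), .groups = "drop") |>
    dplyr::mutate(value = .data$value * cf[.data$protein_id])
  totals <- signal |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$value), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort("Sample(s) with zero total signal cannot be ppm-normalized.")
  }
  empty <- setdiff(metadata$sample_id, totals$sample_id)
  if (length(empty) > 0) {
    abort(paste0("Sample(s) with no evidence: ",
                 paste(empty, collapse = ", ")))
  }
  signal <- signal |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(value = .data$value * 1e6 / .data$total)

  npep <- peptide_count_matrix(evidence, sort(unique(signal$protein_id)),
                               metadata$sample_id)
  ab <- long_to_abundance(signal[c("protein_id", "sample_id", "value")],
                          metadata, "ppm", n_peptides = npep)
  attr(ab, "excluded_proteins") <- excluded
  attr(ab, "correction_factors") <-
    tibble(protein_id = space$protein_id,
           n_theoretical_peptides = space$n_peptides,
           correction_factor = ifelse(space$total_length > 0,
                                      1 / space$total_length, NA_real_))
  ab
}

#' iBAQ quantification
#'
#' Intensity-based absolute quantification: the summed peptide intensity of
#' a protein in a sample divided by its number of theoretical in-range
#' tryptic peptides. Uses the same digestion window as [quantify_ppm()] so
#' one parameterization covers both metrics. Proteins with zero theoretical
#' peptides are excluded with a warning.
#'
#' @inheritParams quantify_ppm
#' @return An [abundance_tbl()] with `value_kind = "ibaq"`.
#' @export
quantify_ibaq <- function(evidence, metadata, proteome,
                          params = digest_params(), validate = TRUE) {
  check_evidence(evidence, metadata)
  if (!"intensity" %in% names(evidence)) {
    abort("`evidence` needs an `intensity` column for iBAQ quantification.")
  }
  if (validate) check_peptides_map(evidence, proteome)

  space <- theoretical_peptide_space(
    proteome[proteome$protein_id %in% evidence$protein_id, ], params)
  excluded <- space$protein_id[space$n_peptides == 0]
  if (length(excluded) > 0) {
    warn(paste0(length(excluded), " protein(s) with no in-range theoretical",
                " peptides excluded from iBAQ quantification."))
    evidence <- evidence[!evidence$protein_id %in% excluded, ]
  }
  npep_theo <- setNames(space$n_peptides, space$protein_id)

  long <- evidence |>
    dplyr::group_by(.data$protein_id, .data$sample_id) |>
    dplyr::summarise(value = sum(.data$intensity), .groups = "drop") |>
    dplyr::mutate(value = .data$value / npep_theo[.data$protein_id])
  npep <- peptide_count_matrix(evidence, sort(unique(long$protein_id)),
                               metadata$sample_id)
  ab <- long_to_abundance(long, metadata, "ibaq", n_peptides = npep)
  attr(ab, "excluded_proteins") <- excluded
  ab
}

#' Summed-intensity quantification
#'
#' Sums peptide intensities per protein and sample — the raw input for
#' [normalize_intensities()]. No peptide-space correction is applied.
#'
#' @inheritParams quantify_ppm
#' @return An [abundance_tbl()] with `value_kind = "intensity"`.
#' @export
quantify_intensity <- function(evidence, metadata) {
  check_evidence(evidence, metadata)
  if (!"intensity" %in% names(evidence)) {
    abort("`evidence` needs an `intensity` column.")
  }
  long <- evidence |>
    dplyr::group_by(.data$protein_id, .data$sample_id) |>
    dplyr::summarise(value = sum(.data$intensity), .groups = "drop")
  npep <- peptide_count_matrix(evidence, sort(unique(long$protein_id)),
                               metadata$sample_id)
  long_to_abundance(long, metadata, "intensity", n_peptides = npep)
}

#' Median-ratio between-sample normalization
#'
#' Scales each sample so that its median ratio to a geometric-mean
#' pseudo-reference (built over proteins detected in every sample) is 1 —
#' the classic size-factor approach to correcting between-run intensity
#' differences. Scaling factors are returned in the `scaling` attribute.
#'
#' @param ab Raw-intensity [abundance_tbl()].
#' @return An [abundance_tbl()] with `value_kind = "normalized-intensity"`.
#' @export
normalize_intensities <- function(ab) {
  m <- ab_matrix(ab)
  complete <- rowSums(is.na(m) | m <= 0) == 0
  if (sum(complete) < 3) {
    abort("Need >= 3 proteins detected in all samples to normalize.")
  }
  ref <- exp(rowMeans(log(m[complete, , drop = FALSE])))
  ratios <- apply(m[complete, , drop = FALSE], 2,
                  function(v) median(v / ref))
  factors <- 1 / ratios
  out <- sweep(m, 2, factors, `*`)
  res <- ab_rewrap(out, ab, value_kind = "normalized-intensity")
  attr(res, "scaling") <- tibble(sample_id = colnames(m),
                                 scaling_factor = unname(factors))
  res
}

#' Merge replicates into per-time-point values
#'
#' Sums abundance across the replicates of each batch/time point, maximizing
#' the number of proteins carried forward, and records a per-protein
#' detection flag for every time point. Under the strict rule (the default,
#' and what differential expression expects) a protein counts as detected at
#' a time point only if it was observed in every replicate; cells failing
#' the rule are set missing. With `strict = FALSE` a single replicate
#' suffices and its value is carried.
#'
#' @param ab Replicate-level [abundance_tbl()] (metadata must contain
#'   `replicate`).
#' @param strict Require detection in all replicates of a time point.
#' @return An [abundance_tbl()] with one column per batch/time point, a
#'   `detected` flag matrix, and an `n_reps_detected` matrix.
#' @export
merge_replicates <- function(ab, strict = TRUE) {
  meta <- ab_metadata(ab)
  if (!"replicate" %in% names(meta)) {
    abort("Metadata must contain a `replicate` column to merge.")
  }
  m <- ab_matrix(ab)
  groups <- dplyr::distinct(meta, .data$batch, .data$hours)
  groups$sample_id <- sprintf("b%d_h%g", groups$batch, groups$hours)
  n_reps <- dplyr::count(meta, .data$batch, .data$hours)$n
  if (dplyr::n_distinct(n_reps) != 1) {
    warn("Unequal replicate counts across time points; strict rule uses each group's own count.")
  }
  merged <- matrix(NA_real_, nrow(m), nrow(groups),
                   dimnames = list(rownames(m), groups$sample_id))
  detected <- matrix(FALSE, nrow(m), nrow(groups),
                     dimnames = dimnames(merged))
  nrep_det <- matrix(0L, nrow(m), nrow(groups), dimnames = dimnames(merged))
  npep_in <- ab_n_peptides(ab)
  npep <- if (is.null(npep_in)) NULL else
    matrix(0L, nrow(m), nrow(groups), dimnames = dimnames(merged))
  for (g in seq_len(nrow(groups))) {
    cols <- meta$sample_id[meta$batch == groups$batch[g] &
                             meta$hours == groups$hours[g]]
    sub <- m[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    vals <- rowSums(sub, na.rm = TRUE)
    vals[n_obs == 0] <- NA_real_
    det <- if (strict) n_obs == length(cols) else n_obs > 0
    if (strict) vals[!det] <- NA_real_
    merged[, g] <- vals
    detected[, g] <- det
    nrep_det[, g] <- n_obs
    if (!is.null(npep)) {
      npep[, g] <- apply(npep_in[, cols, drop = FALSE], 1, max)
    }
  }
  new_meta <- groups[c("sample_id", "batch", "hours")]
  res <- abundance_tbl(
    dplyr::bind_cols(tibble(protein_id = rownames(merged)),
                     as_tibble(merged)),
    new_meta, paste0(ab_value_kind(ab), "-merged"),
    n_peptides = npep, detected = detected)
  attr(res, "n_reps_detected") <- nrep_det
  attr(res, "strict") <- strict
  res
}

#' Minimum unique-peptide detection filter
#'
#' Marks protein/sample cells backed by fewer than `k` unique peptides as
#' missing and drops proteins left undetected everywhere — the standard
#' two-peptide identification filter.
#'
#' @param ab [abundance_tbl()] carrying per-cell unique-peptide counts.
#' @param k Minimum unique peptides per cell (default 2).
#' @return Filtered [abundance_tbl()].
#' @export
filter_min_unique_peptides <- function(ab, k = 2) {
  if (k < 1) abort("`k` must be >= 1.")
  npep <- ab_n_peptides(ab)
  if (is.null(npep)) {
    abort("This abundance table carries no unique-peptide counts.")
  }
  m <- ab_matrix(ab)
  m[npep < k] <- NA_real_
  keep <- rowSums(!is.na(m)) > 0
  npep_out <- npep[keep, , drop = FALSE]
  npep_out[npep_out < k] <- 0L
  ab_rewrap(m[keep, , drop = FALSE], ab, n_peptides = npep_out)
}
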