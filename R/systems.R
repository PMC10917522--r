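#' All-by-all sample similarity matrix
#'
#' Pearson correlation between every pair of samples over the proteins
#' detected in both, the standard replicate/time-point concordance check.
#' Pairs sharing fewer than 3 proteins are flagged unreliable.
#'
#' @param ab An [abundance_tbl()]; log2-scale values are recommended.
#' @return A `sample_similarity` object: tibble with `sample_a`, `sample_b`,
#'   `r`, `n_proteins`, `reliable`; the square matrix is in the `matrix`
#'   attribute and `autoplot()` draws a heatmap.
#' @export
sample_similarity <- function(ab) {
  m <- ab_matrix(ab)
  if (ncol(m) < 2) abort("Need >= 2 samples.")
  cc <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  n_shared <- crossprod(!is.na(m))
  diag(cc) <- 1
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  res <- tibble(sample_a = colnames(m)[idx[, 1]],
                sample_b = colnames(m)[idx[, 2]],
                r = cc[idx], n_proteins = n_shared[idx],
                reliable = n_shared[idx] >= 3)
  structure(res, class = c("sample_similarity", class(tibble())),
            matrix = cc, n_matrix = n_shared, metadata = ab_metadata(ab))
}

#' Pairwise protein-profile correlations
#'
#' Pearson correlation across time points for every pair of eligible
#' proteins. A protein is eligible if detected in at least `min_timepoints`
#' time points (default 2, the detection threshold used for co-regulation
#' analyses); a pair's correlation is computed over the time points shared
#' by both proteins, and pairs sharing fewer than 3 points are flagged
#' (`ok = FALSE`) because a two-point correlation is degenerately +/-1.
#'
#' @param ab Merged (one column per time point) log2-scale
#'   [abundance_tbl()].
#' @param min_timepoints Minimum detected time points for protein
#'   eligibility.
#' @return A `pair_correlations` tibble: `protein_a` < `protein_b`, `r`,
#'   `n_shared`, `ok`. Eligible protein ids are in the `proteins` attribute.
#' @export
protein_pair_correlations <- function(ab, min_timepoints = 2) {
  if (min_timepoints < 2) abort("`min_timepoints` must be >= 2.")
  m <- ab_matrix(ab)
  eligible <- rowSums(!is.na(m)) >= min_timepoints
  m <- m[eligible, , drop = FALSE]
  if (nrow(m) < 2) abort("Fewer than 2 eligible proteins.")
  m <- m[order(rownames(m)), , drop = FALSE]
  cc <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  n_shared <- tcrossprod(!is.na(m))
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  r_v <- cc[idx]
  n_v <- n_shared[idx]
  res <- tibble(protein_a = rownames(m)[idx[, 1]],
                protein_b = rownames(m)[idx[, 2]],
                r = r_v, n_shared = n_v,
                ok = n_v >= 3 & !is.na(r_v))
  structure(res, class = c("pair_correlations", class(tibble())),
            proteins = rownames(m), min_timepoints = min_timepoints)
}

# canonical unordered pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Per-group co-regulation profiles
#'
#' For each annotated group (protein complex or subcellular compartment):
#' the fraction of members detected in the experiment and the distribution
#' of within-group pairwise profile correlations. Multi-localized proteins
#' contribute to every group they are annotated to. Flagged pairs
#' (`ok = FALSE` in the pair table) are excluded from the summaries.
#'
#' @param pairs A [protein_pair_correlations()] result.
#' @param annotations Tibble with `group_id`, `protein_id` and optionally
#'   `group_type`.
#' @return Tibble with one row per group: `group_id`, `group_type`,
#'   `n_members`, `n_detected`, `fraction_detected`, `n_pairs`, `median_r`,
#'   `mean_r`, and the member-pair correlations as a list-column `r_values`.
#' @export
group_correlation_profiles <- function(pairs, annotations) {
  stopifnot(inherits(pairs, "pair_correlations"))
  if (!all(c("group_id", "protein_id") %in% names(annotations))) {
    abort("`annotations` needs `group_id` and `protein_id` columns.")
  }
  detected <- attr(pairs, "proteins")
  ok_pairs <- pairs[pairs$ok, ]
  lookup <- setNames(ok_pairs$r, pair_key(ok_pairs$protein_a,
                                          ok_pairs$protein_b))
  annotations <- dplyr::distinct(as_tibble(annotations))
  if (!"group_type" %in% names(annotations)) {
    annotations$group_type <- NA_character_
  }
  annotations |>
    dplyr::group_by(.data$group_id, .data$group_type) |>
    dplyr::summarise(members = list(unique(.data$protein_id)),
                     .groups = "drop") |>
    dplyr::mutate(purrr::map_dfr(.data$members, function(mem) {
      det <- intersect(mem, detected)
      rv <- if (length(det) >= 2) {
        keys <- combn(sort(det), 2)
        unname(lookup[pair_key(keys[1, ], keys[2, ])])
      } else numeric(0)
      rv <- rv[!is.na(rv)]
      tibble(n_members = length(mem), n_detected = length(det),
             fraction_detected = length(det) / length(mem),
             n_pairs = length(rv),
             median_r = if (length(rv)) median(rv) else NA_real_,
             mean_r = if (length(rv)) mean(rv) else NA_real_,
             r_values = list(rv))
    })) |>
    dplyr::select(-"members")
}

#' Interacting vs non-interacting pair correlations
#'
#' Splits all evaluated protein pairs into physically interacting and
#' non-interacting classes and compares the two correlation distributions
#' with a rank-based location-shift test (Wilcoxon rank-sum). The reported
#' `shift` is the difference of class medians (interacting minus
#' non-interacting); duplicated interaction pairs are deduplicated.
#'
#' @param pairs A [protein_pair_correlations()] result.
#' @param interactions Tibble with `protein_a`, `protein_b` interaction
#'   pairs (order-insensitive).
#' @return A `pair_shift` object (list): per-class tibbles, `shift`,
#'   `statistic`, `p_value`, class sizes. `tidy()` gives a one-row summary
#'   and `autoplot()` overlaid densities.
#' @export
interacting_vs_noninteracting <- function(pairs, interactions) {
  stopifnot(inherits(pairs, "pair_correlations"))
  if (!all(c("protein_a", "protein_b") %in% names(interactions))) {
    abort("`interactions` needs `protein_a` and `protein_b` columns.")
  }
  ok_pairs <- pairs[pairs$ok, ]
  int_keys <- unique(pair_key(interactions$protein_a,
                              interactions$protein_b))
  keys <- pair_key(ok_pairs$protein_a, ok_pairs$protein_b)
  is_int <- keys %in% int_keys
  r_int <- ok_pairs$r[is_int]
  r_non <- ok_pairs$r[!is_int]
  if (length(r_int) == 0 || length(r_non) == 0) {
    warn("One class is empty; no shift test performed.")
    wt <- list(statistic = NA_real_, p.value = NA_real_)
    shift <- NA_real_
  } else {
    wt <- wilcox.test(r_int, r_non)
    shift <- median(r_int) - median(r_non)
  }
  structure(list(interacting = ok_pairs[is_int, ],
                 noninteracting = ok_pairs[!is_int, ],
                 shift = shift,
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 n_interacting = length(r_int),
                 n_noninteracting = length(r_non)),
            class = "pair_shift")
}

#' @export
print.pair_shift <- function(x, ...) {
  cat(sprintf(paste0("pair_shift: %d interacting vs %d non-interacting ",
                     "pairs\n  median shift %.3f, Wilcoxon p = %.3g\n"),
              x$n_interacting, x$n_noninteracting, x$shift, x$p_value))
  invisible(x)
}

#' @export
tidy.pair_shift <- function(x, ...) {
  tibble(shift = x$shift, statistic = x$statistic, p_value = x$p_value,
         n_interacting = x$n_interacting,
         n_noninteracting = x$n_noninteracting,
         median_interacting = median(x$interacting$r),
         median_noninteracting = median(x$noninteracting$r))
}
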