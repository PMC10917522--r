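#' Differential reaction perturbation score (DRPS)
#'
#' For one reaction, the maximal between-sample abundance swing among its
#' catalysts: for each associated entity (protein) take the range of its
#' row-mean-normalized log2 profile (max sample value minus min), then take
#' the maximum over entities — isozymes count through their most perturbed
#' member. Entities with no measurements are skipped; a reaction with no
#' measured entity scores 0 and is flagged.
#'
#' @param entity_ids Proteins catalysing the reaction.
#' @param profiles Numeric matrix of row-mean-normalized log2 abundances
#'   (proteins x samples, rownames = protein ids).
#' @return List with `drps` (log2 units), `n_entities`,
#'   `n_entities_with_data`, `has_data`.
#' @export
reaction_drps <- function(entity_ids, profiles) {
  if (length(entity_ids) == 0) abort("A reaction must have >= 1 entity.")
  present <- intersect(entity_ids, rownames(profiles))
  ranges <- vapply(present, function(p) {
    v <- profiles[p, ]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else max(v) - min(v)
  }, double(1))
  ranges <- ranges[!is.na(ranges)]
  list(drps = if (length(ranges)) max(ranges) else 0,
       n_entities = length(entity_ids),
       n_entities_with_data = length(ranges),
       has_data = length(ranges) > 0)
}

#' Differential pathway perturbation scores (DPPS)
#'
#' Scores every pathway in a pathway -> reaction -> protein model for
#' maximal between-sample perturbation: each reaction gets a DRPS (see
#' [reaction_drps()]), and the pathway score is the root mean square of its
#' reaction DRPS values, `DPPS = sqrt(sum(DRPS^2) / n_reactions)`. By
#' default the divisor counts all reactions, including those with no
#' measured entity (which contribute 0); `measured_only = TRUE` divides by
#' the measured-reaction count instead.
#'
#' @param ab Row-mean-normalized log2 [abundance_tbl()] (value_kind
#'   `"row-centred"`); other kinds trigger a warning.
#' @param pathways Tibble with `pathway_id`, `reaction_id`, `protein_id`.
#' @param measured_only Divide by reactions with data rather than all
#'   reactions.
#' @return A `pathway_scores` tibble: `pathway_id`, `dpps`, `n_reactions`,
#'   `n_reactions_with_data`; the per-reaction DRPS side table is in the
#'   `reactions` attribute.
#' @export
score_pathways <- function(ab, pathways, measured_only = FALSE) {
  if (!all(c("pathway_id", "reaction_id", "protein_id") %in%
           names(pathways))) {
    abort("`pathways` needs pathway_id, reaction_id, protein_id columns.")
  }
  if (inherits(ab, "abundance_tbl")) {
    if (!identical(ab_value_kind(ab), "row-centred")) {
      warn(paste0("Scoring on value_kind '", ab_value_kind(ab),
                  "'; row-mean-normalized log2 values are expected."))
    }
    profiles <- ab_matrix(ab)
  } else {
    profiles <- as.matrix(ab)
  }
  rxn <- pathways |>
    dplyr::group_by(.data$pathway_id, .data$reaction_id) |>
    dplyr::summarise(entities = list(unique(.data$protein_id)),
                     .groups = "drop")
  scored <- rxn |>
    dplyr::mutate(purrr::map_dfr(.data$entities, function(e) {
      s <- reaction_drps(e, profiles)
      tibble(drps = s$drps, n_entities = s$n_entities,
             n_entities_with_data = s$n_entities_with_data,
             has_data = s$has_data)
    })) |>
    dplyr::select(-"entities")
  res <- scored |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(
      n_reactions = dplyr::n(),
      n_reactions_with_data = sum(.data$has_data),
      dpps = sqrt(sum(.data$drps^2) /
                    if (measured_only) max(1L, sum(.data$has_data))
                  else dplyr::n()),
      .groups = "drop") |>
    dplyr::select("pathway_id", "dpps", "n_reactions",
                  "n_reactions_with_data")
  structure(res, class = c("pathway_scores", class(tibble())),
            reactions = scored, measured_only = measured_only)
}

#' Rank pathways by DPPS
#'
#' @param scores A [score_pathways()] result.
#' @param top_n Keep the first `top_n` rows after ranking (default all).
#' @return The scores tibble in descending DPPS order (ties broken by
#'   pathway id) with a `rank` column.
#' @export
rank_pathways <- function(scores, top_n = Inf) {
  if (nrow(scores) == 0) abort("No scored pathways to rank.")
  ranked <- dplyr::arrange(as_tibble(scores), dplyr::desc(.data$dpps),
                           .data$pathway_id)
  ranked$rank <- seq_len(nrow(ranked))
  head(ranked, top_n)
}

#' Leave-enzymes-out pathway re-ranking
#'
#' Recomputes DRPS/DPPS with a set of proteins removed from every reaction
#' and reports how each pathway's rank moves — the probe for rankings driven
#' by a few shared high-swing enzymes. Pathways whose reactions lose all
#' entities score 0 and are noted.
#'
#' @inheritParams score_pathways
#' @param exclude Non-empty character vector of proteins to drop.
#' @return Tibble with `pathway_id`, `dpps_old`, `dpps_new`, `rank_old`,
#'   `rank_new`, `rank_delta` (new minus old; positive = demoted) and
#'   `emptied` (all entities removed).
#' @export
leave_out_rerank <- function(ab, pathways, exclude, measured_only = FALSE) {
  if (length(exclude) == 0) abort("`exclude` must be non-empty.")
  old <- rank_pathways(score_pathways(ab, pathways, measured_only))
  kept <- pathways[!pathways$protein_id %in% exclude, ]
  # reactions fully emptied by the exclusion still count in the divisor
  lost_rxn <- dplyr::anti_join(
    dplyr::distinct(pathways, .data$pathway_id, .data$reaction_id),
    dplyr::distinct(kept, .data$pathway_id, .data$reaction_id),
    by = c("pathway_id", "reaction_id"))
  if (nrow(lost_rxn) > 0) {
    placeholder <- dplyr::mutate(lost_rxn, protein_id = NA_character_)
    kept <- dplyr::bind_rows(kept, placeholder)
  }
  new <- rank_pathways(score_pathways(ab, kept, measured_only))
  out <- dplyr::full_join(
    dplyr::select(old, "pathway_id", dpps_old = "dpps", rank_old = "rank"),
    dplyr::select(new, "pathway_id", dpps_new = "dpps", rank_new = "rank"),
    by = "pathway_id")
  out$rank_delta <- out$rank_new - out$rank_old
  out$emptied <- vapply(out$pathway_id, function(p) {
    all(is.na(kept$protein_id[kept$pathway_id == p]))
  }, logical(1))
  dplyr::arrange(out, .data$rank_old)
}
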