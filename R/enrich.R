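#' Hypergeometric set enrichment
#'
#' One-sided over-representation test: for each term with at least one
#' member in the query set, the upper-tail hypergeometric probability of
#' drawing that many or more term members in a sample of `length(set)` from
#' the population. P-values are BH-adjusted across the tested terms and a
#' term passes at `p_adj < alpha`. The population (enrichment universe)
#' should normally be the detected proteins of the experiment, not the whole
#' proteome, to avoid detection bias.
#'
#' @param set Character vector, the query set (must be a subset of
#'   `population`).
#' @param population Character vector, the enrichment universe.
#' @param terms Tibble mapping `term_id` to `protein_id`; memberships
#'   outside the population are ignored.
#' @param alpha Adjusted-p threshold for the `passes` flag (default 0.05).
#' @return Tibble with one row per tested term: `term_id`, `overlap`,
#'   `set_size`, `term_size`, `population_size`, `p_raw`, `p_adj`, `passes`,
#'   ordered by `p_adj`.
#' @export
enrich_hypergeom <- function(set, population, terms, alpha = 0.05) {
  set <- unique(set)
  population <- unique(population)
  if (!all(set %in% population)) {
    abort("`set` must be a subset of `population`.")
  }
  if (!all(c("term_id", "protein_id") %in% names(terms))) {
    abort("`terms` needs `term_id` and `protein_id` columns.")
  }
  terms <- dplyr::distinct(terms[terms$protein_id %in% population, ])
  n_pop <- length(population)
  n_set <- length(set)
  res <- terms |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(term_size = dplyr::n(),
                     overlap = sum(.data$protein_id %in% set),
                     .groups = "drop") |>
    dplyr::filter(.data$overlap >= 1)
  if (nrow(res) == 0) {
    return(tibble(term_id = character(), overlap = integer(),
                  set_size = integer(), term_size = integer(),
                  population_size = integer(), p_raw = double(),
                  p_adj = double(), passes = logical()))
  }
  res$p_raw <- phyper(res$overlap - 1, res$term_size,
                      n_pop - res$term_size, n_set, lower.tail = FALSE)
  res$p_adj <- bh_adjust(res$p_raw)
  res$set_size <- n_set
  res$population_size <- n_pop
  res$passes <- res$p_adj < alpha
  dplyr::arrange(res[c("term_id", "overlap", "set_size", "term_size",
                       "population_size", "p_raw", "p_adj", "passes")],
                 .data$p_adj, .data$term_id)
}

#' Enrichment across extracted clusters
#'
#' Convenience wrapper running [enrich_hypergeom()] for every cluster (or
#' subcluster) from [cut_at_node_depth()], with the union of clustered
#' proteins (or a supplied universe) as population.
#'
#' @param assignments Tibble from [cut_at_node_depth()].
#' @param terms Term membership tibble (`term_id`, `protein_id`).
#' @param population Optional universe; defaults to all assigned proteins.
#' @param level `"cluster"` or `"subcluster"`.
#' @param alpha Adjusted-p threshold.
#' @return Tibble of enrichment results with a leading `cluster` column.
#' @export
enrich_clusters <- function(assignments, terms, population = NULL,
                            level = c("cluster", "subcluster"),
                            alpha = 0.05) {
  level <- match.arg(level)
  population <- population %||% assignments$protein_id
  labs <- sort(unique(assignments[[level]]))
  purrr::map_dfr(labs, function(lab) {
    members <- assignments$protein_id[assignments[[level]] == lab]
    out <- enrich_hypergeom(intersect(members, population), population,
                            terms, alpha = alpha)
    if (nrow(out) == 0) return(NULL)
    dplyr::bind_cols(tibble(cluster = lab), out)
  })
}
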