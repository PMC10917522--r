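#' @export
autoplot.sample_similarity <- function(object, ...) {
  cc <- attr(object, "matrix")
  long <- as_tibble(as.table(cc), .name_repair = ~c("sample_a", "sample_b",
                                                    "r"))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_a, .data$sample_b,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = "Sample similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.dep_counts <- function(object, ...) {
  mat <- attr(object, "matrix")
  long <- as_tibble(as.table(mat), .name_repair = ~c("group_a", "group_b",
                                                     "n_dep"))
  ggplot2::ggplot(long, ggplot2::aes(.data$group_a, .data$group_b,
                                     fill = .data$n_dep)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_dep), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "DEPs",
                  title = "Differentially expressed proteins per contrast") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.pair_shift <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$interacting, class = "interacting"),
    dplyr::mutate(object$noninteracting, class = "non-interacting"))
  ggplot2::ggplot(df, ggplot2::aes(.data$r, colour = .data$class)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Pairwise Pearson r", y = "Density", colour = NULL,
                  title = sprintf("Median shift %.3f (Wilcoxon p = %.2g)",
                                  object$shift, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pathway_scores <- function(object, top_n = 25, ...) {
  ranked <- rank_pathways(object, top_n = top_n)
  ranked$pathway_id <- factor(ranked$pathway_id,
                              levels = rev(ranked$pathway_id))
  ggplot2::ggplot(ranked, ggplot2::aes(.data$dpps, .data$pathway_id)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "DPPS (log2 units)", y = NULL,
                  title = sprintf("Top %d perturbed pathways",
                                  nrow(ranked))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.copy_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df, ggplot2::aes(.data$mid / 1e3, .data$copy)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = attr(object, "ploidy"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (kb)", y = "Copy number estimate") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.af_track <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$genome_pos / 1e6, .data$freq,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::labs(x = "Concatenated genome position (Mb)",
                  y = "Allele frequency", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Cluster mean temporal profiles
#'
#' Line plot of per-cluster mean row-centred profiles over time, faceted by
#' batch — the quick visual check that extracted clusters carry distinct
#' temporal shapes.
#'
#' @param ab Row-centred merged [abundance_tbl()].
#' @param assignments Tibble from [cut_at_node_depth()].
#' @param level `"cluster"` or `"subcluster"`.
#' @return A ggplot object.
#' @export
plot_cluster_profiles <- function(ab, assignments,
                                  level = c("cluster", "subcluster")) {
  level <- match.arg(level)
  df <- tidy(ab) |>
    dplyr::inner_join(assignments, by = "protein_id") |>
    dplyr::group_by(.data[[level]], .data$batch, .data$hours) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$hours, .data$value,
                                   colour = .data[[level]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~batch, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (h)", y = "log2 fold change vs row mean",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}
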