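#' Protein-by-sample abundance table
#'
#' The central container of the pipeline: a wide tibble with a `protein_id`
#' column and one numeric column per sample, carrying sample metadata and a
#' `value_kind` tag that records where the values sit in the transformation
#' chain (`psm`/`ppm`/`ibaq`/`intensity` -> `normalized-intensity` ->
#' `merged` -> `log2` -> `log2-centred` -> `row-centred`). Missing values are
#' stored as `NA`, never as zero, so that log transforms and detection rules
#' stay honest.
#'
#' @param values Tibble with `protein_id` plus one numeric column per sample.
#' @param metadata Tibble with one row per sample: `sample_id`, `batch`,
#'   `hours`, and (before replicate merging) `replicate`.
#' @param value_kind Character tag describing the values (see Details).
#' @param n_peptides Optional integer matrix (proteins x samples) of unique
#'   peptide counts backing each cell.
#' @param detected Optional logical matrix (proteins x samples) of detection
#'   calls; populated by [merge_replicates()].
#'
#' @return An `abundance_tbl`, a tibble subclass. Use [tidy()] for a long
#'   view joined to the sample metadata, [glance()] for a one-row summary.
#' @export
abundance_tbl <- function(values, metadata, value_kind,
                          n_peptides = NULL, detected = NULL) {
  values <- as_tibble(values)
  metadata <- as_tibble(metadata)
  if (!"protein_id" %in% names(values)) {
    abort("`values` must have a `protein_id` column.")
  }
  if (!all(c("sample_id", "batch", "hours") %in% names(metadata))) {
    abort("`metadata` needs `sample_id`, `batch` and `hours` columns.")
  }
  sample_cols <- setdiff(names(values), "protein_id")
  missing_meta <- setdiff(sample_cols, metadata$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("Samples without metadata: ",
                 paste(missing_meta, collapse = ", ")))
  }
  metadata <- metadata[match(sample_cols, metadata$sample_id), , drop = FALSE]
  for (nm in c("n_peptides", "detected")) {
    m <- get(nm)
    if (!is.null(m) &&
        !identical(dim(m), c(nrow(values), length(sample_cols)))) {
      abort(sprintf("`%s` must be a %d x %d matrix.", nm,
                    nrow(values), length(sample_cols)))
    }
  }
  structure(values,
            metadata = metadata,
            value_kind = value_kind,
            n_peptides = n_peptides,
            detected = detected,
            class = c("abundance_tbl", class(tibble())))
}

#' @rdname abundance_tbl
#' @param x An `abundance_tbl`.
#' @export
ab_metadata <- function(x) attr(x, "metadata")

#' @rdname abundance_tbl
#' @export
ab_value_kind <- function(x) attr(x, "value_kind")

#' @rdname abundance_tbl
#' @export
ab_detected <- function(x) attr(x, "detected")

#' @rdname abundance_tbl
#' @export
ab_n_peptides <- function(x) attr(x, "n_peptides")

#' @rdname abundance_tbl
#' @export
ab_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "protein_id")])
  rownames(m) <- x$protein_id
  storage.mode(m) <- "double"
  m
}

# rebuild an abundance_tbl around a replacement matrix, keeping metadata
ab_rewrap <- function(m, template, value_kind = ab_value_kind(template),
                      n_peptides = attr(template, "n_peptides"),
                      detected = attr(template, "detected")) {
  values <- tibble(protein_id = rownames(m))
  values <- dplyr::bind_cols(values, as_tibble(m))
  meta <- ab_metadata(template)
  abundance_tbl(values, meta[match(colnames(m), meta$sample_id), ],
                value_kind, n_peptides = n_peptides, detected = detected)
}

#' @export
print.abundance_tbl <- function(x, ...) {
  n_s <- ncol(x) - 1L
  cat(sprintf("# abundance_tbl: %d proteins x %d samples [%s]\n",
              nrow(x), n_s, ab_value_kind(x)))
  NextMethod()
}

#' @export
tidy.abundance_tbl <- function(x, ...) {
  long <- tidyr::pivot_longer(as_tibble(x), -"protein_id",
                              names_to = "sample_id", values_to = "value")
  dplyr::left_join(long, ab_metadata(x), by = "sample_id")
}

#' @export
glance.abundance_tbl <- function(x, ...) {
  m <- ab_matrix(x)
  tibble(n_proteins = nrow(m),
         n_samples = ncol(m),
         value_kind = ab_value_kind(x),
         prop_missing = mean(is.na(m)),
         n_batches = dplyr::n_distinct(ab_metadata(x)$batch))
}
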