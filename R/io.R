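#' Read and write the pipeline's file formats
#'
#' Thin wrappers over Biostrings (FASTA) and readr (TSV) fixing the column
#' dialects used throughout: peptide evidence (`protein_id`, `peptide_seq`,
#' `sample_id`, `psm_count`, `intensity`), sample metadata (`sample_id`,
#' `batch`, `hours`, `replicate`), flat annotations (`group_id`,
#' `protein_id`[, `group_type`]), pathway models (`pathway_id`,
#' `reaction_id`, `protein_id`), windowed depth (`chrom`, `start`, `end`,
#' `depth`) and variants (`chrom`, `pos`, `ref`, `alt`, `coverage`,
#' `alt_count`). Abundance tables round-trip with a `#`-prefixed header
#' block recording the `value_kind` and the sample metadata.
#'
#' @param proteome Tibble with `protein_id` and `sequence`.
#' @param path File path.
#' @name brewtrack-io
NULL

#' @rdname brewtrack-io
#' @export
write_proteome_fasta <- function(proteome, path) {
  seqs <- Biostrings::AAStringSet(setNames(proteome$sequence,
                                           proteome$protein_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname brewtrack-io
#' @export
read_proteome_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  tibble(protein_id = names(seqs),
         sequence = unname(as.character(seqs)),
         length = Biostrings::width(seqs))
}

read_tsv_checked <- function(path, required, ...) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, ...)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0(path, " lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x
}

#' @rdname brewtrack-io
#' @export
read_evidence_tsv <- function(path) {
  read_tsv_checked(path, c("protein_id", "peptide_seq", "sample_id"))
}

#' @rdname brewtrack-io
#' @export
read_metadata_tsv <- function(path) {
  read_tsv_checked(path, c("sample_id", "batch", "hours"))
}

#' @rdname brewtrack-io
#' @export
read_annotation_tsv <- function(path) {
  read_tsv_checked(path, c("group_id", "protein_id"))
}

#' @rdname brewtrack-io
#' @export
read_pathways_tsv <- function(path) {
  read_tsv_checked(path, c("pathway_id", "reaction_id", "protein_id"))
}

#' @rdname brewtrack-io
#' @export
read_depth_tsv <- function(path) {
  read_tsv_checked(path, c("chrom", "start", "end", "depth"))
}

#' @rdname brewtrack-io
#' @export
read_variants_tsv <- function(path) {
  read_tsv_checked(path, c("chrom", "pos", "ref", "alt", "coverage",
                           "alt_count"))
}

#' @rdname brewtrack-io
#' @param ab An [abundance_tbl()].
#' @export
write_abundance_tsv <- function(ab, path) {
  meta <- ab_metadata(ab)
  header <- c(
    paste0("# value_kind: ", ab_value_kind(ab)),
    paste0("# sample: ", apply(meta, 1, paste, collapse = "\t")))
  writeLines(header, path)
  readr::write_tsv(as_tibble(ab), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname brewtrack-io
#' @export
read_abundance_tsv <- function(path) {
  lines <- readLines(path, n = 200)
  hdr <- lines[startsWith(lines, "#")]
  kind <- sub("^# value_kind: ", "", hdr[startsWith(hdr, "# value_kind")])
  sample_lines <- sub("^# sample: ", "", hdr[startsWith(hdr, "# sample")])
  parts <- strsplit(sample_lines, "\t", fixed = TRUE)
  meta_names <- c("sample_id", "batch", "hours", "replicate")
  meta <- purrr::map_dfr(parts, function(p) {
    as_tibble(setNames(as.list(p), meta_names[seq_along(p)]))
  })
  meta$batch <- as.integer(meta$batch)
  meta$hours <- as.numeric(meta$hours)
  if ("replicate" %in% names(meta)) {
    meta$replicate <- as.integer(meta$replicate)
  }
  values <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  abundance_tbl(values, meta, kind)
}

#' @rdname brewtrack-io
#' @param intervals Tibble with `chrom`, `start`, `end` (and extra columns,
#'   written as the BED name field when present).
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  bed <- tibble(chrom = intervals$chrom,
                start = as.integer(intervals$start),
                end = as.integer(intervals$end))
  extra <- setdiff(names(intervals), names(bed))
  if (length(extra) > 0) {
    bed$name <- do.call(paste, c(intervals[extra], sep = ";"))
  }
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
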