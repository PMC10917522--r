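#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every K or R that is not followed by P
#' (the classic trypsin rule), optionally joining up to `missed_cleavages`
#' adjacent fragments, then filters peptides to a length window. The 7-40
#' residue window used throughout the quantification module matches the
#' peptide population that survives typical search-engine filtering.
#'
#' @param sequence Single uppercase amino-acid string (20 standard residues).
#' @param missed_cleavages Maximum number of internal cleavage sites allowed
#'   inside a reported peptide (default 0).
#' @param min_length,max_length Inclusive peptide-length window in residues;
#'   `NULL` disables that bound.
#'
#' @return Tibble with columns `peptide`, `start`, `end` (1-based, inclusive)
#'   and `n_missed`, ordered by start position then end.
#' @examples
#' digest_tryptic("MKRPK")                       # "MK", "RPK"
#' digest_tryptic("MKRPK", missed_cleavages = 1) # adds "MKRPK"
#' @export
digest_tryptic <- function(sequence, missed_cleavages = 0L,
                           min_length = NULL, max_length = NULL) {
  if (length(sequence) != 1L || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty string.")
  }
  if (missed_cleavages < 0) abort("`missed_cleavages` must be >= 0.")
  if (!is.null(min_length) && !is.null(max_length) && min_length > max_length) {
    abort("`min_length` must be <= `max_length`.")
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(res), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(bad) > 0) {
    abort(paste0("Invalid residue(s): ", paste(bad, collapse = ", ")))
  }
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]          # terminal K/R ends the chain
  cut_after <- cut_after[res[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  k <- length(starts)
  p_start <- p_end <- p_miss <- integer(0)
  for (m in 0:missed_cleavages) {
    if (k - m < 1L) break
    i <- seq_len(k - m)
    p_start <- c(p_start, starts[i])
    p_end <- c(p_end, ends[i + m])
    p_miss <- c(p_miss, rep.int(m, k - m))
  }
  len <- p_end - p_start + 1L
  keep <- rep(TRUE, length(len))
  if (!is.null(min_length)) keep <- keep & len >= min_length
  if (!is.null(max_length)) keep <- keep & len <= max_length
  p_start <- p_start[keep]
  p_end <- p_end[keep]
  p_miss <- p_miss[keep]
  if (length(p_start) == 0) {
    return(tibble(peptide = character(), start = integer(),
                  end = integer(), n_missed = integer()))
  }
  o <- order(p_start, p_end)
  tibble(peptide = substring(sequence, p_start[o], p_end[o]),
         start = p_start[o], end = p_end[o], n_missed = p_miss[o])
}

#' Digestion parameters
#'
#' Bundles the protease rule and peptide filters used when building the
#' theoretical peptide space for ppm and iBAQ quantification. The defaults
#' (trypsin, 0 missed cleavages, 7-40 residues) define the peptide space
#' over which correction factors and theoretical-peptide counts are taken;
#' evidence peptides themselves may carry missed cleavages.
#'
#' @param missed_cleavages Missed cleavages for the theoretical space.
#' @param min_length,max_length Peptide length window in residues.
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(missed_cleavages = 0L, min_length = 7L,
                          max_length = 40L) {
  if (min_length > max_length) abort("`min_length` must be <= `max_length`.")
  if (missed_cleavages < 0) abort("`missed_cleavages` must be >= 0.")
  structure(list(missed_cleavages = as.integer(missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digest_params")
}

# unique theoretical in-range peptides for each proteome row; memo table
# used by ppm/iBAQ. Returns tibble(protein_id, n_peptides, total_length)
theoretical_peptide_space <- function(proteome, params = digest_params()) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteome)))
  purrr::map2_dfr(proteome$protein_id, proteome$sequence, function(id, seq) {
    pep <- unique(digest_tryptic(seq, params$missed_cleavages,
                                 params$min_length,
                                 params$max_length)$peptide)
    tibble(protein_id = id,
           n_peptides = length(pep),
           total_length = sum(nchar(pep)))
  })
}
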