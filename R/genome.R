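#' Copy-number profile from windowed read depth
#'
#' Converts per-window read depth into copy estimates:
#' `copy = ploidy x depth / genome-wide median depth`, so the profile is
#' invariant to sequencing effort. Both the continuous estimate and its
#' nearest-integer rounding are reported, plus a per-chromosome median copy.
#'
#' @param depth Tibble with `chrom`, `start`, `end` (0-based half-open
#'   windows) and `depth` (mean reads per base).
#' @param ploidy Baseline ploidy assigned to the genome-wide median depth.
#' @return A `copy_profile` tibble: input columns plus `copy` and
#'   `copy_int`; per-chromosome medians are in the `chromosomes` attribute.
#' @export
copy_number_profile <- function(depth, ploidy = 4) {
  need <- c("chrom", "start", "end", "depth")
  if (!all(need %in% names(depth))) {
    abort("`depth` needs chrom, start, end, depth columns.")
  }
  if (any(depth$depth < 0)) abort("Depths must be >= 0.")
  if (dplyr::n_distinct(depth$chrom) < 1 || nrow(depth) < 10) {
    abort("Need >= 1 chromosome with >= 10 windows.")
  }
  med <- median(depth$depth)
  if (med <= 0) abort("Zero median depth; cannot scale to copy number.")
  res <- as_tibble(depth)
  res$copy <- ploidy * res$depth / med
  res$copy_int <- as.integer(round(res$copy))
  chrom_med <- res |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(median_copy = median(.data$copy), .groups = "drop")
  structure(res, class = c("copy_profile", class(tibble())),
            chromosomes = chrom_med, ploidy = ploidy, median_depth = med)
}

#' Candidate deletion intervals
#'
#' Maximal runs of at least `min_consecutive` windows with integer copy 0,
#' reported as half-open genomic intervals — a window-level surrogate for
#' gene-deletion calling.
#'
#' @param profile A [copy_number_profile()] result.
#' @param min_consecutive Minimum run length in windows (default 3).
#' @return Tibble with `chrom`, `start`, `end`, `n_windows`.
#' @export
call_deletions <- function(profile, min_consecutive = 3) {
  stopifnot(inherits(profile, "copy_profile"))
  out <- purrr::map_dfr(split(profile, profile$chrom), function(chr) {
    chr <- dplyr::arrange(as_tibble(chr), .data$start)
    zero <- chr$copy_int == 0
    r <- rle(zero)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    keep <- r$values & r$lengths >= min_consecutive
    if (!any(keep)) return(NULL)
    tibble(chrom = chr$chrom[1],
           start = chr$start[starts[keep]],
           end = chr$end[stops[keep]],
           n_windows = r$lengths[keep])
  })
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_windows = integer()))
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Filtered allele-frequency track with concatenated positions
#'
#' Applies the standard variant filters (minimum coverage, minimum
#' alternate-allele count, minimum frequency), removes mitochondrial
#' records, computes the allele frequency, and assigns each variant a
#' whole-genome concatenated position (cumulative length of preceding
#' chromosomes, in the supplied order, plus its own position) for
#' genome-wide plotting.
#'
#' @param variants Tibble with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `coverage`, `alt_count`.
#' @param chrom_lengths Named vector of chromosome lengths defining the
#'   concatenation order; every non-mitochondrial variant chromosome must
#'   appear here.
#' @param min_coverage Minimum read coverage (default 10).
#' @param min_count Minimum alternate-allele count (default 2).
#' @param min_freq Minimum allele frequency (default 0).
#' @param mito_chroms Chromosome names treated as mitochondrial and dropped.
#' @return An `af_track` tibble: filtered variants with `freq` and
#'   `genome_pos`, ordered by concatenated position.
#' @export
allele_frequency_track <- function(variants, chrom_lengths,
                                   min_coverage = 10, min_count = 2,
                                   min_freq = 0,
                                   mito_chroms = c("chrM", "chrMT", "MT")) {
  need <- c("chrom", "pos", "coverage", "alt_count")
  if (!all(need %in% names(variants))) {
    abort("`variants` needs chrom, pos, coverage, alt_count columns.")
  }
  if (any(variants$alt_count > variants$coverage)) {
    abort("alt_count cannot exceed coverage.")
  }
  v <- as_tibble(variants)
  v <- v[!v$chrom %in% mito_chroms, ]
  unknown <- setdiff(unique(v$chrom), names(chrom_lengths))
  if (length(unknown) > 0) {
    abort(paste0("Chromosome(s) missing from `chrom_lengths`: ",
                 paste(unknown, collapse = ", ")))
  }
  v$freq <- ifelse(v$coverage > 0, v$alt_count / v$coverage, NA_real_)
  v <- v[!is.na(v$freq) & v$coverage >= min_coverage &
           v$alt_count >= min_count & v$freq >= min_freq, ]
  offsets <- c(0, cumsum(as.numeric(chrom_lengths)))[
    seq_along(chrom_lengths)]
  names(offsets) <- names(chrom_lengths)
  v$genome_pos <- unname(offsets[v$chrom]) + v$pos
  v <- dplyr::arrange(v, .data$genome_pos)
  structure(v, class = c("af_track", class(tibble())),
            chrom_lengths = chrom_lengths,
            filters = list(min_coverage = min_coverage,
                           min_count = min_count, min_freq = min_freq))
}

#' Candidate loss-of-heterozygosity segments
#'
#' Maximal runs of at least `min_run` consecutive variants whose allele
#' frequency falls outside the heterozygous band, reported per chromosome —
#' a conservative formalization of the frequency-vs-position LOH plot.
#'
#' @param track An [allele_frequency_track()] result.
#' @param het_band Allele-frequency interval regarded as heterozygous
#'   (default `c(0.1, 0.9)`).
#' @param min_run Minimum number of consecutive homozygous-like variants
#'   (default 10).
#' @return Tibble with `chrom`, `start`, `end` (positions of the first and
#'   last variant in the run, 1-based inclusive), `n_variants`,
#'   `mean_freq`.
#' @export
loh_segments <- function(track, het_band = c(0.1, 0.9), min_run = 10) {
  stopifnot(inherits(track, "af_track"))
  if (length(het_band) != 2 || het_band[1] >= het_band[2]) {
    abort("`het_band` must be an increasing interval.")
  }
  out <- purrr::map_dfr(split(track, track$chrom), function(chr) {
    chr <- dplyr::arrange(as_tibble(chr), .data$pos)
    hom <- chr$freq < het_band[1] | chr$freq > het_band[2]
    r <- rle(hom)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(NULL)
    purrr::map_dfr(which(keep), function(i) {
      span <- starts[i]:stops[i]
      tibble(chrom = chr$chrom[1],
             start = chr$pos[starts[i]], end = chr$pos[stops[i]],
             n_variants = length(span),
             mean_freq = mean(chr$freq[span]))
    })
  })
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_variants = integer(), mean_freq = numeric()))
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}
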