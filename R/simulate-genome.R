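#' Configuration for the synthetic pseudo-genome
#'
#' A toy largely-tetraploid genome: 4 nuclear chromosomes tiled into 1,000-bp
#' windows, plus a small mitochondrial contig that exercises the
#' mitochondrial-variant exclusion. Copy-number events and loss-of-
#' heterozygosity (LOH) blocks are planted as window ranges; heterozygous
#' sites elsewhere draw allele fractions from the tetraploid ladder
#' (0.25/0.5/0.75 by default).
#'
#' @param n_chrom Number of nuclear chromosomes.
#' @param windows_per_chrom Windows per chromosome.
#' @param window_size Window width in bp.
#' @param ploidy Baseline ploidy.
#' @param baseline_depth Mean read depth (reads per base) at baseline copy.
#' @param variant_spacing Average spacing between variant sites in bp.
#' @param het_fractions Allele fractions available to heterozygous sites.
#' @param cnv_events Tibble (`chrom`, `start_window`, `end_window`, `copy`)
#'   of planted copy-number events; window indices are 1-based inclusive.
#' @param loh_blocks Tibble (`chrom`, `start_window`, `end_window`) of
#'   planted LOH blocks; variant sites inside become alt-fixed (frequency 1)
#'   or drop out (ref-fixed sites are never called).
#' @param include_mito Whether to emit a `chrM` contig with variants.
#' @param seed Integer seed.
#' @return A validated list of class `genome_config`.
#' @export
genome_config <- function(n_chrom = 4, windows_per_chrom = 500,
                          window_size = 1000, ploidy = 4,
                          baseline_depth = 60, variant_spacing = 200,
                          het_fractions = c(0.25, 0.5, 0.75),
                          cnv_events = tibble(
                            chrom = c("chr2", "chr3"),
                            start_window = c(101L, 301L),
                            end_window = c(200L, 320L),
                            copy = c(5L, 0L)),
                          loh_blocks = tibble(
                            chrom = "chr4",
                            start_window = 101L, end_window = 180L),
                          include_mito = TRUE,
                          seed = 1L) {
  if (n_chrom < 1 || windows_per_chrom < 10 || window_size < 1 ||
      ploidy < 1 || baseline_depth <= 0) {
    abort("Invalid genome configuration.")
  }
  cnv_events <- as_tibble(cnv_events)
  loh_blocks <- as_tibble(loh_blocks)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  if (nrow(cnv_events) > 0 && (!all(cnv_events$chrom %in% chroms) ||
      any(cnv_events$copy < 0) ||
      any(cnv_events$start_window < 1 |
          cnv_events$end_window > windows_per_chrom |
          cnv_events$start_window > cnv_events$end_window))) {
    abort("`cnv_events` out of range for this genome.")
  }
  if (nrow(loh_blocks) > 0 && !all(loh_blocks$chrom %in% chroms)) {
    abort("`loh_blocks` reference unknown chromosomes.")
  }
  structure(list(n_chrom = as.integer(n_chrom),
                 windows_per_chrom = as.integer(windows_per_chrom),
                 window_size = as.integer(window_size),
                 ploidy = as.integer(ploidy),
                 baseline_depth = baseline_depth,
                 variant_spacing = variant_spacing,
                 het_fractions = het_fractions,
                 cnv_events = cnv_events,
                 loh_blocks = loh_blocks,
                 include_mito = include_mito,
                 seed = as.integer(seed)),
            class = "genome_config")
}

#' Generate synthetic genome tracks
#'
#' Produces the two tabular tracks the genome module consumes, with ground
#' truth: per-window read depth (Poisson around
#' `baseline_depth x copy / ploidy`) and per-variant allele counts (coverage
#' Poisson around the local depth, alt counts binomial at the true allele
#' fraction). Variant sites inside LOH blocks are alt-fixed with probability
#' 0.5 and otherwise ref-fixed and therefore never emitted, mimicking a
#' variant caller that only reports non-reference sites.
#'
#' @param config A [genome_config()].
#' @return List with `depth` (tibble: `chrom`, `start`, `end`, `depth`;
#'   0-based half-open windows), `variants` (tibble: `chrom`, `pos`, `ref`,
#'   `alt`, `coverage`, `alt_count`; 1-based positions),
#'   `chrom_lengths` (named vector over nuclear chromosomes, in order), and
#'   `truth` (list: per-window true copy, planted events, LOH blocks).
#' @export
simulate_genome <- function(config = genome_config()) {
  stopifnot(inherits(config, "genome_config"))
  set.seed(config$seed)
  ws <- config$window_size
  nw <- config$windows_per_chrom
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  chrom_lengths <- setNames(rep(nw * ws, config$n_chrom), chroms)

  windows <- tidyr::expand_grid(chrom = chroms, window = seq_len(nw))
  windows$start <- (windows$window - 1L) * ws
  windows$end <- windows$window * ws
  windows$copy <- config$ploidy
  for (i in seq_len(nrow(config$cnv_events))) {
    ev <- config$cnv_events[i, ]
    hit <- windows$chrom == ev$chrom &
      windows$window >= ev$start_window & windows$window <= ev$end_window
    windows$copy[hit] <- ev$copy
  }
  lambda <- config$baseline_depth * windows$copy / config$ploidy
  windows$depth <- rpois(nrow(windows), lambda * ws) / ws
  depth <- windows[c("chrom", "start", "end", "depth")]

  # variant sites on a jittered grid; true fraction from the het ladder,
  # overridden inside LOH blocks
  variants <- purrr::map_dfr(chroms, function(ch) {
    pos <- seq(config$variant_spacing %/% 2, chrom_lengths[ch],
               by = config$variant_spacing)
    pos <- pos + sample(-20:20, length(pos), replace = TRUE)
    pos <- pmax(1, pmin(chrom_lengths[ch], pos))
    tibble(chrom = ch, pos = as.integer(sort(pos)))
  })
  variants$true_freq <- sample(config$het_fractions, nrow(variants),
                               replace = TRUE)
  in_loh <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(config$loh_blocks))) {
    bl <- config$loh_blocks[i, ]
    hit <- variants$chrom == bl$chrom &
      variants$pos > (bl$start_window - 1L) * ws &
      variants$pos <= bl$end_window * ws
    in_loh <- in_loh | hit
  }
  if (any(in_loh)) {
    alt_fixed <- runif(sum(in_loh)) < 0.5
    variants$true_freq[in_loh] <- ifelse(alt_fixed, 1, NA)  # NA = not called
  }
  variants <- variants[!is.na(variants$true_freq), ]

  widx <- pmin(nw, variants$pos %/% ws + 1L)
  key <- paste(variants$chrom, widx)
  wkey <- paste(windows$chrom, windows$window)
  local_copy <- windows$copy[match(key, wkey)]
  cov_lambda <- config$baseline_depth * local_copy / config$ploidy
  variants$coverage <- rpois(nrow(variants), cov_lambda)
  variants$alt_count <- rbinom(nrow(variants), variants$coverage,
                               variants$true_freq)
  bases <- c("A", "C", "G", "T")
  variants$ref <- sample(bases, nrow(variants), replace = TRUE)
  variants$alt <- vapply(variants$ref,
                         function(b) sample(setdiff(bases, b), 1),
                         character(1))
  variants <- variants[variants$coverage > 0, ]

  if (config$include_mito) {
    mt_pos <- seq(500, 20000, by = 2000)
    mito <- tibble(chrom = "chrM", pos = as.integer(mt_pos),
                   true_freq = 1,
                   coverage = rpois(length(mt_pos),
                                    10 * config$baseline_depth),
                   ref = sample(bases, length(mt_pos), replace = TRUE))
    mito$alt_count <- mito$coverage
    mito$alt <- vapply(mito$ref, function(b) sample(setdiff(bases, b), 1),
                       character(1))
    variants <- dplyr::bind_rows(variants, mito)
  }
  variants <- variants[c("chrom", "pos", "ref", "alt", "coverage",
                         "alt_count", "true_freq")]

  truth <- list(copy = windows[c("chrom", "start", "end", "copy")],
                cnv_events = config$cnv_events,
                loh_blocks = config$loh_blocks)
  list(depth = depth, variants = variants,
       chrom_lengths = chrom_lengths, truth = truth)
}
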