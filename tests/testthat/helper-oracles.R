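# Independent oracles used across tests. These deliberately take different
# computational routes from the package implementations.

# tryptic digestion via regex lookaround: a peptide (s, e) is valid iff both
# boundaries are cleavage boundaries (or sequence ends) and it spans at most
# `mc` internal cleavage sites
oracle_digest <- function(sequence, mc = 0, min_l = NULL, max_l = NULL) {
  n <- nchar(sequence)
  sites <- gregexpr("(?<=[KR])(?!P)", sequence, perl = TRUE)[[1]]
  sites <- sites[sites > 0] - 1L  # cut AFTER this position
  sites <- sites[sites < n]
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  out <- list()
  for (s in starts) {
    for (e in ends[ends >= s]) {
      internal <- sum(sites >= s & sites < e)
      if (internal > mc) next
      len <- e - s + 1L
      if (!is.null(min_l) && len < min_l) next
      if (!is.null(max_l) && len > max_l) next
      out[[length(out) + 1L]] <- c(s, e)
    }
  }
  if (length(out) == 0) {
    return(data.frame(peptide = character(), start = integer(),
                      end = integer()))
  }
  m <- do.call(rbind, out)
  df <- data.frame(peptide = substring(sequence, m[, 1], m[, 2]),
                   start = m[, 1], end = m[, 2])
  df[order(df$start, df$end), ]
}

# BH step-up by the textbook double loop over the sorted p-values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# hypergeometric upper tail by explicit enumeration of the sampling space
oracle_hyper_tail <- function(overlap, term_size, pop_size, set_size) {
  ks <- overlap:min(term_size, set_size)
  sum(choose(term_size, ks) * choose(pop_size - term_size, set_size - ks)) /
    choose(pop_size, set_size)
}

# small standard simulation used by several module tests
tiny_sim <- function(seed = 42, n_proteins = 120, ...) {
  args <- list(...)
  if (!"complex_specs" %in% names(args)) {
    args$complex_specs <- tibble::tibble(size = integer(), cor = double())
  }
  cfg <- do.call(sim_config,
                 c(list(n_proteins = n_proteins, seed = seed), args))
  prot <- simulate_proteome(cfg)
  sim <- simulate_evidence(cfg, prot)
  list(cfg = cfg, proteome = prot, evidence = sim$evidence,
       metadata = sim$metadata, truth = sim$truth)
}

# hand-built abundance table (one batch, values supplied per sample)
toy_abundance <- function(values, value_kind = "intensity",
                          hours = NULL, replicate = NULL) {
  samples <- setdiff(colnames(values), "protein_id")
  meta <- tibble::tibble(
    sample_id = samples,
    batch = 1L,
    hours = hours %||% seq_along(samples),
    replicate = replicate %||% rep(1L, length(samples)))
  abundance_tbl(values, meta, value_kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
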