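#' Log2 transform and per-sample median centring
#'
#' Intensity-style abundances are log-normal, so values are log2-transformed
#' to approximate normality and each sample is centred on its median of
#' detected values to equalize variances across runs. Missing cells stay
#' missing; non-positive detected values are a transform error.
#'
#' @param ab An [abundance_tbl()] of positive (merged or replicate-level)
#'   abundances.
#' @return An [abundance_tbl()] with `value_kind = "log2-centred"` and
#'   per-sample medians stored in the `centres` attribute (log2 units).
#' @export
transform_log2_centre <- function(ab) {
  kind <- ab_value_kind(ab)
  if (grepl("log2|centred", kind)) {
    abort(paste0("Values are already on the log scale (", kind, ")."))
  }
  m <- ab_matrix(ab)
  if (any(m <= 0, na.rm = TRUE)) {
    abort("Non-positive detected values cannot be log2-transformed.")
  }
  lm2 <- log2(m)
  med <- apply(lm2, 2, median, na.rm = TRUE)
  out <- sweep(lm2, 2, med, `-`)
  res <- ab_rewrap(out, ab, value_kind = "log2-centred")
  attr(res, "centres") <- tibble(sample_id = colnames(m),
                                 median_log2 = unname(med))
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-value for the i-th smallest of m p-values is
#' `min over j >= i of p_(j) * m / j`, clipped at 1 and mapped back to the
#' input order; ties are handled stably. Controls the false discovery rate
#' under independence or positive dependence.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` passed through).
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok])
  ranked <- p[ok][o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out[ok[o]] <- pmin(1, adj)
  out
}

# vectorized two-sample t-test over matrix rows; Welch by default
row_t_test <- function(a, b, var_equal = FALSE) {
  na_ <- unname(rowSums(!is.na(a)))
  nb_ <- unname(rowSums(!is.na(b)))
  ma <- unname(rowMeans(a, na.rm = TRUE))
  mb <- unname(rowMeans(b, na.rm = TRUE))
  va <- unname(apply(a, 1, stats::var, na.rm = TRUE))
  vb <- unname(apply(b, 1, stats::var, na.rm = TRUE))
  if (var_equal) {
    sp2 <- ((na_ - 1) * va + (nb_ - 1) * vb) / (na_ + nb_ - 2)
    se <- sqrt(sp2 * (1 / na_ + 1 / nb_))
    df <- na_ + nb_ - 2
  } else {
    se <- sqrt(va / na_ + vb / nb_)
    df <- (va / na_ + vb / nb_)^2 /
      ((va / na_)^2 / (na_ - 1) + (vb / nb_)^2 / (nb_ - 1))
  }
  tstat <- (ma - mb) / se
  tibble(mean_a = ma, mean_b = mb, n_a = na_, n_b = nb_,
         statistic = tstat, df = df,
         p_raw = 2 * pt(-abs(tstat), df))
}

#' Differential expression between two sample groups
#'
#' Two-sample t-test per protein on log2-centred values, Benjamini-Hochberg
#' adjustment over the tested set, and a differentially-expressed-protein
#' (DEP) call requiring both `p_adj < fdr_level` and
#' `|log2FC| >= min_abs_log2fc`. Proteins lacking at least 2 detected
#' replicate values in either group are excluded and reported with a reason
#' code. With 2 replicates per group p-values are unstable; a warning is
#' emitted once per call.
#'
#' @param ab Replicate-level log2-centred [abundance_tbl()].
#' @param group_a,group_b Sample selections: either character vectors of
#'   sample ids or named lists matched against metadata columns, e.g.
#'   `list(batch = 1, hours = 0)`.
#' @param fdr_level BH false discovery rate (default 0.05).
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 1).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return A `dep_test` tibble: one row per tested protein with means,
#'   `log2fc` (A minus B), `p_raw`, `p_adj`, `is_dep`, `direction`. Skipped
#'   proteins are in the `skipped` attribute; [glance()] summarises counts.
#' @export
test_contrast <- function(ab, group_a, group_b, fdr_level = 0.05,
                          min_abs_log2fc = 1, var_equal = FALSE) {
  if (fdr_level <= 0 || fdr_level >= 1) abort("`fdr_level` must be in (0,1).")
  if (min_abs_log2fc < 0) abort("`min_abs_log2fc` must be >= 0.")
  if (!grepl("centred", ab_value_kind(ab))) {
    warn(paste0("Testing on value_kind '", ab_value_kind(ab),
                "'; log2-centred values are expected."))
  }
  meta <- ab_metadata(ab)
  sel <- function(g) {
    if (is.character(g)) return(intersect(meta$sample_id, g))
    keep <- rep(TRUE, nrow(meta))
    for (nm in names(g)) keep <- keep & meta[[nm]] %in% g[[nm]]
    meta$sample_id[keep]
  }
  ids_a <- sel(group_a)
  ids_b <- sel(group_b)
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    abort("Each group needs >= 2 samples.")
  }
  if (length(ids_a) == 2 && length(ids_b) == 2) {
    inform("n = 2 per group: t-test p-values are unstable at this depth.")
  }
  m <- ab_matrix(ab)
  a <- m[, ids_a, drop = FALSE]
  b <- m[, ids_b, drop = FALSE]
  ok <- rowSums(!is.na(a)) >= 2 & rowSums(!is.na(b)) >= 2
  skipped <- tibble(protein_id = rownames(m)[!ok],
                    reason = dplyr::case_when(
                      rowSums(!is.na(a))[!ok] < 2 &
                        rowSums(!is.na(b))[!ok] < 2 ~ "missing_in_both",
                      rowSums(!is.na(a))[!ok] < 2 ~ "missing_in_a",
                      TRUE ~ "missing_in_b"))
  tt <- row_t_test(a[ok, , drop = FALSE], b[ok, , drop = FALSE],
                   var_equal = var_equal)
  res <- tibble(protein_id = rownames(m)[ok],
                mean_a = tt$mean_a, mean_b = tt$mean_b,
                log2fc = tt$mean_a - tt$mean_b,
                statistic = tt$statistic, df = tt$df, p_raw = tt$p_raw)
  # zero-variance rows (identical values in both groups) are not evidence
  # of change: assign p = 1 when the difference is also 0
  degen <- !is.finite(res$p_raw)
  res$p_raw[degen & res$log2fc == 0] <- 1
  res$p_raw[degen & res$log2fc != 0] <- 0  # zero within-group variance
  res$p_adj <- bh_adjust(res$p_raw)
  res$is_dep <- !is.na(res$p_adj) & res$p_adj < fdr_level &
    abs(res$log2fc) >= min_abs_log2fc
  res$direction <- dplyr::case_when(
    !res$is_dep ~ "ns",
    res$log2fc > 0 ~ "up_in_a",
    TRUE ~ "up_in_b")
  structure(res,
            class = c("dep_test", class(tibble())),
            skipped = skipped,
            contrast = list(group_a = group_a, group_b = group_b,
                            samples_a = ids_a, samples_b = ids_b),
            fdr_level = fdr_level, min_abs_log2fc = min_abs_log2fc)
}

#' @export
tidy.dep_test <- function(x, ...) as_tibble(x)

#' @export
glance.dep_test <- function(x, ...) {
  tibble(n_tested = nrow(x),
         n_dep = sum(x$is_dep),
         n_up_in_a = sum(x$direction == "up_in_a"),
         n_up_in_b = sum(x$direction == "up_in_b"),
         n_skipped = nrow(attr(x, "skipped")),
         fdr_level = attr(x, "fdr_level"),
         min_abs_log2fc = attr(x, "min_abs_log2fc"))
}

#' All-by-all DEP count matrix
#'
#' Runs [test_contrast()] for every pair of batch/time-point groups and
#' tabulates the number of differentially expressed proteins, producing the
#' symmetric pairwise DEP-count matrix used to survey where in the time
#' course the proteome moves most.
#'
#' @inheritParams test_contrast
#' @param quiet Suppress the per-contrast n = 2 notes (default `TRUE`).
#' @return A `dep_counts` object: tibble with `group_a`, `group_b` labels
#'   (`"b<batch>_h<hours>"`), `n_dep` and `n_tested`; `autoplot()` draws the
#'   matrix. The square matrix itself is in the `matrix` attribute.
#' @export
dep_count_matrix <- function(ab, fdr_level = 0.05, min_abs_log2fc = 1,
                             var_equal = FALSE, quiet = TRUE) {
  meta <- ab_metadata(ab)
  groups <- dplyr::distinct(meta, .data$batch, .data$hours)
  if (nrow(groups) < 2) abort("Need >= 2 batch/time-point groups.")
  groups$label <- sprintf("b%d_h%g", groups$batch, groups$hours)
  pairs <- combn(nrow(groups), 2)
  run <- function(i, j) {
    test_contrast(ab,
                  list(batch = groups$batch[i], hours = groups$hours[i]),
                  list(batch = groups$batch[j], hours = groups$hours[j]),
                  fdr_level = fdr_level, min_abs_log2fc = min_abs_log2fc,
                  var_equal = var_equal)
  }
  if (quiet) {
    run_quiet <- function(i, j) withCallingHandlers(
      run(i, j), message = function(m) invokeRestart("muffleMessage"))
  } else run_quiet <- run
  res <- purrr::map2_dfr(pairs[1, ], pairs[2, ], function(i, j) {
    ct <- run_quiet(i, j)
    tibble(group_a = groups$label[i], group_b = groups$label[j],
           n_dep = sum(ct$is_dep), n_tested = nrow(ct))
  })
  mat <- matrix(0L, nrow(groups), nrow(groups),
                dimnames = list(groups$label, groups$label))
  mat[cbind(match(res$group_a, groups$label),
            match(res$group_b, groups$label))] <- res$n_dep
  mat <- mat + t(mat)
  structure(res, class = c("dep_counts", class(tibble())),
            matrix = mat, groups = groups)
}
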