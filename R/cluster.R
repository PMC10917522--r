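#' Row-mean normalization and fold-change filter
#'
#' Centres each protein's log2 profile on its own mean across time points and
#' keeps only proteins whose profile departs from that mean by at least
#' `fold_threshold`-fold (log2 units: `max |centred| >= log2(fold)`) at some
#' time point — flat housekeeping profiles carry no clustering signal.
#'
#' @param ab Log2-scale [abundance_tbl()] (merged time-point columns).
#' @param fold_threshold Minimum fold change over the row mean (default 2).
#' @return A filtered [abundance_tbl()] with `value_kind = "row-centred"`.
#' @export
row_mean_normalize_filter <- function(ab, fold_threshold = 2) {
  if (fold_threshold < 1) abort("`fold_threshold` must be >= 1.")
  m <- ab_matrix(ab)
  if (nrow(m) == 0) abort("Empty abundance matrix.")
  centred <- m - rowMeans(m, na.rm = TRUE)
  keep <- apply(abs(centred), 1, max, na.rm = TRUE) >= log2(fold_threshold)
  npep <- ab_n_peptides(ab)
  det <- ab_detected(ab)
  ab_rewrap(centred[keep, , drop = FALSE], ab, value_kind = "row-centred",
            n_peptides = if (is.null(npep)) NULL else
              npep[keep, , drop = FALSE],
            detected = if (is.null(det)) NULL else det[keep, , drop = FALSE])
}

#' Average-linkage hierarchical clustering of temporal profiles
#'
#' Clusters protein rows with agglomerative average linkage. The default
#' distance is 1 - Pearson correlation across time points, which groups
#' proteins by profile shape regardless of amplitude; Euclidean distance is
#' available for amplitude-sensitive clustering. Residual missing cells are
#' imputed with the row mean (0 on row-centred data) and reported. Rows are
#' ordered by protein id before clustering so ties break deterministically.
#'
#' @param ab Row-centred (or log2) [abundance_tbl()] with >= 2 proteins.
#' @param metric `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage Agglomeration method, default `"average"`.
#' @return A `profile_clust` object wrapping the merge tree, with
#'   [cut_at_node_depth()] for cluster extraction and [as_newick()] for
#'   export.
#' @export
cluster_profiles <- function(ab, metric = c("pearson", "euclidean"),
                             linkage = "average") {
  metric <- match.arg(metric)
  m <- ab_matrix(ab)
  if (nrow(m) < 2) abort("Need >= 2 proteins to cluster.")
  m <- m[order(rownames(m)), , drop = FALSE]
  n_imputed <- sum(is.na(m))
  if (n_imputed > 0) {
    inform(paste0("Imputing ", n_imputed, " missing cell(s) with row means."))
    rm_ <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- rm_[idx[, 1]]
  }
  if (metric == "pearson") {
    cc <- suppressWarnings(cor(t(m)))
    if (anyNA(cc)) {
      warn("Constant profile(s): correlation undefined; distance 1 (uncorrelated) used for those pairs.")
      cc[is.na(cc)] <- 0
    }
    d <- as.dist(1 - cc)
  } else {
    d <- stats::dist(m)
  }
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, protein_ids = rownames(m),
                 metric = metric, linkage = linkage,
                 n_imputed = n_imputed),
            class = "profile_clust")
}

#' @export
print.profile_clust <- function(x, ...) {
  cat(sprintf("profile_clust: %d proteins, %s linkage, %s distance\n",
              length(x$protein_ids), x$linkage, x$metric))
  invisible(x)
}

# per-node depth from the root (root merge = depth 0) for an hclust tree;
# returns list(node_depth[merge index], leaf sets per node)
hclust_node_depths <- function(hc) {
  n_merge <- nrow(hc$merge)
  depth <- integer(n_merge)
  parent_first <- order(-seq_len(n_merge))  # root is the last merge
  depth[n_merge] <- 0L
  for (i in rev(seq_len(n_merge))) {
    for (child in hc$merge[i, ]) {
      if (child > 0) depth[child] <- depth[i] + 1L
    }
  }
  depth
}

# leaves under a merge node
hclust_leaves <- function(hc, node) {
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    cur <- stack[[1]]
    stack <- stack[-1]
    if (cur < 0) out <- c(out, -cur)
    else stack <- c(hc$merge[cur, ], stack)
  }
  out
}

#' Extract clusters at a node depth
#'
#' Walks the merge tree from the root and emits one cluster per node at the
#' requested depth (leaves reached earlier become singleton clusters), so a
#' cut at depth `d` yields at most `2^d` clusters. Clusters exceeding
#' `large_cluster_size` are refined by re-cutting their subtree at
#' `refine_depth`, mirroring the two-stage depth-3-then-5 extraction used
#' for large expression-profile trees.
#'
#' @param pc A [cluster_profiles()] result.
#' @param depth Cut depth from the root (root = depth 0); must be >= 1.
#' @param large_cluster_size Clusters larger than this are re-cut
#'   (default 500); `Inf` disables refinement.
#' @param refine_depth Depth for the refinement cut (must exceed `depth`).
#' @return Tibble with `protein_id`, `cluster` (depth-`depth` label, in tree
#'   traversal order), and `subcluster` (refined label, equal to `cluster`
#'   where no refinement happened).
#' @export
cut_at_node_depth <- function(pc, depth = 3, large_cluster_size = 500,
                              refine_depth = 5) {
  stopifnot(inherits(pc, "profile_clust"))
  if (depth < 1) abort("`depth` must be >= 1.")
  if (refine_depth <= depth) abort("`refine_depth` must exceed `depth`.")
  hc <- pc$hclust
  n <- length(pc$protein_ids)

  cut_tree <- function(node, node_depth, target) {
    # returns list of leaf-index vectors for the subtree cut at `target`
    if (node < 0) return(list(-node))
    if (node_depth >= target) return(list(hclust_leaves(hc, node)))
    c(cut_tree(hc$merge[node, 1], node_depth + 1L, target),
      cut_tree(hc$merge[node, 2], node_depth + 1L, target))
  }
  root <- nrow(hc$merge)
  height <- max(hclust_node_depths(hc)) + 1L
  if (depth > height) {
    warn(paste0("Cut depth ", depth, " exceeds tree height ", height,
                "; returning singleton leaves."))
  }
  clusters <- cut_tree(root, 0L, depth)
  labels <- character(n)
  sub_labels <- character(n)
  for (k in seq_along(clusters)) {
    leaves <- clusters[[k]]
    lab <- sprintf("c%d", k)
    labels[leaves] <- lab
    if (length(leaves) > large_cluster_size) {
      # re-cut this subtree at the absolute refine depth
      subtrees <- cut_tree(root, 0L, refine_depth)
      members <- lapply(subtrees, intersect, leaves)
      members <- members[lengths(members) > 0]
      for (j in seq_along(members)) {
        sub_labels[members[[j]]] <- sprintf("%s.%d", lab, j)
      }
    } else {
      sub_labels[leaves] <- lab
    }
  }
  tibble(protein_id = pc$protein_ids, cluster = labels,
         subcluster = sub_labels)
}

#' @export
tidy.profile_clust <- function(x, depth = 3, large_cluster_size = 500,
                               refine_depth = 5, ...) {
  cut_at_node_depth(x, depth, large_cluster_size, refine_depth)
}

#' @export
glance.profile_clust <- function(x, ...) {
  tibble(n_proteins = length(x$protein_ids), metric = x$metric,
         linkage = x$linkage, n_imputed = x$n_imputed,
         tree_height = max(hclust_node_depths(x$hclust)) + 1L)
}

#' Export a cluster tree in Newick format
#'
#' @param pc A [cluster_profiles()] result.
#' @return A single Newick string (branch lengths from merge heights).
#' @export
as_newick <- function(pc) {
  stopifnot(inherits(pc, "profile_clust"))
  hc <- pc$hclust
  build <- function(node, parent_height) {
    if (node < 0) {
      sprintf("%s:%g", pc$protein_ids[-node], parent_height)
    } else {
      h <- hc$height[node]
      sprintf("(%s,%s):%g",
              build(hc$merge[node, 1], h),
              build(hc$merge[node, 2], h),
              parent_height - h)
    }
  }
  root <- nrow(hc$merge)
  paste0("(", build(hc$merge[root, 1], hc$height[root]), ",",
         build(hc$merge[root, 2], hc$height[root]), ");")
}
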