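#' Ward biclustering of an intra-pair difference matrix
#'
#' Hierarchical clustering of probes and donors simultaneously (each axis
#' clustered independently) on the Delta-Beta matrix of called probes, using
#' Euclidean distance and Ward linkage (`ward.D2`, i.e. Ward's criterion on
#' squared Euclidean distances). The donor dendrogram cut at two clusters
#' gives the low-grade / high-grade grouping readout. The agglomeration is
#' deterministic given input order; equal-height merges resolve to the
#' lowest-index pair.
#'
#' @param delta Delta tibble from [intra_pair_delta()] (typically restricted
#'   to called probes), or a numeric matrix probes x donors.
#' @return Object of class `ward_bicluster` with elements `row_hclust`,
#'   `col_hclust`, `row_order`, `col_order`, `col_cut2` (named 2-cluster
#'   labels for the donors) and the clustered `matrix`.
#' @export
ward_bicluster <- function(delta) {
  m <- if (is.matrix(delta)) delta else .delta_matrix(delta)
  if (nrow(m) < 2 || ncol(m) < 2)
    abort("Biclustering needs at least 2 probes and 2 donors.")
  if (anyNA(m)) abort("Delta matrix contains missing values.")
  hr <- stats::hclust(stats::dist(m), method = "ward.D2")
  hc <- stats::hclust(stats::dist(t(m)), method = "ward.D2")
  structure(list(
    row_hclust = hr,
    col_hclust = hc,
    row_order = rownames(m)[hr$order],
    col_order = colnames(m)[hc$order],
    col_cut2 = stats::cutree(hc, k = 2),
    matrix = m
  ), class = "ward_bicluster")
}

#' @export
print.ward_bicluster <- function(x, ...) {
  cat(sprintf("Ward bicluster: %d probes x %d donors\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("2-cluster donor split:\n")
  print(split(names(x$col_cut2), x$col_cut2))
  invisible(x)
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two partitions agree (grouped together in
#' both, or separated in both).
#'
#' @param a,b Vectors of cluster labels over the same items.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("Partitions must cover the same items.")
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

#' Write bicluster leaf orderings and donor cut labels
#' @param bc A `ward_bicluster` object.
#' @param out_dir Output directory.
#' @return Invisible named vector of written paths.
#' @export
write_bicluster <- function(bc, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- file.path(out_dir, "probe_leaf_order.tsv")
  cols <- file.path(out_dir, "donor_clusters.tsv")
  readr::write_tsv(tibble(probe_id = bc$row_order), rows)
  readr::write_tsv(
    tibble(donor_id = bc$col_order,
           cluster2 = unname(bc$col_cut2[bc$col_order])), cols)
  invisible(c(probes = rows, donors = cols))
}
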