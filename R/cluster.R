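# Subgroup discovery: Ward clustering of the posterior matrix and the
# fusion-level cut.

#' Ward clustering of samples on Bayes posteriors
#'
#' Samples are clustered as vectors over genes with Euclidean distance and
#' Ward minimum-variance linkage (the classical Ward criterion on squared
#' Euclidean distances, `stats::hclust(method = "ward.D2")`). Because the
#' posteriors already live in [0, 1], no further normalization is applied.
#'
#' @param p Posterior matrix, genes in rows, samples in columns.
#' @param sample_ids Optional subset of samples to cluster (e.g., leukemia
#'   samples only, excluding normals).
#' @return An [stats::hclust] dendrogram; `$merge`, `$height` and `$labels`
#'   give the merge table.
#' @export
ward_cluster <- function(p, sample_ids = NULL) {
  if (is.null(colnames(p))) stop("posterior matrix needs sample column names")
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, colnames(p))
    if (length(missing) > 0L) {
      stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    }
    p <- p[, sample_ids, drop = FALSE]
  }
  if (ncol(p) < 4L) stop("need at least 4 samples to cluster")
  stats::hclust(stats::dist(t(p)), method = "ward.D2")
}

#' Cut a dendrogram at the largest change in fusion level
#'
#' Chooses `K` as the number of clusters maximizing the gap between
#' successive top fusion heights: `gap(k) = h[n-k+1] - h[n-k]` for
#' `k = 2..k_max`. Ties resolve to the smaller `K`.
#'
#' @param hc An [stats::hclust] object.
#' @param k_max Largest cluster count considered (>= 2).
#' @return A list of class `subgroup_partition` with `K`, `labels` (named
#'   integer cluster per sample) and the inspected `gaps` table.
#' @export
choose_cut <- function(hc, k_max = 10) {
  stopifnot(inherits(hc, "hclust"))
  if (k_max < 2) stop("k_max must be at least 2")
  n <- length(hc$height) + 1L
  ks <- 2:min(k_max, n - 1L)
  h <- hc$height
  if (diff(range(h)) < .Machine$double.eps^0.5) {
    warning("all fusion heights equal; returning K = 2")
    K <- 2L
  } else {
    gaps <- h[n - ks + 1L] - h[n - ks]
    K <- ks[which.max(gaps)]
  }
  labels <- stats::cutree(hc, K)
  gaps_df <- data.frame(k = ks, gap = h[n - ks + 1L] - h[n - ks])
  structure(list(K = as.integer(K), labels = labels, gaps = gaps_df),
            class = "subgroup_partition")
}

#' @export
print.subgroup_partition <- function(x, ...) {
  cat(sprintf("subgroup partition: K = %d (%s)\n", x$K,
              paste(sprintf("G%d: %d", seq_len(x$K), tabulate(x$labels, x$K)),
                    collapse = ", ")))
  invisible(x)
}

#' Contingency table of clusters against known class labels
#'
#' @param partition A `subgroup_partition` (or a named cluster vector).
#' @param annotations Data frame with `sample_id` and `label`; samples
#'   without an annotation are counted under `"NA"`.
#' @return A clusters-by-labels count table; rows are clusters `G1..GK`.
#' @export
cluster_contingency <- function(partition, annotations) {
  labels <- if (inherits(partition, "subgroup_partition")) {
    partition$labels
  } else {
    partition
  }
  if (is.null(names(labels))) stop("partition must name its samples")
  ann <- annotations$label[match(names(labels), annotations$sample_id)]
  ann[is.na(ann)] <- "NA"
  table(cluster = paste0("G", labels), label = ann)
}
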