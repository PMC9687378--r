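# Per-gene differential-expression statistics for subgroup dichotomies:
# the difference of group-average Bayes posteriors (pdeg) and Cohen's D.

#' Define a dichotomy of two sample groups
#'
#' @param group_a,group_b Group labels; the sign convention is positive =
#'   higher in `group_a`.
#' @param samples_a,samples_b Sample identifiers of each group; disjoint,
#'   each with at least 2 members.
#' @return A list of class `dichotomy`.
#' @export
make_dichotomy <- function(group_a, group_b, samples_a, samples_b) {
  if (length(samples_a) < 2L || length(samples_b) < 2L) {
    stop("each group needs at least 2 samples")
  }
  if (length(intersect(samples_a, samples_b)) > 0L) {
    stop("dichotomy groups must be disjoint")
  }
  structure(list(group_a = group_a, group_b = group_b,
                 samples_a = as.character(samples_a),
                 samples_b = as.character(samples_b)),
            class = "dichotomy")
}

#' Group-average Bayes posterior of one gene
#'
#' @param p Posterior matrix, genes in rows.
#' @param gene Gene identifier or row index.
#' @param sample_ids Samples to average over.
#' @return Arithmetic mean posterior, in [0, 1].
#' @export
group_mean_posterior <- function(p, gene, sample_ids) {
  if (length(sample_ids) == 0L) stop("empty sample group")
  missing <- setdiff(sample_ids, colnames(p))
  if (length(missing) > 0L) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  }
  mean(p[gene, sample_ids])
}

#' Posterior-difference statistic pdeg
#'
#' For every gene, the difference of group-average posteriors
#' `mean_a - mean_b`. Values lie in [-1, 1]: +1 is definitive overexpression
#' in `group_a` relative to `group_b`, -1 definitive underexpression, and the
#' statistic is antisymmetric under swapping the groups.
#'
#' @param p Posterior matrix, genes in rows.
#' @param d A `dichotomy`.
#' @return Named numeric vector over genes.
#' @export
pdeg <- function(p, d) {
  stopifnot(inherits(d, "dichotomy"))
  for (s in c(d$samples_a, d$samples_b)) {
    if (!s %in% colnames(p)) stop("unknown sample id: ", s)
  }
  rowMeans(p[, d$samples_a, drop = FALSE]) -
    rowMeans(p[, d$samples_b, drop = FALSE])
}

#' Cohen's D with pooled standard deviation
#'
#' `(mean_a - mean_b) / s_pooled` with the classical (n-1)-weighted pooled
#' standard deviation, accommodating unequal variances and group sizes.
#' Degenerate zero-variance groups yield 0 when the means agree and a capped
#' `±d_max` sentinel (with a warning) when they differ.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param d_max Cap for the zero-variance sentinel.
#' @return Signed effect size.
#' @export
cohens_d <- function(values_a, values_b, d_max = 10) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  delta <- mean(values_a) - mean(values_b)
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) /
    (na + nb - 2)
  if (sp2 <= 0) {
    if (delta == 0) return(0)
    warning("zero pooled variance with differing means; capping at d_max")
    return(sign(delta) * d_max)
  }
  delta / sqrt(sp2)
}

# row-wise Cohen's D for a posterior matrix
.cohens_d_rows <- function(p, samples_a, samples_b, d_max = 10) {
  a <- p[, samples_a, drop = FALSE]
  b <- p[, samples_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  va <- apply(a, 1L, stats::var)
  vb <- apply(b, 1L, stats::var)
  delta <- rowMeans(a) - rowMeans(b)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  d <- ifelse(sp > 0, delta / sp,
              ifelse(delta == 0, 0, sign(delta) * d_max))
  if (any(sp == 0 & delta != 0)) {
    warning("zero pooled variance with differing means; capping at d_max")
  }
  d
}

#' Differential-expression tables for a set of dichotomies
#'
#' For every requested pair of groups, computes per-gene `pdeg` and Cohen's D
#' (both on the posterior scale), together with the group means and sizes.
#' Pairs whose groups have fewer than 2 samples are skipped with a warning.
#'
#' @param p Posterior matrix, genes in rows.
#' @param groups Named list mapping group label to sample identifiers.
#' @param pairs List of 2-element character vectors `(group_a, group_b)`.
#' @param d_max Zero-variance cap passed to the Cohen's D computation.
#' @param d_matrix Optional matrix (same dimnames as `p`) on which Cohen's D
#'   is computed instead of the posteriors — e.g. the log-expression matrix,
#'   for a sensitivity analysis of the effect-size substrate. `pdeg` always
#'   uses the posteriors.
#' @return Named list (`"A_vs_B"`) of data frames with columns `gene`,
#'   `pdeg`, `cohen_d`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
dichotomy_table <- function(p, groups, pairs, d_max = 10, d_matrix = NULL) {
  if (!is.null(d_matrix) && !identical(dimnames(d_matrix), dimnames(p))) {
    stop("d_matrix must share the dimnames of the posterior matrix")
  }
  dm <- if (is.null(d_matrix)) p else d_matrix
  out <- list()
  for (pr in pairs) {
    a <- pr[1L]; b <- pr[2L]
    for (g in c(a, b)) {
      if (!g %in% names(groups)) stop("unknown group label: ", g)
    }
    if (length(groups[[a]]) < 2L || length(groups[[b]]) < 2L) {
      warning("skipping ", a, " vs ", b, ": a group has fewer than 2 samples")
      next
    }
    d <- make_dichotomy(a, b, groups[[a]], groups[[b]])
    out[[paste0(a, "_vs_", b)]] <- data.frame(
      gene = rownames(p),
      pdeg = unname(pdeg(p, d)),
      cohen_d = unname(.cohens_d_rows(dm, d$samples_a, d$samples_b, d_max)),
      mean_a = unname(rowMeans(p[, d$samples_a, drop = FALSE])),
      mean_b = unname(rowMeans(p[, d$samples_b, drop = FALSE])),
      n_a = length(d$samples_a), n_b = length(d$samples_b),
      stringsAsFactors = FALSE)
  }
  out
}
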