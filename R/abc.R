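# Computed ABC analysis: the cumulative-contribution (Lorenz-like) curve
# over item magnitudes, the A|B and B|C boundaries, and the recursive
# application that derives the selection threshold for "the important few".
#
# Boundary rules: the A|B limit is the curve point closest (Euclidean) to the
# theoretically ideal point (0, 1); the B|C limit is the break-even rule —
# the last item whose segment slope exceeds 1, i.e., that still contributes
# more than a uniform share. Ties break toward the smaller index. Boundary
# indices are exported so alternative rules can be audited.

#' ABC curve of a non-negative value vector
#'
#' Items are sorted by descending value (ties by original index); curve point
#' `i` is `(i/n, cumulative value fraction)`.
#'
#' @param values Non-negative numeric vector with at least one positive entry.
#' @param ids Optional item identifiers (defaults to `names(values)` or
#'   indices).
#' @return A list of class `abc_curve` with `order` (original indices in
#'   sorted order), sorted `values`, curve coordinates `x`, `y`, and `n`.
#' @export
abc_curve <- function(values, ids = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty value vector")
  if (anyNA(values)) stop("values must not contain NA")
  if (any(values < 0)) stop("values must be non-negative")
  if (all(values == 0)) stop("all values are zero; nothing to rank")
  ord <- order(-values, seq_along(values))
  n <- length(values)
  vs <- values[ord]
  structure(list(order = ord, values = vs, x = seq_len(n) / n,
                 y = cumsum(vs) / sum(vs), n = n,
                 ids = if (is.null(ids)) names(values) else ids),
            class = "abc_curve")
}

#' Partition an ABC curve into sets A, B and C
#'
#' @param curve An `abc_curve`.
#' @return A list of class `abc_partition`: `A`, `B`, `C` (original indices),
#'   the boundary positions `ab_index` and `bc_index` (1-based inclusive ends
#'   of A and of B in sorted order), and the input curve.
#' @export
abc_partition <- function(curve) {
  stopifnot(inherits(curve, "abc_curve"))
  d2 <- curve$x^2 + (1 - curve$y)^2
  # ties break toward the smaller index; exact rational ties (e.g. curve
  # points mirrored about the diagonal) must not be decided by cumsum
  # rounding, so compare with a small tolerance
  ab <- which(d2 <= min(d2) + 1e-12)[1L]
  # segment slope_i = v_i * n / total; compare on the products so that exact
  # ties (uniform stretches) are never pushed over 1 by rounding
  above <- which(curve$values * curve$n > sum(curve$values))
  bc <- max(if (length(above) > 0L) max(above) else 0L, ab)
  idx <- curve$order
  structure(list(
    A = idx[seq_len(ab)],
    B = if (bc > ab) idx[(ab + 1L):bc] else integer(0),
    C = if (bc < curve$n) idx[(bc + 1L):curve$n] else integer(0),
    ab_index = as.integer(ab), bc_index = as.integer(bc),
    curve = curve), class = "abc_partition")
}

#' @export
print.abc_partition <- function(x, ...) {
  cat(sprintf("ABC partition: |A| = %d, |B| = %d, |C| = %d (n = %d)\n",
              length(x$A), length(x$B), length(x$C), x$curve$n))
  invisible(x)
}

#' Recursive computed ABC analysis
#'
#' Applies the ABC partition `iterations` times, each round keeping set A of
#' the previous round; at the final round either A or A-union-B is kept,
#' matching the two published selection modes. The selection threshold is the
#' smallest value of the final kept set. Rounds with fewer than 3 surviving
#' items stop the recursion early (with a warning), falling back on the last
#' completed round.
#'
#' @param values Non-negative numeric vector (use `abs()` of a signed
#'   statistic).
#' @param iterations Number of ABC rounds (>= 1), default 3.
#' @param keep `"A"` or `"AB"`: the set kept at the final round.
#' @return A list of class `abc_selection` with `threshold`, `kept`
#'   (original indices of the final kept set), `rounds` (kept indices per
#'   completed round), `iterations_run` and `keep`.
#' @export
recursive_abc <- function(values, iterations = 3, keep = c("AB", "A")) {
  keep <- match.arg(keep)
  if (iterations < 1) stop("iterations must be at least 1")
  values <- as.numeric(values)
  if (any(values < 0)) stop("values must be non-negative")
  if (length(values) > 0L && diff(range(values)) == 0) {
    warning("all values equal; threshold degenerates to that common value")
    return(structure(list(threshold = values[1L], kept = seq_along(values),
                          rounds = list(), iterations_run = 0L, keep = keep),
                     class = "abc_selection"))
  }
  idx <- seq_along(values)
  rounds <- list()
  for (r in seq_len(iterations)) {
    if (length(idx) < 3L) {
      warning("fewer than 3 items entering round ", r,
              "; stopping after ", r - 1L, " round(s)")
      break
    }
    pa <- abc_partition(abc_curve(values[idx]))
    sel <- if (r == iterations && keep == "AB") {
      c(pa$A, pa$B)
    } else {
      pa$A
    }
    idx <- idx[sel]
    rounds[[r]] <- sort(idx)
  }
  structure(list(threshold = min(values[idx]), kept = sort(idx),
                 rounds = rounds, iterations_run = length(rounds),
                 keep = keep),
            class = "abc_selection")
}

#' @export
print.abc_selection <- function(x, ...) {
  cat(sprintf("recursive ABC: threshold = %.4g after %d round(s), keep %s, |kept| = %d\n",
              x$threshold, x$iterations_run, x$keep, length(x$kept)))
  invisible(x)
}

#' Apply a selection threshold to a dichotomy table
#'
#' Marks genes whose selection statistic reaches `threshold` in absolute
#' value (the boundary itself is kept), and adds a display column where
#' Cohen's D values below `display_threshold` in absolute value are set to 0,
#' as in the published tables.
#'
#' @param tab A dichotomy table (see [dichotomy_table()]).
#' @param threshold Selection threshold, e.g. from [recursive_abc()].
#' @param display_threshold Zeroing threshold for the reported Cohen's D;
#'   defaults to `threshold`.
#' @param statistic Column used for selection, default `"pdeg"`.
#' @return `tab` with added logical `selected` and numeric `cohen_d_display`
#'   columns.
#' @export
select_genes <- function(tab, threshold, display_threshold = threshold,
                         statistic = "pdeg") {
  if (!statistic %in% colnames(tab)) stop("no column '", statistic, "'")
  tab$selected <- abs(tab[[statistic]]) >= threshold
  tab$cohen_d_display <- ifelse(abs(tab$cohen_d) < display_threshold,
                                0, tab$cohen_d)
  tab
}
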