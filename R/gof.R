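# Chi-square goodness of fit of a mixture model to pooled log expression.

# numeric inverse of the mixture CDF
.gmm_quantile <- function(model, p) {
  lo <- min(model$m - 10 * model$s)
  hi <- max(model$m + 10 * model$s)
  cdf <- function(q) {
    sum(model$w * stats::pnorm(q, model$m, model$s))
  }
  vapply(p, function(pp) {
    stats::uniroot(function(q) cdf(q) - pp, c(lo, hi), tol = 1e-10)$root
  }, 0)
}

#' Chi-square goodness of fit for a fitted mixture
#'
#' Bins the data into `n_bins` equal-probability bins under the model, merges
#' adjacent bins until every expected count reaches `min_expected`, and tests
#' the observed counts against the model with
#' `dof = bins - 1 - (3M - 1)` (mixture parameters estimated from the data).
#'
#' @param model A fitted `gmm`.
#' @param x Pooled log-expression values the model was fitted to (>= 100).
#' @param min_expected Minimum expected count per bin after merging.
#' @param n_bins Number of equal-probability bins before merging.
#' @return A list of class `gmm_gof` with `chi2_stat`, `dof`, `p_value`,
#'   `bin_edges`, `observed` and `expected`.
#' @export
chi_square_gof <- function(model, x, min_expected = 5, n_bins = 50) {
  stopifnot(inherits(model, "gmm"))
  x <- as.numeric(x)
  n <- length(x)
  if (n < 100L) stop("goodness of fit needs at least 100 points")
  inner <- .gmm_quantile(model, seq_len(n_bins - 1L) / n_bins)
  edges <- c(-Inf, inner, Inf)
  observed <- tabulate(findInterval(x, inner) + 1L, nbins = n_bins)
  expected <- rep(n / n_bins, n_bins)

  # merge adjacent bins until all expected counts are large enough; the
  # deficient bin joins its smaller neighbor so mass does not pile up in
  # one runaway bin
  while (length(expected) > 1L && min(expected) < min_expected) {
    i <- which.min(expected)
    j <- if (i == 1L) {
      2L
    } else if (i == length(expected)) {
      i - 1L
    } else if (expected[i + 1L] < expected[i - 1L]) {
      i + 1L
    } else {
      i - 1L
    }
    a <- min(i, j); b <- max(i, j)
    expected[a] <- expected[a] + expected[b]
    observed[a] <- observed[a] + observed[b]
    expected <- expected[-b]; observed <- observed[-b]
    edges <- edges[-b]
  }
  nb <- length(expected)
  dof <- nb - 1L - (3L * model$M - 1L)
  if (nb < 3L || dof < 1L) {
    stop("fewer than 3 usable bins (or no residual degrees of freedom); ",
         "increase the sample or decrease min_expected")
  }
  stat <- sum((observed - expected)^2 / expected)
  structure(list(chi2_stat = stat, dof = dof,
                 p_value = stats::pchisq(stat, dof, lower.tail = FALSE),
                 bin_edges = edges, observed = observed, expected = expected),
            class = "gmm_gof")
}

#' @export
print.gmm_gof <- function(x, ...) {
  cat(sprintf("chi-square GOF: stat = %.2f, dof = %d, p = %.4g (%d bins)\n",
              x$chi2_stat, x$dof, x$p_value, length(x$observed)))
  invisible(x)
}
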