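# Pooled Gaussian mixture modeling of log expression and Bayes posterior
# normalization.
#
# The pooled distribution of log-transformed expression values is modeled as
#   f(x) = sum_i w_i N(x | m_i, s_i),
# fitted by expectation-maximization with the component count chosen by AIC.
# The posterior probability that a value belongs to the high-expression
# component maps every measurement into [0, 1]; the decision border is the
# log-expression value where that posterior equals 0.5.

#' Construct a Gaussian mixture model
#'
#' Components are stored sorted by ascending mean, so the last component is
#' always the high-expression mode.
#'
#' @param w Component weights; must sum to 1.
#' @param m Component means (log-expression units).
#' @param s Component standard deviations, all positive.
#' @param log_base Base of the log transform the model lives on.
#' @return An object of class `gmm`.
#' @export
gmm <- function(w, m, s, log_base = 10) {
  w <- as.numeric(w); m <- as.numeric(m); s <- as.numeric(s)
  if (length(w) != length(m) || length(m) != length(s)) {
    stop("w, m, s must have equal length")
  }
  if (any(!is.finite(c(w, m, s)))) stop("non-finite mixture parameters")
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-9) stop("weights must be positive and sum to 1")
  if (any(s <= 0)) stop("standard deviations must be positive")
  ord <- order(m)
  structure(list(w = w[ord], m = m[ord], s = s[ord], M = length(w),
                 log_base = log_base, loglik = NA_real_, aic = NA_real_,
                 n_points = NA_integer_),
            class = "gmm")
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture model, M = %d (log base %g)\n", x$M, x$log_base))
  print(round(data.frame(w = x$w, m = x$m, s = x$s), 4))
  if (!is.na(x$aic)) {
    cat(sprintf("loglik %.2f, AIC %.2f, n = %d\n", x$loglik, x$aic, x$n_points))
  }
  invisible(x)
}

#' Log-transform an expression matrix
#'
#' @param m Non-negative numeric matrix or vector of raw expression values.
#' @param log_base Logarithm base (default 10).
#' @param pseudocount Added before taking the log; use 1 for count data with
#'   zeros, 0 for intensity data.
#' @return Matrix/vector of `log_base`-logarithms of `m + pseudocount`.
#' @export
log_transform <- function(m, log_base = 10, pseudocount = 0) {
  if (any(m < 0)) stop("expression values must be non-negative")
  if (any(m + pseudocount <= 0)) {
    stop("zero values require a positive pseudocount")
  }
  log(m + pseudocount, base = log_base)
}

#' Invert the log transform
#'
#' @param x_log Log-scale value(s).
#' @param log_base Logarithm base.
#' @param pseudocount Pseudocount used in [log_transform()].
#' @return Raw-scale value(s), `log_base^x_log - pseudocount`.
#' @export
back_transform <- function(x_log, log_base = 10, pseudocount = 0) {
  log_base^x_log - pseudocount
}

#' Mixture probability density
#'
#' @param model A `gmm` object.
#' @param x Numeric vector of log-scale values.
#' @return Density of the mixture at `x`.
#' @export
gmm_density <- function(model, x) {
  stopifnot(inherits(model, "gmm"))
  dens <- vapply(seq_len(model$M), function(k) {
    model$w[k] * stats::dnorm(x, model$m[k], model$s[k])
  }, numeric(length(x)))
  if (length(x) == 1L) sum(dens) else rowSums(matrix(dens, nrow = length(x)))
}

# log densities per component, n x M
.log_comp_dens <- function(model, x) {
  vapply(seq_len(model$M), function(k) {
    log(model$w[k]) + stats::dnorm(x, model$m[k], model$s[k], log = TRUE)
  }, numeric(length(x)))
}

#' Bayes posterior of mixture components
#'
#' Computes `p(c_k | x) = w_k N(x | m_k, s_k) / f(x)` in log space, so values
#' arbitrarily deep in the tails never produce NaN.
#'
#' @param model A `gmm` object.
#' @param x Numeric vector of log-scale values.
#' @param component `"high"` (component with the largest mean, the default),
#'   `"all"` (matrix of all component posteriors), or a component index.
#' @return Posterior probabilities: a vector, or an n-by-M matrix for
#'   `component = "all"`.
#' @export
posterior <- function(model, x, component = "high") {
  stopifnot(inherits(model, "gmm"))
  ld <- matrix(.log_comp_dens(model, x), nrow = length(x))
  lmax <- apply(ld, 1L, max)
  p <- exp(ld - lmax)
  p <- p / rowSums(p)
  if (identical(component, "all")) return(p)
  k <- if (identical(component, "high")) model$M else as.integer(component)
  if (k < 1L || k > model$M) stop("component index out of range")
  p[, k]
}

# quantile-split moment initialization, optionally perturbed
.init_em <- function(x, M, perturb) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = M + 1L),
                        names = FALSE)
  grp <- findInterval(x, qs[-c(1L, M + 1L)] , rightmost.closed = TRUE) + 1L
  m <- vapply(seq_len(M), function(k) mean(x[grp == k]), 0)
  s <- vapply(seq_len(M), function(k) {
    v <- stats::sd(x[grp == k])
    if (!is.finite(v) || v <= 0) diff(range(x)) / (4 * M) else v
  }, 0)
  w <- rep(1 / M, M)
  if (perturb) {
    spread <- stats::sd(x)
    m <- m + stats::rnorm(M, 0, spread / 2)
    s <- s * stats::runif(M, 0.5, 1.5)
    w <- w * stats::runif(M, 0.5, 1.5)
    w <- w / sum(w)
  }
  list(w = w, m = m, s = s)
}

# best-of-restarts EM for a fixed component count
.fit_em_M <- function(x, M, n_restarts, tol, max_iter, s_floor) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- .init_em(x, M, perturb = r > 1L)
    fit <- em_gmm_cpp(x, init$w, init$m, init$s, max_iter, tol, s_floor)
    if (fit$degenerate) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop("all EM restarts degenerated for M = ", M,
         " (component standard deviation below floor)")
  }
  best
}

#' Fit a Gaussian mixture by EM with AIC model-order selection
#'
#' For every candidate component count the model is fitted by
#' expectation-maximization (best of `n_restarts` initializations: a
#' quantile-split moment start plus random perturbations); the returned model
#' minimizes `AIC = 2k - 2 logL` with `k = 3M - 1` free parameters.
#'
#' @param x Numeric vector of pooled log-expression values (>= 50 points).
#' @param m_candidates Candidate component counts, a subset of 1..6.
#' @param n_restarts EM restarts per candidate.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param max_iter Maximum EM iterations per run.
#' @param s_floor Lower bound on component standard deviations; defaults to
#'   `1e-4` of the data range. A run crossing the floor is discarded as
#'   degenerate and restarted.
#' @param seed Optional integer seed for the restart perturbations; the
#'   caller's RNG state is preserved.
#' @param log_base Log base recorded in the model.
#' @return A `gmm` object with `loglik`, `aic`, `n_points`, an
#'   `aic_table` attribute (one row per candidate M) and a `trace` attribute
#'   (per-iteration log-likelihood of the winning EM run).
#' @export
fit_gmm <- function(x, m_candidates = 1:5, n_restarts = 10, tol = 1e-8,
                    max_iter = 500L, s_floor = NULL, seed = NULL,
                    log_base = 10) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("x must be finite")
  if (length(x) < 50L) stop("need at least 50 pooled values")
  m_candidates <- sort(unique(as.integer(m_candidates)))
  if (!all(m_candidates %in% 1:6)) stop("m_candidates must lie in 1..6")
  if (is.null(s_floor)) s_floor <- 1e-4 * diff(range(x))

  with_seed(seed, {
    fits <- lapply(m_candidates, function(M) {
      .fit_em_M(x, M, n_restarts, tol, max_iter, s_floor)
    })
    k <- 3 * m_candidates - 1
    loglik <- vapply(fits, function(f) f$loglik, 0)
    aic <- 2 * k - 2 * loglik
    best_i <- which.min(aic)
    fit <- fits[[best_i]]
    model <- gmm(fit$w, fit$m, fit$s, log_base = log_base)
    model$loglik <- fit$loglik
    model$aic <- aic[best_i]
    model$n_points <- length(x)
    attr(model, "aic_table") <- data.frame(
      M = m_candidates, loglik = loglik, aic = aic,
      converged = vapply(fits, function(f) isTRUE(f$converged), TRUE))
    attr(model, "trace") <- fit$trace
    model
  })
}

#' Locate the Bayesian decision border of a fitted mixture
#'
#' The border is the log-expression value where the posterior of the
#' high-expression component equals 0.5. For models with more than two
#' components the border is placed between the two components flanking the
#' largest mean gap, using their pairwise posterior.
#'
#' @param model A `gmm` object with at least two components.
#' @param tol Bisection tolerance on the border location.
#' @return A list of class `decision_border` with `x_log`, the back-transformed
#'   `x_raw = log_base^x_log`, the posterior at the border, and the flanking
#'   component indices.
#' @export
decision_border <- function(model, tol = 1e-12) {
  stopifnot(inherits(model, "gmm"))
  if (model$M < 2L) stop("decision border requires at least two components")
  gap <- which.max(diff(model$m))
  lo <- gap; hi <- gap + 1L
  # pairwise posterior of the high component minus 0.5, in log space
  f <- function(x) {
    la <- log(model$w[lo]) + stats::dnorm(x, model$m[lo], model$s[lo], log = TRUE)
    lb <- log(model$w[hi]) + stats::dnorm(x, model$m[hi], model$s[hi], log = TRUE)
    1 / (1 + exp(la - lb)) - 0.5
  }
  a <- model$m[lo]; b <- model$m[hi]
  fa <- f(a); fb <- f(b)
  if (is.na(fa) || is.na(fb) || fa * fb > 0) {
    stop(sprintf(paste0("no posterior = 0.5 crossing between component means ",
                        "%g and %g (posteriors %.4f / %.4f); the component ",
                        "weights leave one mode dominant on the whole interval"),
                 a, b, fa + 0.5, fb + 0.5))
  }
  while (b - a > tol) {
    mid <- (a + b) / 2
    if (fa * f(mid) <= 0) b <- mid else a <- mid
  }
  x_log <- (a + b) / 2
  structure(list(x_log = x_log,
                 x_raw = back_transform(x_log, model$log_base),
                 posterior = f(x_log) + 0.5,
                 components = c(low = lo, high = hi)),
            class = "decision_border")
}

#' @export
print.decision_border <- function(x, ...) {
  cat(sprintf("decision border: x_log = %.4f (raw %.4g), posterior %.6f\n",
              x$x_log, x$x_raw, x$posterior))
  invisible(x)
}

#' Normalize a log-expression matrix to Bayes posteriors
#'
#' Every entry is replaced by the posterior probability of the high-expression
#' component, mapping the matrix into the closed interval [0, 1]: 0 indicates
#' definitive underexpression, 1 definitive overexpression.
#'
#' @param model A fitted `gmm`.
#' @param log_matrix Matrix of log-scale expression values (genes in rows).
#' @return Matrix of posteriors with the same dimnames.
#' @export
normalize_to_posteriors <- function(model, log_matrix) {
  stopifnot(inherits(model, "gmm"))
  p <- posterior(model, as.numeric(log_matrix), component = "high")
  out <- matrix(p, nrow = nrow(log_matrix), ncol = ncol(log_matrix),
                dimnames = dimnames(log_matrix))
  out
}
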