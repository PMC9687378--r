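test_that("log and back transforms are exact inverses at the printed pairs", {
  expect_equal(log_transform(1000), 3)
  expect_equal(log_transform(0, pseudocount = 1), 0)
  expect_equal(signif(log_transform(912), 3), 2.96)
  expect_equal(signif(back_transform(2.96), 3), 912)
  expect_equal(signif(back_transform(1.48), 3), 30.2)
  expect_equal(back_transform(0), 1)

  x <- c(0.5, 1, 912, 30.2, 1e5)
  expect_equal(back_transform(log_transform(x)), x, tolerance = 1e-9)
  expect_equal(back_transform(log_transform(x, pseudocount = 1),
                              pseudocount = 1), x, tolerance = 1e-9)
  expect_error(log_transform(c(0, 1)), "pseudocount")
  expect_error(log_transform(-1), "non-negative")
})

test_that("the mixture density matches a term-by-term evaluation", {
  single <- gmm(1, 0, 1)
  expect_equal(gmm_density(single, 0), 1 / sqrt(2 * pi))

  sym <- gmm(c(0.5, 0.5), c(-2, 2), c(1, 1))
  expect_equal(gmm_density(sym, 0), dnorm(2))

  model <- gmm(c(0.6, 0.4), c(1, 4), c(0.5, 0.5))
  x <- 2.5
  manual <- 0.6 * exp(-(x - 1)^2 / (2 * 0.25)) / (sqrt(2 * pi) * 0.5) +
    0.4 * exp(-(x - 4)^2 / (2 * 0.25)) / (sqrt(2 * pi) * 0.5)
  expect_equal(gmm_density(model, x), manual, tolerance = 1e-12)

  grid <- seq(-10, 15, by = 0.01)
  expect_equal(sum(gmm_density(model, grid)) * 0.01, 1, tolerance = 1e-4)
})

test_that("posteriors follow Bayes' rule, sum to one and never underflow", {
  sym <- gmm(c(0.5, 0.5), c(0, 4), c(1, 1))
  expect_equal(posterior(sym, 2), 0.5)
  expect_equal(posterior(sym, 2, component = 1), 0.5)
  expect_gt(posterior(sym, 4), 0.5)

  model <- gmm(c(0.6, 0.4), c(1, 4), c(0.5, 0.5))
  x <- 2.5
  num <- 0.4 * dnorm(x, 4, 0.5)
  den <- 0.6 * dnorm(x, 1, 0.5) + num
  expect_equal(posterior(model, x), num / den, tolerance = 1e-12)

  grid <- c(-1e4, -50, seq(-5, 10, by = 0.5), 50, 1e4)
  p_all <- posterior(model, grid, component = "all")
  expect_false(anyNA(p_all))
  expect_equal(rowSums(p_all), rep(1, length(grid)), tolerance = 1e-9)
  expect_equal(posterior(model, 1e4), 1)
  expect_equal(posterior(model, -1e4), 0)
})

test_that("EM recovers parameters and increases the likelihood monotonically", {
  set.seed(21)
  x1 <- rnorm(20000, 2, 1)
  m1 <- fit_gmm(x1, m_candidates = 1:3, n_restarts = 4, seed = 1)
  expect_equal(m1$M, 1L)
  expect_lt(abs(m1$m - 2), 0.05)
  expect_lt(abs(m1$s - 1), 0.05)

  set.seed(22)
  x2 <- c(rnorm(30000, 1, 0.5), rnorm(20000, 4, 0.5))
  m2 <- fit_gmm(x2, m_candidates = 2, n_restarts = 4, seed = 2)
  expect_lt(max(abs(m2$w - c(0.6, 0.4))), 0.05)
  expect_lt(max(abs(m2$m - c(1, 4))), 0.05)
  expect_lt(max(abs(m2$s - c(0.5, 0.5))), 0.05)
  expect_equal(sum(m2$w), 1, tolerance = 1e-9)

  trace <- attr(m2, "trace")
  expect_true(all(diff(trace) > -1e-10))

  expect_error(fit_gmm(rnorm(10)), "at least 50")
  expect_error(fit_gmm(x1, m_candidates = 7), "1..6")
})

test_that("our EM matches an independent mixture implementation", {
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(31)
  x <- c(rnorm(3000, 1, 0.5), rnorm(2000, 4, 0.6))
  ours <- fit_gmm(x, m_candidates = 2, n_restarts = 5, seed = 3)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-6)
  expect_equal(ours$m, as.numeric(ref$parameters$mean), tolerance = 0.01)
  expect_equal(ours$w, as.numeric(ref$parameters$pro), tolerance = 0.01)
})

test_that("the decision border sits exactly at posterior one half", {
  sym <- gmm(c(0.5, 0.5), c(0, 4), c(1, 1))
  b <- decision_border(sym)
  expect_equal(b$x_log, 2, tolerance = 1e-8)
  expect_equal(b$posterior, 0.5, tolerance = 1e-8)
  expect_equal(b$x_raw, 10^b$x_log)

  skewed <- gmm(c(0.7, 0.3), c(1, 4), c(0.5, 0.5))
  b2 <- decision_border(skewed)
  expect_equal(posterior(skewed, b2$x_log), 0.5, tolerance = 1e-8)
  # brute-force grid scan oracle
  grid <- seq(1, 4, by = 1e-6)
  p <- posterior(skewed, grid)
  root <- grid[which.min(abs(p - 0.5))]
  expect_equal(b2$x_log, root, tolerance = 1e-5)
  expect_true(b2$x_log > 1 && b2$x_log < 4)

  # pathological weights: the high mode dominates the whole interval
  lop <- gmm(c(1e-9, 1 - 1e-9), c(0, 0.5), c(1, 1))
  expect_error(decision_border(lop), "crossing")
  expect_error(decision_border(gmm(1, 0, 1)), "two components")
})

test_that("posterior normalization is elementwise and respects its limits", {
  set.seed(41)
  x <- c(rnorm(800, 1, 0.4), rnorm(700, 4, 0.5))
  model <- fit_gmm(x, m_candidates = 2, n_restarts = 3, seed = 4)
  lg <- matrix(sample(x, 500), 50, 10,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  post <- normalize_to_posteriors(model, lg)
  expect_true(all(post >= 0 & post <= 1))
  expect_equal(as.numeric(post), posterior(model, as.numeric(lg)))

  b <- decision_border(model)
  at_border <- matrix(b$x_log, 3, 3,
                      dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(as.numeric(normalize_to_posteriors(model, at_border)),
               rep(0.5, 9), tolerance = 1e-8)
  # tail limits hold for equal-variance models (with unequal variances the
  # wider component rightfully dominates both far tails)
  eq <- gmm(c(0.5, 0.5), c(1, 4), c(0.5, 0.5))
  hi <- matrix(100, 1, 1, dimnames = list("g", "s"))
  lo <- matrix(-100, 1, 1, dimnames = list("g", "s"))
  expect_equal(as.numeric(normalize_to_posteriors(eq, hi)), 1)
  expect_equal(as.numeric(normalize_to_posteriors(eq, lo)), 0)
  grid <- seq(-3, 8, by = 0.05)
  expect_true(all(diff(posterior(eq, grid)) >= 0))   # monotone for equal s
})
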