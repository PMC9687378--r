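toy_posteriors <- function() {
  m <- rbind(g1 = c(0.9, 0.8, 0.1, 0.3),
             g2 = c(1, 1, 0, 0),
             g3 = c(0.4, 0.4, 0.4, 0.4))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  m
}

test_that("group-average posteriors are plain arithmetic means", {
  p <- toy_posteriors()
  expect_equal(group_mean_posterior(p, "g1", c("a1", "a2")), 0.85)
  expect_equal(group_mean_posterior(p, "g2", c("a1", "a2")), 1)
  expect_equal(group_mean_posterior(p, "g3", "b1"), 0.4)
  expect_error(group_mean_posterior(p, "g1", "zz"), "unknown sample")
})

test_that("pdeg is the difference of group means, bounded and antisymmetric", {
  p <- toy_posteriors()
  d <- make_dichotomy("A", "B", c("a1", "a2"), c("b1", "b2"))
  v <- pdeg(p, d)
  expect_equal(unname(v["g1"]), 0.65)
  expect_equal(unname(v["g2"]), 1)          # maximal overexpression in A
  expect_equal(unname(v["g3"]), 0)          # identical groups

  swap <- make_dichotomy("B", "A", c("b1", "b2"), c("a1", "a2"))
  expect_equal(pdeg(p, swap), -v)

  # property: pdeg stays within [-1, 1] for arbitrary posterior matrices
  set.seed(8)
  for (i in 1:20) {
    pm <- matrix(runif(60), 6, 10,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
    di <- make_dichotomy("x", "y", paste0("s", 1:4), paste0("s", 5:10))
    vv <- pdeg(pm, di)
    expect_true(all(vv >= -1 & vv <= 1))
    expect_equal(pdeg(pm, make_dichotomy("y", "x", paste0("s", 5:10),
                                         paste0("s", 1:4))), -vv)
  }
})

test_that("Cohen's D matches the pooled-SD formula and its invariances", {
  expect_equal(cohens_d(1:3, 4:6), -3)
  expect_equal(cohens_d(4:6, 1:3), 3)
  expect_equal(cohens_d(c(2, 2, 2), c(2, 2, 2)), 0)

  set.seed(9)
  a <- rnorm(15); b <- rnorm(20, 1)
  d0 <- cohens_d(a, b)
  expect_equal(cohens_d(a + 5, b + 5), d0)          # shift invariance
  expect_equal(cohens_d(3 * a, 3 * b), d0)          # scale invariance
  expect_equal(cohens_d(b, a), -d0)

  expect_warning(dcap <- cohens_d(c(1, 1), c(0, 0)), "capping")
  expect_equal(dcap, 10)
  expect_error(cohens_d(1, 1:3), "at least 2")
})

test_that("dichotomy tables carry both statistics for each valid pair", {
  p <- toy_posteriors()
  groups <- list(A = c("a1", "a2"), B = c("b1", "b2"), tiny = "a1")
  expect_error(make_dichotomy("A", "A2", c("a1", "a2"), c("a2", "b1")),
               "disjoint")

  # two warnings expected: the skipped undersized pair and the capped D of
  # the zero-variance gene
  expect_warning(
    expect_warning(tabs <- dichotomy_table(p, groups,
                                           list(c("A", "B"), c("A", "tiny"))),
                   "fewer than 2"),
    "capping")
  expect_named(tabs, "A_vs_B")
  tab <- tabs$A_vs_B
  expect_equal(tab$gene, rownames(p))
  expect_equal(tab$pdeg, c(0.65, 1, 0))
  expect_equal(tab$n_a, rep(2L, 3))
  expect_equal(sign(tab$cohen_d[1:2]), c(1, 1))
  expect_error(dichotomy_table(p, groups, list(c("A", "nope"))), "unknown group")

  # effect-size substrate sensitivity: D from an alternative matrix,
  # pdeg still from the posteriors
  lg <- p * 4 + 1
  tab2 <- suppressWarnings(
    dichotomy_table(p, groups, list(c("A", "B")), d_matrix = lg))$A_vs_B
  expect_equal(tab2$pdeg, tab$pdeg)
  expect_equal(tab2$cohen_d, tab$cohen_d)   # D is shift/scale invariant
  bad <- lg; rownames(bad) <- rev(rownames(bad))
  expect_error(dichotomy_table(p, groups, list(c("A", "B")), d_matrix = bad),
               "dimnames")
})

test_that("a fully separated planted marker tops its dichotomy", {
  de <- data.frame(gene = 5L, group = "A", direction = 1L, effect = 1)
  cfg <- simulation_config(n_genes = 80, group_sizes = c(A = 10, B = 10),
                           m_low = 1, s_low = 0.3, m_high = 4, s_high = 0.3,
                           state_fidelity = 1, noise_sd = 0, de_spec = de,
                           seed = 12)
  sim <- simulate_expression(cfg)
  lg <- log_transform(sim$expression)
  model <- fit_gmm(as.numeric(lg), m_candidates = 2, n_restarts = 3, seed = 1)
  post <- normalize_to_posteriors(model, lg)
  ann <- sim$annotations
  groups <- split(ann$sample_id, ann$label)
  tab <- dichotomy_table(post, groups, list(c("A", "B")))$A_vs_B
  expect_equal(which.max(abs(tab$pdeg)), 5L)
  expect_gt(abs(tab$pdeg[5]), 0.95)
})

test_that("without planted effects pdeg noise stays within the binomial bound", {
  # Null oracle: the group-mean state difference has SD
  # sqrt(f(1-f)(1/n_a+1/n_b)) — 0.095 for the smallest pair (15 vs 29) at
  # f = 0.9 — scaled by the posterior contrast (~0.85). The maximum over
  # 417 genes and three dichotomies sits near 3.5 SDs (~0.28) with a
  # discrete binomial tail reaching ~4.5-5 SDs; 0.45 bounds it.
  maxima <- sapply(1:5, function(seed) {
    cfg <- simulation_config(de_spec = NULL, seed = seed)
    sim <- simulate_expression(cfg)
    lg <- log_transform(sim$expression)
    model <- fit_gmm(sample(as.numeric(lg), 10000), m_candidates = 2,
                     n_restarts = 3, seed = seed)
    post <- normalize_to_posteriors(model, lg)
    ann <- sim$annotations
    groups <- split(ann$sample_id, ann$label)
    pairs <- list(c("APL", "AML1"), c("APL", "AML2"), c("AML1", "AML2"))
    tabs <- dichotomy_table(post, groups, pairs)
    c(max(sapply(tabs, function(t) max(abs(t$pdeg)))),
      mean(sapply(tabs, function(t) mean(t$pdeg))))
  })
  expect_lt(max(maxima[1, ]), 0.45)
  expect_lt(mean(maxima[1, ]), 0.35)
  expect_lt(max(abs(maxima[2, ])), 0.05)   # centered null
})
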