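# Synthetic expression data with the statistical structure the analysis
# assumes: a bimodal pooled log-expression distribution (unexpressed and
# expressed modes), planted sample subgroups, and planted marker genes with
# ground truth for recovery testing.
#
# Expression states are generated per gene and group as a probability of
# being in the high (expressed) mode; each sample then draws its state from
# that probability, emulating the within-group heterogeneity of real tumor
# samples. Differential expression is planted by shifting a gene's high-state
# probability in one group relative to all others (a marker gene), so the
# posterior-difference statistic responds to mode membership, not merely to
# mean shifts.

#' Default marker-gene assignment
#'
#' One-vs-rest marker genes per leukemia-like subgroup, alternating direction
#' (overexpressed / underexpressed in the marked group), full effect. The APL
#' analog receives the most markers, mirroring how strongly promyelocytic
#' leukemia separates from the rest of AML.
#'
#' @param markers Named integer vector: markers per group.
#' @param effect Effect multiplier in (0, 1]; 1 is a full state flip.
#' @param start_gene Index of the first marker gene.
#' @return Data frame with columns `gene`, `group`, `direction`, `effect`.
#' @export
default_de_spec <- function(markers = c(APL = 26, AML1 = 13, AML2 = 13),
                            effect = 1, start_gene = 1L) {
  gi <- start_gene
  rows <- lapply(names(markers), function(g) {
    n <- markers[[g]]
    df <- data.frame(gene = seq.int(gi, length.out = n), group = g,
                     direction = rep_len(c(1L, -1L), n), effect = effect,
                     stringsAsFactors = FALSE)
    gi <<- gi + n
    df
  })
  do.call(rbind, rows)
}

#' Build a simulation configuration
#'
#' @param n_genes Number of genes.
#' @param group_sizes Named integer vector of samples per group; every group
#'   needs at least 2 samples.
#' @param m_low,s_low Mean and SD of the unexpressed (low) mode, log scale.
#' @param m_high,s_high Mean and SD of the expressed (high) mode, log scale.
#' @param w_low Baseline fraction of unexpressed gene states, in (0, 1).
#' @param state_fidelity Probability that a sample realizes its group's
#'   expression state, in (0.5, 1]; 1 makes states deterministic.
#' @param noise_sd Extra within-state jitter on the log scale.
#' @param de_spec Data frame of planted marker genes
#'   (`gene`, `group`, `direction`, `effect`), or `NULL` for none.
#' @param log_base,pseudocount Transform parameters; generation happens on
#'   the log scale and is back-transformed with these, so the pipeline's log
#'   transform exactly inverts it.
#' @param seed Integer seed; a fixed seed makes [simulate_expression()]
#'   byte-identical.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 417,
                              group_sizes = c(APL = 15, AML1 = 106,
                                              AML2 = 29, normal = 40),
                              m_low = 2.2, s_low = 0.45,
                              m_high = 3.5, s_high = 0.5,
                              w_low = 0.6, state_fidelity = 0.9,
                              noise_sd = 0.1, de_spec = NULL,
                              log_base = 10, pseudocount = 0, seed = 101) {
  if (!is_count(n_genes)) stop("n_genes must be a positive integer")
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    stop("group_sizes must be named")
  }
  if (any(group_sizes < 2)) stop("every group needs at least 2 samples")
  if (s_low <= 0 || s_high <= 0) stop("mode standard deviations must be positive")
  if (m_low >= m_high) stop("m_low must be below m_high")
  if (w_low <= 0 || w_low >= 1) stop("w_low must lie in (0, 1)")
  if (state_fidelity <= 0.5 || state_fidelity > 1) {
    stop("state_fidelity must lie in (0.5, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(de_spec)) {
    req <- c("gene", "group", "direction", "effect")
    if (!all(req %in% colnames(de_spec))) {
      stop("de_spec needs columns ", paste(req, collapse = ", "))
    }
    if (any(de_spec$gene < 1 | de_spec$gene > n_genes)) {
      stop("de_spec gene index out of range")
    }
    if (anyDuplicated(de_spec$gene)) stop("a gene may carry only one marker assignment")
    if (!all(de_spec$group %in% names(group_sizes))) {
      stop("de_spec group not in group_sizes")
    }
    if (!all(de_spec$direction %in% c(-1L, 1L))) stop("direction must be +1 or -1")
    if (any(de_spec$effect <= 0 | de_spec$effect > 1)) {
      stop("effect must lie in (0, 1]")
    }
  }
  structure(list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
                 m_low = m_low, s_low = s_low, m_high = m_high,
                 s_high = s_high, w_low = w_low,
                 state_fidelity = state_fidelity, noise_sd = noise_sd,
                 de_spec = de_spec, log_base = log_base,
                 pseudocount = pseudocount, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Reference simulation configuration
#'
#' 417 CD-like genes; subgroups APL-like (15), AML1-like (106), AML2-like
#' (29) and normal-like (40) samples; log10 modes 2.2 (SD 0.45) and 3.5
#' (SD 0.50) with 60% baseline unexpressed states; 26/13/13 one-vs-rest
#' marker genes at full effect. Stable across releases.
#'
#' @return A `simulation_config`.
#' @export
default_config <- function() {
  simulation_config(de_spec = default_de_spec())
}

# high-state probability per gene x group implied by a config
.state_probs <- function(cfg) {
  groups <- names(cfg$group_sizes)
  base <- stats::rbinom(cfg$n_genes, 1L, 1 - cfg$w_low)
  P <- matrix(ifelse(base == 1L, cfg$state_fidelity, 1 - cfg$state_fidelity),
              nrow = cfg$n_genes, ncol = length(groups),
              dimnames = list(NULL, groups))
  if (!is.null(cfg$de_spec)) {
    for (i in seq_len(nrow(cfg$de_spec))) {
      r <- cfg$de_spec[i, ]
      hi <- 0.5 + r$effect * (cfg$state_fidelity - 0.5)
      lo <- 0.5 - r$effect * (cfg$state_fidelity - 0.5)
      if (r$direction > 0) {
        P[r$gene, ] <- lo; P[r$gene, r$group] <- hi
      } else {
        P[r$gene, ] <- hi; P[r$gene, r$group] <- lo
      }
    }
  }
  P
}

#' Simulate an expression study
#'
#' Draws per-sample expression states from the per-gene, per-group high-state
#' probabilities, samples log-scale values from the corresponding mode, adds
#' within-state jitter, and back-transforms to the raw scale with the
#' config's log base (so the analysis log transform inverts generation
#' exactly).
#'
#' @param cfg A `simulation_config`.
#' @return A list of class `aml_simulation` with elements
#'   \describe{
#'     \item{expression}{raw-scale matrix, genes in rows (`CD001`, ...).}
#'     \item{annotations}{data frame `sample_id`, `label`.}
#'     \item{truth}{ground truth: `state_prob` (gene-by-group high-state
#'       probabilities), the `de_spec`, and the config.}
#'   }
#' @export
simulate_expression <- function(cfg = default_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    groups <- names(cfg$group_sizes)
    labels <- rep(groups, cfg$group_sizes)
    n_samples <- length(labels)
    gene_ids <- sprintf("CD%0*d", max(3L, nchar(cfg$n_genes)),
                        seq_len(cfg$n_genes))
    sample_ids <- sprintf("S%0*d", max(3L, nchar(n_samples)),
                          seq_len(n_samples))
    P <- .state_probs(cfg)
    probs <- P[, labels, drop = FALSE]
    states <- matrix(stats::rbinom(length(probs), 1L, probs),
                     nrow = cfg$n_genes)
    mu <- ifelse(states == 1L, cfg$m_high, cfg$m_low)
    sdv <- ifelse(states == 1L, cfg$s_high, cfg$s_low)
    lg <- matrix(stats::rnorm(length(mu), mu, sdv), nrow = cfg$n_genes)
    if (cfg$noise_sd > 0) {
      lg <- lg + matrix(stats::rnorm(length(mu), 0, cfg$noise_sd),
                        nrow = cfg$n_genes)
    }
    raw <- back_transform(lg, cfg$log_base, cfg$pseudocount)
    if (cfg$pseudocount > 0) raw <- pmax(raw, 0)
    dimnames(raw) <- list(gene_ids, sample_ids)
    rownames(P) <- gene_ids
    structure(list(
      expression = raw,
      annotations = data.frame(sample_id = sample_ids, label = labels,
                               stringsAsFactors = FALSE),
      truth = list(state_prob = P, de_spec = cfg$de_spec, config = cfg)
    ), class = "aml_simulation")
  })
}

#' Realized differential-expression truth for one dichotomy
#'
#' A gene is truly differentially expressed between two groups when its
#' high-state probabilities differ by at least `min_shift` — the planted
#' state-frequency shift the selection stage is asked to recover.
#'
#' @param truth The `truth` element of an [simulate_expression()] result.
#' @param group_a,group_b Group labels.
#' @param min_shift Minimum state-probability difference counted as true
#'   differential expression.
#' @return Named logical vector over genes.
#' @export
de_truth <- function(truth, group_a, group_b, min_shift = 0.5) {
  P <- truth$state_prob
  for (g in c(group_a, group_b)) {
    if (!g %in% colnames(P)) stop("unknown group: ", g)
  }
  abs(P[, group_a] - P[, group_b]) >= min_shift
}
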