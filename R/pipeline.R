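# End-to-end orchestration: log transform -> pooled GMM fit (AIC) -> GOF ->
# posterior normalization -> Ward clustering and cut -> contingency ->
# dichotomy statistics -> recursive ABC threshold -> gene selection.

#' Build a pipeline configuration
#'
#' Input is either a simulation config (the default) or a pair of file paths
#' to an expression matrix and annotation table.
#'
#' @param simulation A [simulation_config()] used to generate the input, or
#'   `NULL` when `expression_path` is given.
#' @param expression_path,annotations_path Paths to TSV inputs, used when
#'   `simulation` is `NULL`.
#' @param log_base,pseudocount Log-transform parameters.
#' @param m_candidates,n_restarts Mixture-fit settings (see [fit_gmm()]).
#' @param gmm_sample Number of pooled values subsampled for the mixture fit
#'   and the goodness-of-fit test (`NULL` uses all pooled values).
#' @param k_max Largest cluster count for the dendrogram cut.
#' @param exclude_labels Annotation labels excluded from clustering (the
#'   diagnostic reference entities, e.g. normals); they still enter the
#'   vs-reference dichotomies.
#' @param abc_iterations,abc_keep Recursive-ABC settings.
#' @param display_threshold Zeroing threshold for reported Cohen's D values;
#'   `NULL` uses the ABC-derived selection threshold.
#' @param seed Seed for the mixture fit and pooled subsampling.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = default_config(),
                            expression_path = NULL, annotations_path = NULL,
                            log_base = 10, pseudocount = 0,
                            m_candidates = 1:5, n_restarts = 10,
                            gmm_sample = 20000L, k_max = 10,
                            exclude_labels = "normal",
                            abc_iterations = 3, abc_keep = "AB",
                            display_threshold = NULL, seed = 2203) {
  if (is.null(simulation) && is.null(expression_path)) {
    stop("either a simulation config or an expression_path is required")
  }
  structure(list(simulation = simulation,
                 expression_path = expression_path,
                 annotations_path = annotations_path,
                 log_base = log_base, pseudocount = pseudocount,
                 m_candidates = m_candidates, n_restarts = n_restarts,
                 gmm_sample = gmm_sample, k_max = k_max,
                 exclude_labels = exclude_labels,
                 abc_iterations = abc_iterations, abc_keep = abc_keep,
                 display_threshold = display_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition, log transform, pooled mixture fit
#' with AIC selection, chi-square goodness of fit, posterior normalization,
#' Ward clustering of the non-reference samples with the fusion-gap cut,
#' cluster-vs-label contingency, per-dichotomy `pdeg` and Cohen's D tables
#' (all cluster pairs, plus each cluster against each excluded reference
#' label), recursive ABC on the pooled `|pdeg|` values, and gene selection.
#' Deterministic given the seeds in the configuration.
#'
#' @param cfg A `pipeline_config`.
#' @param out_dir Optional directory; when given, all intermediates and a
#'   JSON run report are written via [write_pipeline_report()].
#' @return A list of class `aml_pipeline_run`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))

  input <- run_stage("input", {
    if (!is.null(cfg$simulation)) {
      sim <- simulate_expression(cfg$simulation)
      list(expression = sim$expression, annotations = sim$annotations,
           truth = sim$truth)
    } else {
      list(expression = read_expression_matrix(cfg$expression_path),
           annotations = read_annotations(cfg$annotations_path),
           truth = NULL)
    }
  })

  logm <- run_stage("log_transform",
                    log_transform(input$expression, cfg$log_base,
                                  cfg$pseudocount))

  pooled <- as.numeric(logm)
  fit_input <- run_stage("gmm_fit", {
    if (!is.null(cfg$gmm_sample) && cfg$gmm_sample < length(pooled)) {
      with_seed(cfg$seed, sample(pooled, cfg$gmm_sample))
    } else {
      pooled
    }
  })
  model <- run_stage("gmm_fit",
                     fit_gmm(fit_input, m_candidates = cfg$m_candidates,
                             n_restarts = cfg$n_restarts, seed = cfg$seed + 1L,
                             log_base = cfg$log_base))
  gof <- run_stage("goodness_of_fit", chi_square_gof(model, fit_input))
  border <- run_stage("decision_border", {
    if (model$M >= 2L) decision_border(model) else NULL
  })
  post <- run_stage("normalize", normalize_to_posteriors(model, logm))

  ann <- input$annotations
  cluster_samples <- ann$sample_id[!ann$label %in% cfg$exclude_labels]
  hc <- run_stage("ward_cluster", ward_cluster(post, cluster_samples))
  partition <- run_stage("choose_cut", choose_cut(hc, cfg$k_max))
  contingency <- run_stage("contingency",
                           cluster_contingency(partition, ann))

  groups <- run_stage("dichotomies", {
    g <- split(names(partition$labels), paste0("G", partition$labels))
    for (lab in intersect(cfg$exclude_labels, unique(ann$label))) {
      g[[lab]] <- ann$sample_id[ann$label == lab]
    }
    g
  })
  cluster_ids <- paste0("G", seq_len(partition$K))
  pairs <- c(
    if (partition$K >= 2L) {
      cmb <- utils::combn(cluster_ids, 2L)
      lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
    },
    unlist(lapply(intersect(cfg$exclude_labels, unique(ann$label)),
                  function(lab) lapply(cluster_ids, function(g) c(g, lab))),
           recursive = FALSE)
  )
  tables <- run_stage("dichotomies", dichotomy_table(post, groups, pairs))

  selection <- run_stage("abc_selection", {
    pooled_pdeg <- abs(unlist(lapply(tables, `[[`, "pdeg"), use.names = FALSE))
    recursive_abc(pooled_pdeg, iterations = cfg$abc_iterations,
                  keep = cfg$abc_keep)
  })
  disp <- if (is.null(cfg$display_threshold)) selection$threshold else cfg$display_threshold
  selected <- run_stage("select_genes", {
    lapply(tables, select_genes, threshold = selection$threshold,
           display_threshold = disp)
  })

  run <- structure(list(
    config = cfg, annotations = ann, truth = input$truth,
    model = model, gof = gof, border = border, posteriors = post,
    hclust = hc, partition = partition, contingency = contingency,
    groups = groups, tables = tables, selection = selection,
    display_threshold = disp, selected = selected
  ), class = "aml_pipeline_run")

  if (!is.null(out_dir)) write_pipeline_report(run, out_dir)
  run
}

#' @export
print.aml_pipeline_run <- function(x, ...) {
  cat("AML surface-marker pipeline run\n")
  cat(sprintf("  mixture: M = %d by AIC (n = %d pooled values)\n",
              x$model$M, x$model$n_points))
  if (!is.null(x$border)) {
    cat(sprintf("  decision border: log %.3f -> raw %.3g\n",
                x$border$x_log, x$border$x_raw))
  }
  cat(sprintf("  GOF: chi2 = %.1f (dof %d), p = %.3g\n",
              x$gof$chi2_stat, x$gof$dof, x$gof$p_value))
  cat(sprintf("  clustering: K = %d on %d samples\n", x$partition$K,
              length(x$partition$labels)))
  cat(sprintf("  ABC threshold (|pdeg|, keep %s): %.3f\n",
              x$selection$keep, x$selection$threshold))
  for (nm in names(x$selected)) {
    cat(sprintf("  %s: %d gene(s) selected\n", nm,
                sum(x$selected[[nm]]$selected)))
  }
  invisible(x)
}

#' Write all pipeline intermediates and a JSON run report
#'
#' Emits `model.json`, `posteriors.tsv`, `merges.tsv`, `partition.tsv`,
#' `contingency.tsv`, one `deg/<pair>.tsv` and `selected/<pair>.tsv` per
#' dichotomy, and `report.json`; every reported number is recomputable from
#' the serialized intermediates.
#'
#' @param run An `aml_pipeline_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(run, out_dir) {
  stopifnot(inherits(run, "aml_pipeline_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "deg"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "selected"), showWarnings = FALSE)

  write_model(run$model, file.path(out_dir, "model.json"))
  write_expression_matrix(run$posteriors, file.path(out_dir, "posteriors.tsv"))
  hc <- run$hclust
  sz <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    cnt <- function(ch) if (ch < 0) 1L else sz[ch]
    sz[i] <- cnt(hc$merge[i, 1L]) + cnt(hc$merge[i, 2L])
  }
  merges <- data.frame(child_a = hc$merge[, 1L], child_b = hc$merge[, 2L],
                       height = hc$height, size = sz)
  utils::write.table(merges, file.path(out_dir, "merges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(run$partition$labels),
               cluster = paste0("G", run$partition$labels)),
    file.path(out_dir, "partition.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(as.data.frame.matrix(unclass(run$contingency)),
                     file.path(out_dir, "contingency.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  for (nm in names(run$tables)) {
    utils::write.table(run$tables[[nm]],
                       file.path(out_dir, "deg", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(run$selected[[nm]],
                       file.path(out_dir, "selected", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("abcdeg")),
    model = list(M = run$model$M, w = run$model$w, m = run$model$m,
                 s = run$model$s, loglik = run$model$loglik,
                 aic = run$model$aic, n_points = run$model$n_points),
    gof = list(chi2_stat = run$gof$chi2_stat, dof = run$gof$dof,
               p_value = run$gof$p_value),
    decision_border = if (!is.null(run$border)) {
      list(x_log = run$border$x_log, x_raw = run$border$x_raw)
    },
    clustering = list(K = run$partition$K,
                      sizes = as.integer(tabulate(run$partition$labels,
                                                  run$partition$K))),
    contingency = as.data.frame(run$contingency),
    abc = list(threshold = run$selection$threshold,
               keep = run$selection$keep,
               iterations = run$selection$iterations_run,
               display_threshold = run$display_threshold),
    selected_counts = vapply(run$selected, function(t) sum(t$selected), 0L),
    seeds = list(pipeline = run$config$seed,
                 simulation = if (!is.null(run$config$simulation)) {
                   run$config$simulation$seed
                 })
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(out_dir)
}
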