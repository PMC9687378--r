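# Reading and writing expression matrices, sample annotations and fitted
# mixture models in plain-text formats.

MODEL_FORMAT <- "abcdeg_gmm"
MODEL_VERSION <- 1L

#' Read a gene-by-sample expression matrix from delimited text
#'
#' The expected layout is a header row of sample identifiers and a first
#' column of gene symbols (genes in rows). Values must be numeric and
#' non-negative; missing values are not supported.
#'
#' @param path Path to a delimited text file.
#' @param samples_in_rows If `TRUE`, the file stores samples in rows and genes
#'   in columns; the returned matrix is transposed back to genes-by-samples.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return A numeric matrix with gene symbols as row names and sample
#'   identifiers as column names.
#' @export
read_expression_matrix <- function(path, samples_in_rows = FALSE, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected an identifier column plus at least one value column")
  ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]
  if (anyDuplicated(ids)) {
    stop("duplicate row identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(col_ids)) {
    stop("duplicate column identifiers: ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("malformed numeric cell at row '%s', column '%s': \"%s\"",
                 ids[bad[1L, 1L]], col_ids[bad[1L, 2L]],
                 body[bad[1L, , drop = FALSE]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)
    stop(sprintf("negative expression value at row '%s', column '%s'",
                 ids[bad[1L, 1L]], col_ids[bad[1L, 2L]]))
  }
  dimnames(num) <- list(ids, col_ids)
  m <- if (samples_in_rows) t(num) else num
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix as delimited text
#'
#' @param m Numeric matrix, genes in rows.
#' @param path Output file path.
#' @param samples_in_rows Write the transpose (samples in rows).
#' @param sep Field separator.
#' @param id_column Name of the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, samples_in_rows = FALSE,
                                    sep = "\t", id_column = "gene_id") {
  validate_expression_matrix(m)
  out <- if (samples_in_rows) t(m) else m
  df <- data.frame(rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- if (samples_in_rows) "sample_id" else id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Contract checks on the expression-matrix container.
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must carry gene row names and sample column names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
  if (anyNA(m)) stop("missing values are not supported")
  if (any(m < 0)) stop("negative expression values are not allowed")
  invisible(m)
}

#' Read a sample annotation table
#'
#' Requires columns `sample_id` and `label`; any further columns are carried
#' through untouched.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator.
#' @return A data frame keyed by `sample_id`.
#' @export
read_annotations <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (col in c("sample_id", "label")) {
    if (!col %in% colnames(df)) stop("missing required column '", col, "'")
  }
  df$sample_id <- as.character(df$sample_id)
  df$label <- as.character(df$label)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  df
}

#' Write a sample annotation table
#'
#' @param annotations Data frame with columns `sample_id` and `label`.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, sep = "\t") {
  for (col in c("sample_id", "label")) {
    if (!col %in% colnames(annotations)) stop("missing required column '", col, "'")
  }
  utils::write.table(annotations, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix to a gene whitelist
#'
#' Keeps the rows whose symbol appears in `whitelist`, preserving the input
#' gene order. Whitelist symbols absent from the matrix are reported via the
#' `"missing_symbols"` attribute of the result.
#'
#' @param m Expression matrix (genes in rows).
#' @param whitelist Character vector of gene symbols to keep.
#' @return The row-subset matrix; `attr(, "missing_symbols")` lists whitelist
#'   entries not found.
#' @export
filter_genes <- function(m, whitelist) {
  validate_expression_matrix(m)
  if (length(whitelist) == 0L) stop("whitelist must be non-empty")
  whitelist <- unique(as.character(whitelist))
  keep <- rownames(m) %in% whitelist
  if (!any(keep)) stop("no whitelist gene found in the expression matrix")
  out <- m[keep, , drop = FALSE]
  missing <- setdiff(whitelist, rownames(m))
  if (length(missing) > 0L) {
    message(length(missing), " whitelist symbol(s) absent from the matrix")
  }
  attr(out, "missing_symbols") <- missing
  out
}

#' Serialize a fitted Gaussian mixture model to JSON
#'
#' Stores weights, means and standard deviations at full double precision,
#' together with the log base, the decision border (if the model has at least
#' two components) and fit metadata, so that `read_model()` reproduces
#' identical posteriors.
#'
#' @param model A `gmm` object (see [fit_gmm()] / [gmm()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "gmm"))
  border <- tryCatch(decision_border(model)$x_log, error = function(e) NA_real_)
  obj <- list(
    format = MODEL_FORMAT,
    version = MODEL_VERSION,
    log_base = model$log_base,
    components = data.frame(w = model$w, m = model$m, s = model$s),
    decision_border = border,
    loglik = model$loglik,
    aic = model$aic,
    n_points = model$n_points
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a Gaussian mixture model from JSON
#'
#' @param path Path to a file written by [write_model()].
#' @return A `gmm` object.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse model file: ", conditionMessage(e))
                  })
  if (!identical(obj$format, MODEL_FORMAT)) {
    stop("not a mixture-model file (format field missing or unknown)")
  }
  if (!identical(as.integer(obj$version), MODEL_VERSION)) {
    stop("unsupported model file version: ", obj$version)
  }
  model <- gmm(w = obj$components$w, m = obj$components$m,
               s = obj$components$s, log_base = obj$log_base)
  model$loglik <- if (is.null(obj$loglik)) NA_real_ else obj$loglik
  model$aic <- if (is.null(obj$aic)) NA_real_ else obj$aic
  model$n_points <- if (is.null(obj$n_points)) NA_integer_ else obj$n_points
  model
}
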