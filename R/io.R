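# Tab-delimited readers/writers and versioned plain-text model serialization.

#' Read a tab-delimited expression matrix
#'
#' Expects gene identifiers in the first column and a header row of sample
#' identifiers. Rows sharing a gene identifier are collapsed by the
#' per-sample median (the usual summarization of multiple probes per gene),
#' with a message reporting the count.
#'
#' @param path Path to a tab-delimited text file.
#' @return Numeric matrix, genes by samples, with row and column names.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_ct("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, colClasses = "character",
                      fill = FALSE),
    error = function(e) stop_ct("cannot parse ", path, ": ",
                                conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 2)
    stop_ct("expression file ", path, " has no data rows or no sample columns")
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids))
    stop_ct("duplicate sample id(s): ",
            paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  genes <- df[[1]]
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, sample_ids))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop_ct("non-numeric value in ", path, " at data line ", bad)
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    message("collapsing ", n_dup, " duplicate gene row(s) by median")
    vals <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i)
      apply(vals[i, , drop = FALSE], 2, stats::median)))
    vals <- vals[unique(genes), , drop = FALSE]
  } else {
    rownames(vals) <- genes
  }
  vals
}

#' Read tab-delimited sample metadata
#'
#' Requires columns `sample_id`, `individual_id`, `study_id`, `condition`,
#' and `time_hours`. Times are wrapped once onto `[0, period)` (with a
#' warning) and scaled to `[0, 1)` in the added `time` column; values still
#' out of range after a single wrap are an error.
#'
#' @param path Path to a tab-delimited text file.
#' @param period Period in hours (default 24).
#' @return Data frame with the required columns plus scaled `time`.
#' @export
read_metadata <- function(path, period = 24) {
  if (!file.exists(path)) stop_ct("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "individual_id", "study_id", "condition",
                "time_hours")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_ct("metadata lacks column(s): ", paste(missing, collapse = ", "))
  t <- df$time_hours
  check_finite(t, "time_hours")
  out_of_range <- t < 0 | t >= period
  if (any(out_of_range)) {
    wrapped <- t[out_of_range] %% period
    if (any(t[out_of_range] < -period | t[out_of_range] >= 2 * period))
      stop_ct("time_hours outside [", -period, ", ", 2 * period,
              "): cannot wrap once onto [0, ", period, ")")
    warning("wrapped ", sum(out_of_range), " time(s) onto [0, ", period, ")")
    t[out_of_range] <- wrapped
  }
  df$time_hours <- t
  df$time <- t / period
  if (anyDuplicated(df$sample_id))
    stop_ct("duplicate sample_id(s) in metadata")
  df
}

#' Check that expression and metadata describe the same samples
#'
#' @param expr Genes-by-samples matrix.
#' @param meta Metadata data frame with `sample_id`.
#' @return Invisibly `TRUE`; errors on any cross-reference mismatch.
#' @export
validate_cohort <- function(expr, meta) {
  missing <- setdiff(as.character(meta$sample_id), colnames(expr))
  if (length(missing) > 0)
    stop_ct("metadata sample(s) absent from expression matrix: ",
            paste(utils::head(missing, 5), collapse = ", "))
  extra <- setdiff(colnames(expr), as.character(meta$sample_id))
  if (length(extra) > 0)
    stop_ct("expression sample(s) absent from metadata: ",
            paste(utils::head(extra, 5), collapse = ", "))
  invisible(TRUE)
}

#' Write an expression matrix / metadata table
#'
#' Tab-delimited, the same formats [read_expression()] and [read_metadata()]
#' consume.
#'
#' @param expr Genes-by-samples matrix.
#' @param meta Metadata data frame.
#' @param path Output path.
#' @name write_cohort_files
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_files
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

model_format <- "circatime-model"
model_version <- 1L

#' Serialize a predictor to a versioned JSON text file
#'
#' Stores the configuration, selected genes, loadings, component spline
#' coefficients and residual SDs at full numeric precision, so that a
#' restored predictor reproduces predictions to machine accuracy and writing
#' the same predictor twice yields byte-identical files. Training scores are
#' not stored; a restored predictor predicts but cannot be plotted.
#'
#' @param object A `circatime` predictor.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "circatime"))
  # flat column-major vectors with explicit dimensions: JSON round-trips
  # them without any container-shape ambiguity
  doc <- list(format = model_format, version = model_version,
              config = object$config,
              gene_ids = object$spc_model$gene_ids,
              loadings = as.numeric(object$spc_model$loadings),
              singular_values = object$spc_model$singular_values,
              spline_n_knots = object$spc_splines[[1]]$n_knots,
              spline_coefficients = as.numeric(
                vapply(object$spc_splines, function(s) s$coefficients,
                       numeric(object$spc_splines[[1]]$n_knots))),
              spline_rmse = vapply(object$spc_splines,
                                   function(s) s$residual_rmse, numeric(1)),
              spc_sd = object$spc_sd,
              n_samples = object$n_samples,
              dropped_genes = object$dropped_genes)
  # 17 significant digits: IEEE doubles round-trip exactly
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Restore a predictor from a serialized model file
#'
#' @param path Path written by [write_model()].
#' @return A `circatime` predictor (without training scores).
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, model_format))
    stop_ct(path, " is not a ", model_format, " file")
  if (doc$version > model_version)
    stop_ct("model version ", doc$version, " is newer than supported (",
            model_version, ")")
  nSPC <- doc$config$nSPC
  loadings <- matrix(doc$loadings, ncol = nSPC,
                     dimnames = list(doc$gene_ids,
                                     paste0("SPC", seq_len(nSPC))))
  model <- structure(list(loadings = loadings, gene_ids = doc$gene_ids,
                          singular_values = doc$singular_values,
                          sumabsv = doc$config$sumabsv, nSPC = nSPC),
                     class = "spc_model")
  coefs <- matrix(doc$spline_coefficients, nrow = doc$spline_n_knots)
  splines <- lapply(seq_len(nSPC), function(k)
    new_periodic_spline(doc$spline_n_knots, coefs[, k],
                        doc$spline_rmse[k], doc$n_samples))
  structure(list(spc_model = model, spc_splines = splines,
                 spc_sd = as.numeric(doc$spc_sd), config = doc$config,
                 dropped_genes = as.character(unlist(doc$dropped_genes)),
                 train_times = NULL, train_scores = NULL,
                 train_sample_ids = NULL, n_samples = doc$n_samples,
                 call = NULL),
            class = "circatime")
}

#' Write per-sample predictions or CV records
#'
#' @param records Data frame of predictions (e.g. `ct_cv$records`).
#' @param path Output path (tab-delimited).
#' @export
write_predictions <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
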