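# Personalized predictors trained under universal guidance: a universal
# predictor's feature selection shrinks an individual's tiny training set to
# a handful of informative genes, making personal training feasible; the
# universal and personal predictions are then combined by circular mean.

#' Shrink a personal training set to the universal predictor's genes
#'
#' Restricts the expression matrix to one individual's samples and to exactly
#' the genes with nonzero loading in the guiding universal predictor. With
#' only a few samples per individual, training on the full transcriptome
#' overfits hopelessly; guidance exploits the universal predictor's feature
#' selection to make a personal fit possible.
#'
#' @param expr Genes-by-samples expression matrix (row/column names required).
#' @param meta Sample metadata with `sample_id`, `individual_id`, `time`.
#' @param universal A `circatime` predictor providing the gene filter.
#' @param individual_id The individual whose samples form the personal set.
#' @return A list of class `guided_set` with fields `expr` (universal genes
#'   by the individual's samples) and `meta` (that individual's rows).
#' @export
shrink_training_set <- function(expr, meta, universal, individual_id) {
  stopifnot(inherits(universal, "circatime"))
  genes <- predictor_genes(universal)
  if (length(genes) == 0) stop_ct("universal predictor selected no genes")
  meta <- as.data.frame(meta)
  rows <- meta$individual_id == individual_id
  if (!any(rows)) stop_ct("individual '", individual_id, "' not in metadata")
  m <- meta[rows, , drop = FALSE]
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0)
    stop_ct("expression matrix lacks universal gene(s): ",
            paste(utils::head(missing, 5), collapse = ", "))
  structure(list(expr = expr[genes, as.character(m$sample_id), drop = FALSE],
                 meta = m),
            class = "guided_set")
}

#' Train a personal predictor on a shrunken training set
#'
#' Runs the standard training pipeline on one individual's samples restricted
#' to the universal predictor's genes. The personal predictor may select a
#' further subset of the guiding genes. Training requires at least
#' `min_samples` samples at 3 or more distinct times; below 7 samples a
#' warning flags that accuracy is not expected to be robust.
#'
#' @param guided A `guided_set` from [shrink_training_set()].
#' @param sumabsv,nSPC As in [circatime()]; defaults match the universal
#'   predictor's usual settings.
#' @param min_samples Hard floor on the personal sample count (default 4).
#' @param ... Passed on to [circatime()].
#' @return A `circatime` predictor whose genes are a subset of the guide's.
#' @export
train_personal <- function(guided, sumabsv = 2, nSPC = 2, min_samples = 4,
                           ...) {
  stopifnot(inherits(guided, "guided_set"))
  n <- ncol(guided$expr)
  if (n < min_samples)
    stop_ct("too few personal samples: ", n, " < ", min_samples)
  if (length(unique(round(guided$meta$time, 10))) < 3)
    stop_ct("personal training needs at least 3 distinct sample times")
  if (n < 7)
    warning("only ", n, " personal samples; accuracy is not robust below 7")
  circatime(guided$expr, guided$meta, sumabsv = sumabsv, nSPC = nSPC, ...)
}

#' Universal + personal ensemble prediction
#'
#' Predicts a sample's time with the universal and the personal predictor
#' separately and combines the two by circular mean.
#'
#' @param universal,personal `circatime` predictors.
#' @param x Named expression vector (or one-column matrix) covering both
#'   predictors' genes.
#' @return A `ct_prediction` with source `"personal"`; errors if the two
#'   predictions are antipodal (degenerate mean).
#' @export
personal_ensemble <- function(universal, personal, x) {
  tu <- unname(predict(universal, x))
  tp <- unname(predict(personal, x))
  p <- ensemble_predict_circmean(c(tu, tp))
  p$source <- "personal"
  p$members <- c(universal = tu, personal = tp)
  p
}
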