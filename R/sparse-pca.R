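# Sparse principal components of the discretized, scaled spline-fit matrix,
# via rank-one penalized matrix decomposition (PMD) with an L1 constraint on
# the gene-loading vector and deflation between components.

#' Center and noise-scale a discretized fit matrix
#'
#' Prepares the matrix decomposed into sparse components: each gene's
#' discretized spline profile (a column) is centered to mean zero and divided
#' by the spline's residual RMSE (floored). A gene with a large fitted range
#' and small residual noise -- i.e. high signal-to-noise ratio -- therefore
#' has large magnitude and is favored by the component selection.
#'
#' @param discretized Matrix, `n_time` rows by genes columns, of discretized
#'   spline fits.
#' @param rmse Per-gene residual RMSE (length `ncol(discretized)`).
#' @param floor Lower bound applied to `rmse` so noiseless fits do not blow
#'   up the scale (default 1e-6).
#' @return Matrix of the same shape, columns centered and scaled.
#' @export
scale_fit_matrix <- function(discretized, rmse, floor = 1e-6) {
  discretized <- as.matrix(discretized)
  if (length(rmse) != ncol(discretized))
    stop_ct("rmse must have one entry per gene column")
  if (any(rmse < 0)) stop_ct("rmse must be non-negative")
  centered <- sweep(discretized, 2, colMeans(discretized), "-")
  sweep(centered, 2, pmax(rmse, floor), "/")
}

soft_threshold <- function(a, delta) sign(a) * pmax(abs(a) - delta, 0)

# Project a vector onto {v : ||v||_2 = 1, ||v||_1 <= c} along the
# soft-threshold path: v = S(a, delta)/||S(a, delta)||_2 with the smallest
# delta >= 0 satisfying the L1 budget, found by bisection.
l1_unit <- function(a, c) {
  v <- a / sqrt(sum(a^2))
  if (sum(abs(v)) <= c) return(v)
  lo <- 0
  hi <- max(abs(a))
  for (i in seq_len(80)) {
    mid <- (lo + hi) / 2
    s <- soft_threshold(a, mid)
    ns <- sqrt(sum(s^2))
    if (ns == 0 || sum(abs(s)) / ns > c) lo <- mid else hi <- mid
  }
  s <- soft_threshold(a, hi)
  s / sqrt(sum(s^2))
}

#' Rank-one penalized matrix decomposition
#'
#' Finds unit vectors `u` (rows) and `v` (columns, with `||v||_1 <=
#' sumabsv`) maximizing `t(u) %*% X %*% v` by alternating updates:
#' `u <- X v / ||X v||` and `v <- S(X'u, delta) / ||.||` where the
#' soft-threshold `delta` is the smallest value meeting the L1 budget
#' (bisection). `v` is initialized at the leading right singular vector of
#' `X`, so the procedure is deterministic; the sign convention makes the
#' largest-magnitude loading positive. With a slack budget
#' (`sumabsv >= sqrt(ncol(X))`) the result coincides with the leading
#' singular triplet.
#'
#' @param X Numeric matrix (here: time points by genes), finite, not all zero.
#' @param sumabsv L1 budget on `v`, at least 1.
#' @param max_iter Maximum alternating iterations (default 200).
#' @param tol Convergence tolerance on the change in `v` (default 1e-7).
#' @return List with unit vectors `u` and `v`, the value `d = t(u) X v >= 0`,
#'   the number of `iterations`, logical `converged`, and the per-iteration
#'   `objective` trace (non-decreasing).
#' @export
rank_one_pmd <- function(X, sumabsv, max_iter = 200, tol = 1e-7) {
  X <- as.matrix(X)
  check_finite(X, "X")
  if (all(X == 0)) stop_ct("X is identically zero")
  if (sumabsv < 1) stop_ct("sumabsv must be at least 1")
  v <- svd(X, nu = 0, nv = 1)$v[, 1]
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    xv <- drop(X %*% v)
    u <- xv / sqrt(sum(xv^2))
    v_new <- l1_unit(drop(crossprod(X, u)), sumabsv)
    objective <- c(objective, sum(u * drop(X %*% v_new)))
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      converged <- TRUE
      break
    }
    v <- v_new
  }
  if (!converged)
    warning("rank_one_pmd did not converge in ", max_iter,
            " iterations; returning best iterate")
  xv <- drop(X %*% v)
  d <- sqrt(sum(xv^2))
  u <- if (d > 0) xv / d else xv
  imax <- which.max(abs(v))
  if (v[imax] < 0) {
    v <- -v
    u <- -u
  }
  v <- v + 0  # collapse IEEE negative zeros left by soft-thresholding
  list(u = u, v = v, d = d, iterations = iter, converged = converged,
       objective = objective)
}

#' Compute sparse principal components
#'
#' Extracts `nSPC` components by repeated [rank_one_pmd()] with deflation
#' `X <- X - d u v'` between components. Components are not forced
#' orthogonal and the `d` sequence is not guaranteed monotone.
#'
#' @param X_scaled Centered, noise-scaled fit matrix (time points by genes),
#'   as produced by [scale_fit_matrix()].
#' @param sumabsv L1 budget per component (default 2).
#' @param nSPC Number of components (default 2); must not exceed the matrix
#'   rank.
#' @param gene_ids Optional column identifiers; defaults to column names.
#' @return An object of class `spc_model`: sparse `loadings` (genes by
#'   `nSPC`), `gene_ids`, `singular_values` (`d` per component), `sumabsv`,
#'   `nSPC`.
#' @export
compute_spcs <- function(X_scaled, sumabsv = 2, nSPC = 2,
                         gene_ids = colnames(X_scaled)) {
  X <- as.matrix(X_scaled)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(X)))
  if (nSPC < 1) stop_ct("nSPC must be at least 1")
  rank <- sum(svd(X, nu = 0, nv = 0)$d > max(dim(X)) * 1e-12 * max(abs(X)))
  if (nSPC > rank)
    stop_ct("nSPC = ", nSPC, " exceeds the matrix rank (", rank, ")")
  loadings <- matrix(0, ncol(X), nSPC,
                     dimnames = list(gene_ids, paste0("SPC", seq_len(nSPC))))
  d <- numeric(nSPC)
  for (k in seq_len(nSPC)) {
    r <- rank_one_pmd(X, sumabsv)
    loadings[, k] <- r$v
    d[k] <- r$d
    X <- X - r$d * tcrossprod(r$u, r$v)
  }
  structure(list(loadings = loadings, gene_ids = gene_ids,
                 singular_values = d, sumabsv = sumabsv, nSPC = nSPC),
            class = "spc_model")
}

#' @export
print.spc_model <- function(x, ...) {
  cat("Sparse PC model:", x$nSPC, "components over", length(x$gene_ids),
      "genes;", sum(rowSums(x$loadings != 0) > 0), "genes with nonzero loading",
      "(sumabsv =", paste0(format(x$sumabsv), ")"), "\n")
  invisible(x)
}

#' Project expression onto sparse components
#'
#' The score of a component in a sample is the dot product of the component's
#' gene loadings with the sample's (log-scale) expression values; samples are
#' not re-scaled at projection time.
#'
#' @param x Named numeric vector of one sample's expression, or a matrix of
#'   genes by samples with row names. Must cover every gene in the model.
#' @param model An `spc_model`.
#' @return A matrix of `nSPC` rows by samples (a one-column matrix for a
#'   vector input).
#' @export
project_spcs <- function(x, model) {
  stopifnot(inherits(model, "spc_model"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), NULL))
  if (is.null(rownames(x)))
    stop_ct("expression input must carry gene identifiers as (row) names")
  missing <- setdiff(model$gene_ids, rownames(x))
  if (length(missing) > 0)
    stop_ct("sample is missing ", length(missing), " model gene(s): ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  crossprod(model$loadings, x[model$gene_ids, , drop = FALSE])
}
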