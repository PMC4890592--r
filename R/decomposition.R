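#' Principal components analysis of an expression matrix
#'
#' Fits PCA with samples as observations and genes as variables: each gene is
#' centered by its mean across samples, no unit-variance scaling (the natural
#' treatment of log2 RMA intensities, where variance carries meaning). The
#' fit uses the singular value decomposition of the centered matrix, which is
#' stable in the usual regime of many more genes than samples.
#'
#' A deterministic sign convention is applied so results are reproducible:
#' each loading column is flipped so that its largest-magnitude entry is
#' positive (first index wins ties).
#'
#' @param x expression matrix (genes x samples), see [as_expression()].
#' @param k number of components to retain, between 1 and
#'   `min(n_samples - 1, n_genes)`.
#' @return an object of class `pca_model`: a list with
#'   \describe{
#'     \item{center}{per-gene mean vector (length n_genes).}
#'     \item{loadings}{genes x k matrix of unit-norm, mutually orthogonal
#'       loading vectors (columns `PC1..PCk`).}
#'     \item{scores}{samples x k matrix of sample scores.}
#'     \item{explained_fraction}{fraction of total gene-centered variance
#'       explained by each retained component.}
#'     \item{eigenvalues}{all sample-covariance eigenvalues (not just the
#'       retained k).}
#'     \item{total_variance}{sum of per-gene variances.}
#'     \item{k, gene_ids, sample_ids}{bookkeeping.}
#'   }
#' @examples
#' x <- simulate_expression(synthetic_preset("compendium", n_genes = 200,
#'                                           scale = 0.2))$expression
#' fit <- fit_pca(x, k = 3)
#' fit$explained_fraction
#' @export
fit_pca <- function(x, k) {
  x <- as_expression(x)
  n_genes <- nrow(x)
  n_samples <- ncol(x)
  k_max <- min(n_samples - 1L, n_genes)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a single positive integer")
  if (k > k_max)
    stop(sprintf("k = %d exceeds the maximum of min(n_samples - 1, n_genes) = %d",
                 as.integer(k), k_max))
  center <- rowMeans(x)
  xc <- x - center
  total_var <- sum(xc^2) / (n_samples - 1)
  if (total_var == 0)
    stop("constant matrix: no variance to decompose")
  sv <- svd(xc, nu = k, nv = 0)
  loadings <- flip_signs(sv$u)
  scores <- crossprod(xc, loadings)
  eigenvalues <- sv$d^2 / (n_samples - 1)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  rownames(loadings) <- rownames(x)
  rownames(scores) <- colnames(x)
  structure(list(
    center = center,
    loadings = loadings,
    scores = scores,
    explained_fraction = eigenvalues[seq_len(k)] / total_var,
    eigenvalues = eigenvalues,
    total_variance = total_var,
    k = as.integer(k),
    gene_ids = rownames(x),
    sample_ids = colnames(x)
  ), class = "pca_model")
}

# Flip each column so its largest-|.| entry is positive; which.max takes the
# first maximum, giving a deterministic tie-break.
flip_signs <- function(u) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  u
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d genes x %d samples, k = %d\n",
              length(x$gene_ids), length(x$sample_ids), x$k))
  cat("explained variance fractions:",
      paste(sprintf("%.3f", x$explained_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Split an expression matrix into projected and residual parts
#'
#' Decomposes the gene-centered matrix into the rank-k reconstruction from
#' the first k principal components (the "projected" matrix, which carries
#' the information in those components) and the orthogonal remainder (the
#' "residual" matrix, which carries components k+1 and higher). Both parts
#' have the same shape as the input and satisfy, to numerical tolerance,
#' `projected + residual == centered input` and trace orthogonality.
#'
#' @inheritParams fit_pca
#' @param model a `pca_model` fitted on the same gene set as `x`.
#' @param k number of components to project out, `0 <= k <= model$k`
#'   (defaults to `model$k`; `k = 0` gives an all-zero projected matrix).
#' @return an object of class `pca_decomposition`: list with `projected` and
#'   `residual` (genes x samples matrices) and `k`.
#' @examples
#' x <- simulate_expression(synthetic_preset("compendium", n_genes = 200,
#'                                           scale = 0.2))$expression
#' dec <- decompose_expression(x, fit_pca(x, 5), k = 3)
#' max(abs(dec$projected + dec$residual - (x - rowMeans(x))))
#' @export
decompose_expression <- function(x, model, k = model$k) {
  x <- as_expression(x)
  stopifnot(inherits(model, "pca_model"))
  if (!identical(rownames(x), model$gene_ids))
    stop("gene set of x does not match the fitted model")
  if (k < 0 || k > model$k)
    stop(sprintf("k must be between 0 and the %d fitted components", model$k))
  xc <- x - model$center
  if (k == 0) {
    projected <- xc * 0
  } else {
    l <- model$loadings[, seq_len(k), drop = FALSE]
    projected <- l %*% crossprod(l, xc)
  }
  residual <- xc - projected
  structure(list(projected = projected, residual = residual,
                 k = as.integer(k)),
            class = "pca_decomposition")
}

#' Project new samples onto foreign PCA loadings
#'
#' Scores samples of a new dataset against loading vectors obtained
#' elsewhere (e.g. from a reference compendium on another platform, after
#' identifier translation with [map_genes()]). Each new sample is centered by
#' the new dataset's own per-gene means — not the reference's — and scored by
#' scalar products with the loading columns.
#'
#' @param x_new expression matrix whose rows are aligned with
#'   `foreign_loadings` (same genes, same order).
#' @param foreign_loadings genes x k loading matrix.
#' @return samples x k score matrix.
#' @export
project_external <- function(x_new, foreign_loadings) {
  x_new <- as_expression(x_new)
  foreign_loadings <- as.matrix(foreign_loadings)
  if (nrow(x_new) == 0L || nrow(foreign_loadings) == 0L)
    stop("empty gene set")
  if (nrow(x_new) != nrow(foreign_loadings))
    stop("gene sets not aligned: ", nrow(x_new), " rows vs ",
         nrow(foreign_loadings), " loading rows; align with map_genes() first")
  if (!is.null(rownames(foreign_loadings)) &&
      !identical(rownames(x_new), rownames(foreign_loadings)))
    stop("gene identifiers of x_new and foreign_loadings differ")
  scores <- crossprod(x_new - rowMeans(x_new), foreign_loadings)
  rownames(scores) <- colnames(x_new)
  scores
}

#' Linear-regression similarity of loading vectors
#'
#' Quantifies how well one gene-space direction (e.g. a principal-component
#' loading of one dataset) is explained by a set of directions from another
#' dataset: ordinary least squares of `target` on the predictor columns plus
#' an intercept, reporting R-squared. Used to compare the spaces spanned by
#' the leading components of two compendia.
#'
#' @param target numeric vector over genes.
#' @param predictors genes x m matrix, rows aligned with `target`.
#' @return R-squared in `[0, 1]`.
#' @export
loading_r2 <- function(target, predictors) {
  predictors <- as.matrix(predictors)
  if (length(target) != nrow(predictors))
    stop("target and predictors must be aligned on a common gene set")
  if (length(target) < ncol(predictors) + 1L)
    stop("underdetermined: fewer genes than predictors + intercept")
  fit <- stats::lm.fit(cbind(1, predictors), target)
  tss <- sum((target - mean(target))^2)
  if (tss == 0) stop("constant target vector")
  max(0, min(1, 1 - sum(fit$residuals^2) / tss))
}

#' Export a PCA model as tab-separated tables
#'
#' Writes `<prefix>_loadings.tsv` (gene_id + PC columns), `<prefix>_scores.tsv`
#' (sample_id + PC columns), and `<prefix>_summary.tsv` (center and explained
#' variance fractions).
#'
#' @param model a `pca_model`.
#' @param prefix output path prefix.
#' @return the three file paths, invisibly.
#' @export
write_pca <- function(model, prefix) {
  stopifnot(inherits(model, "pca_model"))
  paths <- paste0(prefix, c("_loadings.tsv", "_scores.tsv", "_summary.tsv"))
  utils::write.table(
    data.frame(gene_id = model$gene_ids, model$loadings, check.names = FALSE),
    paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = model$sample_ids, model$scores, check.names = FALSE),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(component = paste0("PC", seq_len(model$k)),
               explained_fraction = model$explained_fraction),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
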