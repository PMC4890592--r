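#' PCA on a residual sample subset
#'
#' Whole-dataset PCA on the residual matrix merely recovers components
#' k+1, k+2, ... of the original decomposition. Restricting the residual to
#' a sample subset before fitting, however, can reveal directions that are
#' invisible to the whole-dataset analysis — subtype structure within one
#' tissue or disease group. Genes are re-centered within the subset (the
#' residual has near-zero global gene means but not zero subset means).
#'
#' @param residual genes x samples residual matrix (e.g.
#'   `decompose_expression(...)$residual`).
#' @param subset character vector of sample ids (or column indices) to keep;
#'   must contain at least `m + 1` samples.
#' @param m number of residual subset components to fit.
#' @param parent_k number of components that were removed from the parent
#'   dataset before subsetting (bookkeeping only).
#' @return object of class `subset_pca`: list with `subset_sample_ids`,
#'   `residual_model` (a `pca_model` on the subset) and `parent_k`.
#' @export
residual_subset_pca <- function(residual, subset, m, parent_k = NA_integer_) {
  if (is.numeric(subset)) subset <- colnames(residual)[subset]
  missing_ids <- setdiff(subset, colnames(residual))
  if (length(missing_ids))
    stop("samples not in residual matrix: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  if (length(subset) < m + 1)
    stop("subset of ", length(subset), " samples is too small for m = ", m)
  model <- fit_pca(residual[, subset, drop = FALSE], k = m)
  structure(list(subset_sample_ids = subset, residual_model = model,
                 parent_k = as.integer(parent_k)),
            class = "subset_pca")
}

#' Project external data onto residual subset components
#'
#' Validates subset structure on an independent cohort: each validation
#' sample is centered by the validation dataset's own per-gene means, the
#' projection onto the parent components is subtracted, and the remaining
#' residual is scored against the residual subset loadings by scalar
#' products. Gene spaces must be aligned beforehand (see [map_genes()]).
#'
#' @param x_val validation expression matrix, rows aligned with the parent
#'   loadings and the subset model.
#' @param parent_loadings genes x k loading matrix of the parent model.
#' @param subset_model a `subset_pca` object.
#' @param m number of subset components to score (default: all fitted).
#' @return samples x m score matrix.
#' @export
validate_on_external <- function(x_val, parent_loadings, subset_model,
                                 m = subset_model$residual_model$k) {
  x_val <- as_expression(x_val)
  stopifnot(inherits(subset_model, "subset_pca"))
  sub_load <- subset_model$residual_model$loadings[, seq_len(m), drop = FALSE]
  if (nrow(x_val) == 0L) stop("empty gene set")
  if (nrow(x_val) != nrow(sub_load) ||
      (!is.null(parent_loadings) && nrow(x_val) != nrow(parent_loadings)))
    stop("gene sets not aligned; align with map_genes() first")
  xc <- x_val - rowMeans(x_val)
  if (!is.null(parent_loadings) && ncol(parent_loadings) > 0) {
    p <- as.matrix(parent_loadings)
    xc <- xc - p %*% crossprod(p, xc)
  }
  scores <- crossprod(xc, sub_load)
  rownames(scores) <- colnames(x_val)
  scores
}

#' Proportion-matched downsampling of annotated samples
#'
#' Draws a reproducible subset whose per-group sizes match requested counts:
#' groups in `keep_all` are retained in full, every other requested group
#' contributes a simple random sample without replacement of the requested
#' size. Candidates are sorted by sample id before drawing, so the result
#' depends only on the annotation content and the seed, not on row order.
#'
#' @param annotation sample annotation, see [as_annotation()].
#' @param target_counts named integer vector: requested number of samples
#'   per group label.
#' @param keep_all character vector of group labels kept in full.
#' @param seed integer seed for the draw.
#' @param group_col annotation column holding the labels (default
#'   `"large_scale_group"`, the coarse categories that dominate compendium
#'   composition).
#' @return sorted character vector of selected sample ids.
#' @export
downsample_to_proportions <- function(annotation, target_counts,
                                      keep_all = character(), seed = 1,
                                      group_col = "large_scale_group") {
  annotation <- as_annotation(annotation)
  if (!group_col %in% colnames(annotation))
    stop("annotation has no column '", group_col, "'")
  grp <- annotation[[group_col]]
  chosen <- sort(annotation$sample_id[grp %in% keep_all])
  with_seed(seed, {
    for (lab in names(target_counts)) {
      pool <- sort(annotation$sample_id[grp == lab])
      want <- target_counts[[lab]]
      if (want > length(pool))
        stop(sprintf("group '%s' has only %d samples, %d requested",
                     lab, length(pool), want))
      chosen <- c(chosen, sample(pool, want))
    }
  })
  sort(unique(chosen))
}

#' Sample-size perturbation scan of a target group
#'
#' Measures how the representation of one group in the leading principal
#' components depends on how many of its samples the dataset contains. For
#' each fraction f, all non-target samples are kept, a random `ceiling(f *
#' n_target)` subset of target samples is added, PCA is fitted, and two
#' alignment measures against the target-group indicator are recorded over
#' the first `n_top_pcs` components: the maximum absolute point-biserial
#' correlation between scores and the indicator, and the maximum absolute
#' cosine between a loading vector and the normalized target-group
#' signature. A minority group below its detection threshold scores near
#' zero on both; above the threshold one of the top components locks onto
#' it.
#'
#' @param x expression matrix (genes x samples).
#' @param annotation sample annotation.
#' @param target_group group label whose sample count is varied.
#' @param fractions numeric vector in `(0, 1]`.
#' @param n_top_pcs number of leading components examined (default 4).
#' @param seed integer seed; each fraction uses a derived child seed.
#' @param group_col annotation column holding the labels.
#' @return object of class `sample_size_scan`: data frame with columns
#'   `fraction`, `n_target`, `alignment`, `aligned_pc`, `cosine`,
#'   `cosine_pc`, plus attributes `target_group`, `n_top_pcs`, `seed`.
#' @export
sample_size_scan <- function(x, annotation, target_group, fractions,
                             n_top_pcs = 4, seed = 1, group_col = "group") {
  x <- as_expression(x)
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  targets <- sort(intersect(group_members(annotation, target_group, group_col),
                            colnames(x)))
  if (length(targets) == 0L) stop("target group has no samples in x")
  others <- setdiff(colnames(x), targets)
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    n_keep <- ceiling(f * length(targets))
    if (n_keep == 0L) stop("fraction ", f, " yields 0 target samples")
    keep <- with_seed(child_seed(seed, i), sample(targets, n_keep))
    cols <- c(others, keep)
    xi <- x[, cols, drop = FALSE]
    fit <- fit_pca(xi, k = min(n_top_pcs, ncol(xi) - 1L, nrow(xi)))
    ind <- as.numeric(cols %in% targets)
    if (stats::var(ind) == 0) {
      align <- 0; pc <- 0L; cosine <- 0; cpc <- 0L
    } else {
      r <- abs(suppressWarnings(stats::cor(fit$scores, ind)))
      r[is.na(r)] <- 0
      align <- max(r); pc <- which.max(r)
      sig <- rowMeans(xi[, cols %in% targets, drop = FALSE]) - rowMeans(xi)
      sig <- sig / sqrt(sum(sig^2))
      cr <- abs(drop(crossprod(fit$loadings, sig)))
      cosine <- max(cr); cpc <- which.max(cr)
    }
    data.frame(fraction = f, n_target = n_keep, alignment = align,
               aligned_pc = as.integer(pc), cosine = cosine,
               cosine_pc = as.integer(cpc))
  })
  out <- do.call(rbind, rows)
  attr(out, "target_group") <- target_group
  attr(out, "n_top_pcs") <- n_top_pcs
  attr(out, "seed") <- seed
  class(out) <- c("sample_size_scan", class(out))
  out
}
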