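#' Group expression signatures
#'
#' A group's signature is the vector pointing from the overall mean of the
#' dataset to the group's mean expression, one column per qualifying group.
#' Applied to a residual matrix (whose overall mean is numerically zero) the
#' columns are simply the residual group means.
#'
#' @param x numeric matrix, genes x samples (original, projected or residual).
#' @param annotation sample annotation, see [as_annotation()].
#' @param min_group_size smallest group size admitted (default 10, the usual
#'   filter for stable group means).
#' @param group_col annotation column holding the group labels.
#' @return object of class `signature_set`: list with `vectors` (genes x
#'   n_groups matrix), `group_labels`, `group_sizes`.
#' @export
group_signatures <- function(x, annotation, min_group_size = 10,
                             group_col = "group") {
  annotation <- as_annotation(annotation)
  annotation <- annotation[annotation$sample_id %in% colnames(x), ]
  sizes <- table(annotation[[group_col]])
  labels <- names(sizes)[sizes >= min_group_size]
  if (length(labels) == 0L)
    stop("no group with at least ", min_group_size, " samples")
  overall <- rowMeans(x)
  vectors <- vapply(labels, function(lab) {
    ids <- annotation$sample_id[annotation[[group_col]] == lab]
    rowMeans(x[, ids, drop = FALSE]) - overall
  }, numeric(nrow(x)))
  dimnames(vectors) <- list(rownames(x), labels)
  structure(list(vectors = vectors, group_labels = labels,
                 group_sizes = as.integer(sizes[labels])),
            class = "signature_set")
}

#' Signature correlation matrix with clustering order
#'
#' Pearson correlations between all group signatures, with rows and columns
#' ordered by complete-linkage hierarchical clustering on euclidean
#' distances between signatures. The leaf order of `stats::hclust` is
#' deterministic for a fixed input (ties resolved by original index), so the
#' heatmap ordering is reproducible.
#'
#' @param s a `signature_set` from [group_signatures()] with at least 2
#'   signatures.
#' @return list of class `signature_correlation` with `correlation` (the
#'   matrix, rows/columns in clustering leaf order), `order` (leaf order as
#'   labels) and `hclust` (the clustering tree).
#' @export
signature_correlation <- function(s) {
  stopifnot(inherits(s, "signature_set"))
  v <- s$vectors
  if (ncol(v) < 2) stop("need at least 2 signatures")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("constant signature for group(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  co <- stats::cor(v)
  hc <- stats::hclust(stats::dist(t(v)), method = "complete")
  ord <- hc$order
  structure(list(correlation = co[ord, ord, drop = FALSE],
                 order = colnames(v)[ord], hclust = hc),
            class = "signature_correlation")
}

#' Mean within-group sample correlation
#'
#' For each qualifying group, the mean Pearson correlation over all
#' unordered pairs of its samples. In the original space samples are first
#' referenced to the overall dataset mean per gene (`center = TRUE`), which
#' makes the statistic comparable to the residual-space version where the
#' reference is already (numerically) zero; pass a residual matrix with
#' `center = TRUE` harmlessly or `FALSE` to use it as-is.
#'
#' @inheritParams group_signatures
#' @param center subtract the overall per-gene mean before correlating.
#' @return data frame with columns `group`, `n`, `mean_correlation`.
#' @export
within_group_correlation <- function(x, annotation, min_group_size = 10,
                                     group_col = "group", center = TRUE) {
  annotation <- as_annotation(annotation)
  annotation <- annotation[annotation$sample_id %in% colnames(x), ]
  sizes <- table(annotation[[group_col]])
  labels <- names(sizes)[sizes >= min_group_size]
  if (length(labels) == 0L)
    stop("no group with at least ", min_group_size, " samples")
  xr <- if (center) x - rowMeans(x) else x
  res <- lapply(labels, function(lab) {
    ids <- annotation$sample_id[annotation[[group_col]] == lab]
    co <- stats::cor(xr[, ids, drop = FALSE])
    data.frame(group = lab, n = length(ids),
               mean_correlation = mean(co[upper.tri(co)]))
  })
  do.call(rbind, res)
}
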