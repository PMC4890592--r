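#' Predefined biological direction sets
#'
#' A direction set is a genes x directions matrix of annotated biological
#' axes (for example tissue-specific expression patterns derived from a
#' reference atlas) onto which centered sample deviations are projected.
#' Columns are normalized to unit euclidean norm when loaded; an all-zero
#' column is an error.
#'
#' @param path tab-separated file: header `gene_id` plus one column per
#'   direction, one row per gene.
#' @param vectors numeric genes x directions matrix for `as_directions()`.
#' @return object of class `direction_set`: list with `vectors` (unit-norm
#'   columns) and `direction_labels`.
#' @export
load_directions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, fileEncoding = "UTF-8")
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- tab[[1]]
  as_directions(v)
}

#' @rdname load_directions
#' @export
as_directions <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (is.null(colnames(vectors)) || anyDuplicated(colnames(vectors)))
    stop("directions must have unique column labels")
  norms <- sqrt(colSums(vectors^2))
  if (any(norms == 0))
    stop("zero-norm direction(s): ",
         paste(colnames(vectors)[norms == 0], collapse = ", "))
  structure(list(vectors = sweep(vectors, 2, norms, "/"),
                 direction_labels = colnames(vectors)),
            class = "direction_set")
}

#' Score samples against a direction set
#'
#' Each sample's deviation from the overall dataset mean is projected onto
#' every direction by scalar product over the common gene set, yielding one
#' score per sample and direction (a simplified linear variant of
#' atlas-based physiological scoring). Directions are re-normalized over the
#' common gene set so scores are comparable across directions.
#'
#' @param x expression matrix (genes x samples).
#' @param d a `direction_set`.
#' @return samples x n_directions score matrix.
#' @export
score_samples <- function(x, d) {
  x <- as_expression(x)
  stopifnot(inherits(d, "direction_set"))
  common <- intersect(rownames(x), rownames(d$vectors))
  if (length(common) == 0L) stop("empty gene intersection")
  v <- d$vectors[common, , drop = FALSE]
  norms <- sqrt(colSums(v^2))
  if (any(norms == 0))
    stop("direction(s) vanish on the common gene set: ",
         paste(colnames(v)[norms == 0], collapse = ", "))
  v <- sweep(v, 2, norms, "/")
  xc <- x[common, , drop = FALSE] - rowMeans(x[common, , drop = FALSE])
  scores <- crossprod(xc, v)
  rownames(scores) <- colnames(x)
  scores
}

#' Flag samples whose score contradicts their annotation
#'
#' Mislabel screening: among samples annotated with a given label, flags
#' those whose score on the label's own direction lies more than
#' `z_threshold` robust z-units (median/MAD) below the label's median score.
#' With `z_threshold = 0` everything strictly below the median is flagged
#' (degenerate but well defined). If the MAD is zero, any sample strictly
#' below the median is infinitely many robust z-units away and is flagged.
#'
#' @param scores samples x directions score matrix from [score_samples()].
#' @param annotation sample annotation.
#' @param label annotation group label selecting the samples to screen (at
#'   least 3 required).
#' @param score_label direction column to screen against (defaults to
#'   `label`).
#' @param z_threshold robust z cutoff (default 3).
#' @param group_col annotation column holding the labels.
#' @return data frame of flagged samples: `sample_id`, `score`, `z`.
#' @export
flag_outlier_annotations <- function(scores, annotation, label,
                                     score_label = label, z_threshold = 3,
                                     group_col = "group") {
  ids <- intersect(group_members(annotation, label, group_col),
                   rownames(scores))
  if (length(ids) < 3)
    stop("need at least 3 samples annotated '", label, "', got ", length(ids))
  if (!score_label %in% colnames(scores))
    stop("no score column '", score_label, "'")
  s <- scores[ids, score_label]
  med <- stats::median(s)
  md <- stats::mad(s)
  z <- if (md > 0) (s - med) / md else ifelse(s < med, -Inf, ifelse(s > med, Inf, 0))
  flagged <- z < -z_threshold
  data.frame(sample_id = ids[flagged], score = unname(s[flagged]),
             z = unname(z[flagged]))
}
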