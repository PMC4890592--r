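#' Per-gene two-group p-values
#'
#' Computes, for every gene, the two-sample Welch (unequal-variance) t-test
#' p-value between two disjoint sample groups. Welch's test is the safer
#' default for heterogeneous compendia where group variances routinely
#' differ; a pooled-variance test is available via `var_equal = TRUE`.
#'
#' Conventions for degenerate genes: a gene whose values are constant within
#' both groups carries no evidence, so it gets p = 1 when the group means
#' agree and the floor value when they differ. All p-values are floored at
#' `1e-300` so that `-log10` transforms stay finite.
#'
#' @param x numeric matrix, genes x samples, with sample column names.
#' @param members_a,members_b disjoint character vectors of sample ids (or
#'   integer column indices), each of size at least 2.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return named numeric vector of p-values in `(0, 1]`, one per gene.
#' @export
group_pvalues <- function(x, members_a, members_b, var_equal = FALSE) {
  if (is.character(members_a)) members_a <- match(members_a, colnames(x))
  if (is.character(members_b)) members_b <- match(members_b, colnames(x))
  if (anyNA(members_a) || anyNA(members_b))
    stop("some sample ids not found in the matrix")
  if (length(intersect(members_a, members_b)))
    stop("groups must be disjoint")
  n1 <- length(members_a); n2 <- length(members_b)
  if (n1 < 2 || n2 < 2)
    stop("both groups need at least 2 samples (got ", n1, " and ", n2, ")")
  xa <- x[, members_a, drop = FALSE]
  xb <- x[, members_b, drop = FALSE]
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  v1 <- row_vars(xa); v2 <- row_vars(xb)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se2 <- a + b
    df <- se2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  # zero variance in both groups: no evidence if means agree, floor otherwise
  degen <- se2 == 0
  p[degen & m1 == m2] <- 1
  p[degen & m1 != m2] <- 1e-300
  p <- pmax(p, 1e-300)
  names(p) <- rownames(x)
  p
}

#' Information ratio of two p-value vectors
#'
#' Summarises how two-group differential-expression evidence partitions
#' between the projected and residual subspaces into a single number in
#' `[0, 1]`: low values mean most information sits in the projected space
#' (the first k principal components), high values mean most information
#' sits in the residual space. Evidence in each subspace is totalled as
#' `S = sum(-log10 p)` over genes and the ratio is `S_res / (S_proj +
#' S_res)`; when both sums are zero (no evidence anywhere) the convention
#' is 0.5.
#'
#' @param p_projected,p_residual equal-length vectors of per-gene p-values
#'   from the projected and residual matrices (see [group_pvalues()]).
#' @return scalar in `[0, 1]`.
#' @examples
#' information_ratio(10^-(1:3), 10^-(2 * (1:3)))  # 12/18
#' @export
information_ratio <- function(p_projected, p_residual) {
  if (length(p_projected) != length(p_residual))
    stop("p-value vectors must have equal length")
  s_p <- sum(-log10(pmax(p_projected, 1e-300)))
  s_r <- sum(-log10(pmax(p_residual, 1e-300)))
  if (s_p + s_r == 0) return(0.5)
  s_r / (s_p + s_r)
}

#' Information ratio for a pair of annotated groups
#'
#' Decomposes the expression matrix at `k` components and computes per-gene
#' Welch p-values between the two groups in the original, projected and
#' residual matrices, together with the information ratio. The returned
#' object also carries the `-log10` p-value scatter data (subspace versus
#' original) that underlies the usual diagnostic plots.
#'
#' @inheritParams decompose_expression
#' @param annotation sample annotation, see [as_annotation()].
#' @param group_a,group_b group labels resolved against `group_col`.
#' @param group_col annotation column holding the labels (default `"group"`).
#' @param var_equal passed on to [group_pvalues()].
#' @return object of class `ir_result`: list with `p_original`,
#'   `p_projected`, `p_residual`, `ir`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `k`, and `scatter` (data frame of per-gene log10 p-values).
#' @export
ir_for_groups <- function(x, model, k, annotation, group_a, group_b,
                          group_col = "group", var_equal = FALSE) {
  x <- as_expression(x)
  ids_a <- intersect(group_members(annotation, group_a, group_col), colnames(x))
  ids_b <- intersect(group_members(annotation, group_b, group_col), colnames(x))
  dec <- decompose_expression(x, model, k)
  p_orig <- group_pvalues(x, ids_a, ids_b, var_equal)
  # a numerically empty subspace (k = 0, or k = full rank leaving only
  # floating-point residue) carries no information: p = 1 by convention
  # rather than t-tests on rounding noise
  sub_pvalues <- function(m, ref) {
    if (norm(m, "F") < 1e-10 * norm(ref, "F"))
      stats::setNames(rep(1, nrow(m)), rownames(m))
    else group_pvalues(m, ids_a, ids_b, var_equal)
  }
  xc <- x - model$center
  p_proj <- sub_pvalues(dec$projected, xc)
  p_res <- sub_pvalues(dec$residual, xc)
  structure(list(
    p_original = p_orig, p_projected = p_proj, p_residual = p_res,
    ir = information_ratio(p_proj, p_res),
    group_a = group_a, group_b = group_b,
    n_a = length(ids_a), n_b = length(ids_b), k = as.integer(k),
    scatter = data.frame(gene_id = rownames(x),
                         log10_original = log10(p_orig),
                         log10_projected = log10(p_proj),
                         log10_residual = log10(p_res))
  ), class = "ir_result")
}

#' @export
print.ir_result <- function(x, ...) {
  cat(sprintf("IR = %.4f  (%s [n=%d] vs %s [n=%d], k = %d)\n",
              x$ir, x$group_a, x$n_a, x$group_b, x$n_b, x$k))
  invisible(x)
}

#' Information ratio as a function of subspace dimension
#'
#' Recomputes the information ratio for a series of projection dimensions k.
#' Signals carried by few genes (genetic contrasts such as sex) keep the IR
#' high until k reaches the components that actually contain them, at which
#' point the IR drops — the scan localises where in the spectrum a contrast
#' lives.
#'
#' @inheritParams ir_for_groups
#' @param k_values integer vector of dimensions, each within `0..model$k`.
#' @return data frame with columns `k` and `ir`.
#' @export
ir_dimension_scan <- function(x, model, annotation, group_a, group_b,
                              k_values, group_col = "group",
                              var_equal = FALSE) {
  ir <- vapply(k_values, function(k) {
    ir_for_groups(x, model, k, annotation, group_a, group_b,
                  group_col, var_equal)$ir
  }, numeric(1))
  data.frame(k = as.integer(k_values), ir = ir)
}

#' Pairwise information-ratio matrix over annotated groups
#'
#' Computes the information ratio for every unordered pair of groups that
#' meet a minimum size, returning a labelled symmetric matrix (diagonal NA).
#' Mirrors the all-pairs heatmap analysis over groups with at least 10
#' samples.
#'
#' @inheritParams ir_for_groups
#' @param min_group_size smallest group size admitted (default 10).
#' @return symmetric numeric matrix with group labels as dimnames.
#' @export
pairwise_ir_matrix <- function(x, model, k, annotation,
                               min_group_size = 10, group_col = "group",
                               var_equal = FALSE) {
  annotation <- as_annotation(annotation)
  annotation <- annotation[annotation$sample_id %in% colnames(x), ]
  sizes <- table(annotation[[group_col]])
  labels <- names(sizes)[sizes >= min_group_size]
  if (length(labels) < 2)
    stop("fewer than 2 groups with at least ", min_group_size, " samples")
  m <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_along(labels)[-length(labels)]) {
    for (j in seq((i + 1), length(labels))) {
      r <- ir_for_groups(x, model, k, annotation, labels[i], labels[j],
                         group_col, var_equal)
      m[i, j] <- m[j, i] <- r$ir
    }
  }
  m
}
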