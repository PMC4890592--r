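#' Per-gene kurtosis
#'
#' Moment-ratio kurtosis `m4 / m2^2` from central sample moments, with no
#' bias correction and no excess subtraction. Low kurtosis flags bimodal
#' expression: a balanced two-point distribution attains the moment-ratio
#' lower bound of 1, a normal gives 3. Rankings are identical across the
#' common kurtosis variants; absolute values are not, so the variant used
#' here is stated explicitly. Constant genes have undefined kurtosis and are
#' returned as `NA` (and excluded from any ranking) rather than failing the
#' whole screen.
#'
#' @param x numeric matrix, genes x samples, at least 4 samples.
#' @return named numeric vector of kurtosis values (`NA` for constant genes).
#' @export
gene_kurtosis <- function(x) {
  if (ncol(x) < 4) stop("kurtosis needs at least 4 samples")
  xc <- x - rowMeans(x)
  m2 <- rowMeans(xc^2)
  m4 <- rowMeans(xc^4)
  k <- ifelse(m2 > 0, m4 / m2^2, NA_real_)
  names(k) <- rownames(x)
  k
}

#' Rank genes by bimodality (ascending kurtosis)
#'
#' Screens for bimodally expressed genes — the typical fingerprint of
#' genetic contrasts such as sex or copy number that are too small in total
#' effect to surface in the leading principal components. Genes are ranked
#' by ascending kurtosis (lowest = most bimodal); ties are broken
#' lexicographically by gene id.
#'
#' @inheritParams gene_kurtosis
#' @param top_n number of top-ranked (lowest-kurtosis) genes to report; if
#'   larger than the number of screened genes the report is truncated with a
#'   warning.
#' @return object of class `bimodality_report`: list with `report` (data
#'   frame `gene_id`, `kurtosis`, `rank` for the top_n genes), `kurtosis`
#'   (full named vector), `n_screened`, `excluded` (constant gene ids).
#' @export
rank_bimodal <- function(x, top_n = 20) {
  k <- gene_kurtosis(x)
  screened <- k[!is.na(k)]
  ord <- order(screened, names(screened))
  ranked <- screened[ord]
  if (top_n > length(ranked)) {
    warning("top_n = ", top_n, " exceeds the ", length(ranked),
            " screened genes; truncating")
    top_n <- length(ranked)
  }
  structure(list(
    report = data.frame(gene_id = names(ranked)[seq_len(top_n)],
                        kurtosis = unname(ranked[seq_len(top_n)]),
                        rank = seq_len(top_n)),
    kurtosis = k,
    n_screened = length(ranked),
    excluded = names(k)[is.na(k)]
  ), class = "bimodality_report")
}

#' @export
print.bimodality_report <- function(x, ...) {
  cat(sprintf("bimodality screen: %d genes ranked (%d constant excluded)\n",
              x$n_screened, length(x$excluded)))
  print(utils::head(x$report, 10))
  invisible(x)
}

#' Split samples by one gene's expression
#'
#' Deterministic one-dimensional 2-means on a single gene's values: centers
#' are initialised at the minimum and maximum, samples are assigned to the
#' nearest center, and centers are recomputed until the assignment is
#' stable. The cluster with the smaller mean is labelled 0. For a truly
#' bimodal gene (e.g. a Y-chromosomal gene splitting the sexes) this
#' recovers the two modes; for unimodal genes the split is arbitrary.
#'
#' @param x numeric matrix, genes x samples.
#' @param gene_id row to split on; must be present and non-constant.
#' @return named integer vector of 0/1 labels, one per sample.
#' @export
split_by_gene <- function(x, gene_id) {
  if (!gene_id %in% rownames(x)) stop("gene '", gene_id, "' not found")
  v <- x[gene_id, ]
  if (max(v) == min(v)) stop("gene '", gene_id, "' is constant")
  centers <- c(min(v), max(v))
  labels <- NULL
  for (iter in seq_len(100)) {
    new_labels <- as.integer(abs(v - centers[2]) < abs(v - centers[1]))
    if (identical(new_labels, labels)) break
    labels <- new_labels
    if (any(labels == 0)) centers[1] <- mean(v[labels == 0])
    if (any(labels == 1)) centers[2] <- mean(v[labels == 1])
  }
  if (mean(v[labels == 1]) < mean(v[labels == 0])) labels <- 1L - labels
  names(labels) <- colnames(x)
  labels
}
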