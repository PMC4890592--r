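#' Expression matrices, sample annotations and gene mappings
#'
#' An expression matrix is a plain numeric matrix of log2-scale intensities
#' with genes as rows and samples as columns (the prevalent microarray
#' convention, used throughout this package and on disk). Row names are gene
#' identifiers, column names sample identifiers; both must be unique and all
#' values finite. `as_expression()` validates an existing matrix,
#' `read_expression()`/`write_expression()` move it to and from tab-separated
#' text.
#'
#' @param x numeric matrix, genes in rows, samples in columns, with unique
#'   row and column names.
#' @return For `as_expression()`, the validated matrix (invisibly unchanged).
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' as_expression(m)
#' @export
as_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene row names and sample column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  x
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a UTF-8 TSV whose first row holds sample identifiers preceded by a
#' `gene_id` corner cell, and whose first column holds gene identifiers. All
#' body cells must be numeric; missing or non-numeric cells are an error
#' (RMA-style preprocessing produces complete matrices, and silent imputation
#' would corrupt the exact decomposition identities downstream). Identifiers
#' are compared case-sensitively. Row and column order are preserved.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix (genes x samples) with identifier dimnames.
#' @seealso [write_expression()], [as_expression()]
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  if (ncol(tab) < 2) stop("expected gene_id column plus at least one sample")
  gene_ids <- tab[[1]]
  sample_ids <- colnames(tab)[-1]
  body <- as.matrix(tab[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value '%s' at gene '%s', sample '%s'",
                 body[bad[1], bad[2]], gene_ids[bad[1]], sample_ids[bad[2]]))
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  as_expression(vals)
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]: genes as rows, samples as columns, header
#' `gene_id<TAB>sample...`.
#'
#' @inheritParams as_expression
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  x <- as_expression(x)
  tab <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or validate a sample annotation table
#'
#' The annotation is a data frame with columns `sample_id`, `group` (fine
#' label, e.g. tissue or disease state), `large_scale_group` (coarse category
#' such as hematopoietic / brain / cell line / incompletely differentiated /
#' muscle / other), and optionally `sex` and `study_id`. Sample identifiers
#' must be unique.
#'
#' @param path path to a tab-separated annotation file with a header row.
#' @param annotation a data frame to validate in place of reading a file.
#' @return validated annotation data frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  as_annotation(ann)
}

#' @rdname read_annotation
#' @export
as_annotation <- function(annotation) {
  req <- c("sample_id", "group", "large_scale_group")
  miss <- setdiff(req, colnames(annotation))
  if (length(miss))
    stop("annotation is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$sample_id))
    stop("duplicate sample_id in annotation")
  annotation
}

#' @rdname read_annotation
#' @param x validated annotation data frame to write.
#' @export
write_annotation <- function(x, path) {
  utils::write.table(as_annotation(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a probe/gene identifier mapping table
#'
#' A mapping is a two-column table (`source_id`, `target_id`) of identifier
#' pairs; many-to-many relations are allowed, empty identifiers are not.
#'
#' @param path tab-separated file with header `source_id<TAB>target_id`.
#' @param mapping a data frame to validate instead of reading a file.
#' @return data frame with character columns `source_id` and `target_id`.
#' @export
read_gene_mapping <- function(path) {
  map <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  as_gene_mapping(map)
}

#' @rdname read_gene_mapping
#' @export
as_gene_mapping <- function(mapping) {
  req <- c("source_id", "target_id")
  if (!all(req %in% colnames(mapping)))
    stop("mapping must have columns source_id and target_id")
  mapping <- mapping[, req]
  if (any(!nzchar(mapping$source_id)) || any(!nzchar(mapping$target_id)))
    stop("mapping contains empty identifiers")
  mapping
}

#' Translate expression rows across identifier spaces
#'
#' Re-indexes an expression matrix from source identifiers (e.g. one
#' platform's probe sets) to target identifiers (e.g. gene symbols or another
#' platform's probes) via a mapping table. When several source rows map to a
#' target, the target row is their arithmetic mean; a source feeding several
#' targets contributes to each (the behaviour of common identifier
#' translation tools). Sources absent from the mapping are dropped; target
#' rows are returned in lexicographic order.
#'
#' @inheritParams as_expression
#' @param mapping a gene mapping, see [read_gene_mapping()].
#' @param ambiguous `"average"` (default) averages multi-mapped sources per
#'   target; `"drop"` removes source identifiers that map to more than one
#'   target before translation.
#' @return expression matrix indexed by target identifiers.
#' @export
map_genes <- function(x, mapping, ambiguous = c("average", "drop")) {
  x <- as_expression(x)
  mapping <- as_gene_mapping(mapping)
  ambiguous <- match.arg(ambiguous)
  if (ambiguous == "drop") {
    multi <- unique(mapping$source_id[duplicated(mapping[, "source_id"])])
    n_tgt <- tapply(mapping$target_id, mapping$source_id,
                    function(t) length(unique(t)))
    multi <- names(n_tgt)[n_tgt > 1]
    mapping <- mapping[!mapping$source_id %in% multi, , drop = FALSE]
  }
  mapping <- unique(mapping)
  mapping <- mapping[mapping$source_id %in% rownames(x), , drop = FALSE]
  if (nrow(mapping) == 0L)
    stop("no common genes between expression matrix and mapping")
  targets <- sort(unique(mapping$target_id))
  out <- matrix(0, length(targets), ncol(x),
                dimnames = list(targets, colnames(x)))
  for (i in seq_along(targets)) {
    src <- mapping$source_id[mapping$target_id == targets[i]]
    block <- x[src, , drop = FALSE]
    out[i, ] <- colMeans(block)
  }
  out
}
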