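#' Run a packaged analysis recipe
#'
#' Recipes chain the package's operations into the standard end-to-end
#' analyses and write their outputs as files, so a whole study is one
#' reproducible call. All randomness flows from `seed`, fanned out into
#' per-stage child seeds; re-running a recipe with the same inputs and seed
#' reproduces identical output files.
#'
#' \describe{
#'   \item{signature_correlation}{Group signatures and within-group
#'     correlations before and after decomposition at `k` (inter-/intra-
#'     group correlation analysis).}
#'   \item{pairwise_ir}{Pairwise information-ratio matrix over all groups
#'     meeting `min_group_size`.}
#'   \item{residual_subsets}{Residual subset PCA on one large-scale group,
#'     with scores written for plotting.}
#'   \item{liver_scan}{Sample-size perturbation scan of a minority group.}
#'   \item{sex_screen}{Kurtosis bimodality screen plus an information-ratio
#'     dimension scan for a carrier contrast.}
#' }
#'
#' @param name recipe name (see Details).
#' @param x expression matrix; defaults to simulating the preset named in
#'   `preset`.
#' @param annotation sample annotation matching `x`.
#' @param preset synthetic preset used when `x` is not supplied.
#' @param out_dir output directory, created if needed.
#' @param k number of parent components (default 3, the usual choice for
#'   large heterogeneous compendia).
#' @param min_group_size group-size filter (default 10).
#' @param target_group,group_a,group_b,subset_group recipe-specific labels;
#'   sensible defaults are derived from the preset.
#' @param fractions fraction grid for `liver_scan`.
#' @param seed top-level seed.
#' @return named list of written file paths (also summarised in
#'   `summary.json` in `out_dir`), invisibly; the computed objects are
#'   returned in the `results` attribute.
#' @export
run_recipe <- function(name = c("signature_correlation", "pairwise_ir",
                                "residual_subsets", "liver_scan",
                                "sex_screen"),
                       x = NULL, annotation = NULL,
                       preset = NULL, out_dir = tempfile("recipe_"),
                       k = 3, min_group_size = 10,
                       target_group = NULL, group_a = NULL, group_b = NULL,
                       subset_group = NULL,
                       fractions = seq(0.2, 1, by = 0.2), seed = 1) {
  if (!is.character(name) || !name[1] %in%
      c("signature_correlation", "pairwise_ir", "residual_subsets",
        "liver_scan", "sex_screen"))
    stop("unknown recipe '", name[1], "'; available: signature_correlation, ",
         "pairwise_ir, residual_subsets, liver_scan, sex_screen")
  name <- name[1]
  if (is.null(x)) {
    if (is.null(preset))
      preset <- switch(name, liver_scan = "liver_scan",
                       sex_screen = "sex_lymphoma",
                       residual_subsets = "cancer_subset", "compendium")
    sim <- simulate_expression(
      synthetic_preset(preset, seed = child_seed(seed, "simulate")))
    x <- sim$expression
    annotation <- sim$annotation
  }
  x <- as_expression(x)
  annotation <- as_annotation(annotation)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  results <- list()
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }

  if (name == "signature_correlation") {
    model <- fit_pca(x, k = k)
    dec <- decompose_expression(x, model, k)
    sig_o <- group_signatures(x, annotation, min_group_size)
    sig_r <- group_signatures(dec$residual, annotation, min_group_size)
    co_o <- signature_correlation(sig_o)
    co_r <- signature_correlation(sig_r)
    wg <- merge(within_group_correlation(x, annotation, min_group_size),
                within_group_correlation(dec$residual, annotation,
                                         min_group_size, center = FALSE),
                by = c("group", "n"), suffixes = c("_original", "_residual"))
    out$correlation_original <- emit(
      data.frame(group = rownames(co_o$correlation), co_o$correlation,
                 check.names = FALSE), "signature_correlation_original.tsv")
    out$correlation_residual <- emit(
      data.frame(group = rownames(co_r$correlation), co_r$correlation,
                 check.names = FALSE), "signature_correlation_residual.tsv")
    out$within_group <- emit(wg, "within_group_correlation.tsv")
    results <- list(original = co_o, residual = co_r, within_group = wg)
  } else if (name == "pairwise_ir") {
    model <- fit_pca(x, k = k)
    m <- pairwise_ir_matrix(x, model, k, annotation, min_group_size)
    out$pairwise_ir <- emit(
      data.frame(group = rownames(m), m, check.names = FALSE),
      "pairwise_ir.tsv")
    results <- list(pairwise_ir = m)
  } else if (name == "residual_subsets") {
    if (is.null(subset_group)) {
      lsg <- table(annotation$large_scale_group)
      lsg <- lsg[!names(lsg) %in% c("other")]
      counts <- table(annotation$group[annotation$large_scale_group %in%
                                         names(lsg)],
                      annotation$large_scale_group[
                        annotation$large_scale_group %in% names(lsg)])
      n_sub <- colSums(counts > 0)
      subset_group <- names(n_sub)[which.max(n_sub)]
    }
    model <- fit_pca(x, k = k)
    dec <- decompose_expression(x, model, k)
    ids <- annotation$sample_id[annotation$large_scale_group == subset_group]
    sp <- residual_subset_pca(dec$residual, intersect(ids, colnames(x)),
                              m = 2, parent_k = k)
    sc <- sp$residual_model$scores
    out$subset_scores <- emit(
      data.frame(sample_id = rownames(sc), sc,
                 group = annotation$group[match(rownames(sc),
                                                annotation$sample_id)]),
      "residual_subset_scores.tsv")
    results <- list(subset_pca = sp)
  } else if (name == "liver_scan") {
    if (is.null(target_group)) {
      sizes <- table(annotation$group)
      target_group <- names(sizes)[which.min(sizes)]
      if ("liver" %in% names(sizes)) target_group <- "liver"
    }
    scan <- sample_size_scan(x, annotation, target_group, fractions,
                             n_top_pcs = 4, seed = child_seed(seed, "scan"))
    out$scan <- emit(as.data.frame(scan), "sample_size_scan.tsv")
    results <- list(scan = scan)
  } else if (name == "sex_screen") {
    if (is.null(group_a)) { group_a <- "female"; group_b <- "male" }
    rb <- rank_bimodal(x, top_n = 20)
    out$kurtosis <- emit(rb$report, "kurtosis_ranking.tsv")
    if ("sex" %in% colnames(annotation) && !anyNA(annotation$sex)) {
      ann2 <- annotation
      k_max <- min(30, ncol(x) - 1, nrow(x))
      model <- fit_pca(x, k = k_max)
      scan <- ir_dimension_scan(x, model, ann2, group_a, group_b,
                                k_values = c(0, 2, 4, 6, 8, 12, 16, 20),
                                group_col = "sex")
      out$ir_scan <- emit(scan, "ir_dimension_scan.tsv")
      results$ir_scan <- scan
    }
    results$bimodality <- rb
  }

  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(recipe = name, seed = seed, k = k,
         n_genes = nrow(x), n_samples = ncol(x),
         files = lapply(out, basename)),
    summary_path, auto_unbox = TRUE, pretty = TRUE)
  out$summary <- summary_path
  attr(out, "results") <- results
  invisible(out)
}
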