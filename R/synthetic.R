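#' Configuration for the synthetic compendium generator
#'
#' Describes a generative model for log2-scale expression compendia with the
#' statistical structure the package's analyses assume:
#' \deqn{x_{gs} = \mu_g + \sum_L 1[s \in L]\,\delta_L u_L(g)
#'   + \sum_c 1[s \in c]\,\delta_c u_c(g) + 1[s \in m]\,\delta_m w(g)
#'   + 1[s\ carrier]\,d\,1[g \in G] + \beta_{study(s),g} + \epsilon_{gs}}
#' with per-gene baselines \eqn{\mu_g \sim N(\mu_0, \sigma_0^2)}, one shared
#' unit-norm direction \eqn{u_L} per large-scale group (the coarse cluster
#' structure that dominates the leading principal components), one unit-norm
#' direction \eqn{u_c} per fine group (tissue/subtype signatures), an
#' optional minority group direction \eqn{w} (a group present at a small,
#' tunable sample fraction), an optional few-gene "genetic" signal (a
#' constant per-gene shift \eqn{d} on a small gene set \eqn{G} for a carrier
#' subset of samples, the sex-signal analog), per-study batch offsets
#' \eqn{\beta \sim N(0, \sigma_b^2)} and i.i.d. measurement noise
#' \eqn{\epsilon \sim N(0, \sigma^2)}.
#'
#' Direction vectors are unit-normalized, so each \eqn{\delta} is the total
#' log2 effect energy of that signature; `sparsity` controls what fraction
#' of genes carries it. With `effect_continuum = TRUE` the nonzero direction
#' entries are drawn with exponential magnitudes instead of equal ones,
#' giving the continuum of per-gene effect sizes typical of real tissue
#' contrasts; either way the vector is renormalized to unit norm.
#'
#' @param n_genes number of genes.
#' @param group_spec data frame with columns `label`, `large_scale_group`,
#'   `n_samples`, `effect_size` (fine-group delta, log2 energy units),
#'   `sparsity` (fraction of genes in the direction's support).
#' @param large_scale_effect named numeric vector: delta per large-scale
#'   group (unnamed scalar recycled to all); groups absent from the names
#'   get 0.
#' @param large_scale_sparsity support fraction of large-scale directions.
#' @param minority_spec optional list `(label, large_scale_group, fraction,
#'   effect_size, sparsity)`; `fraction` is the minority share of the full
#'   dataset.
#' @param genetic_spec optional list `(n_genes, shift, carrier_fraction)`.
#' @param effect_continuum draw per-gene direction magnitudes from an
#'   exponential distribution.
#' @param n_studies number of batches samples are assigned to (at random).
#' @param batch_sd per-study, per-gene batch offset sd (log2 units).
#' @param noise_sd i.i.d. measurement noise sd (log2 units).
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   intensities (log2 units; defaults emulate RMA output).
#' @param seed integer seed; the generator is fully reproducible given the
#'   config.
#' @return object of class `synthetic_config`.
#' @seealso [simulate_expression()], [synthetic_preset()]
#' @export
synthetic_config <- function(n_genes,
                             group_spec,
                             large_scale_effect = 0,
                             large_scale_sparsity = 0.2,
                             minority_spec = NULL,
                             genetic_spec = NULL,
                             effect_continuum = FALSE,
                             n_studies = 1,
                             batch_sd = 0,
                             noise_sd = 0.3,
                             baseline_mean = 7,
                             baseline_sd = 1.5,
                             seed = 1) {
  req <- c("label", "large_scale_group", "n_samples", "effect_size", "sparsity")
  miss <- setdiff(req, colnames(group_spec))
  if (length(miss))
    stop("group_spec missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(n_genes >= 1, all(group_spec$n_samples >= 0),
            all(group_spec$effect_size >= 0),
            all(group_spec$sparsity > 0 & group_spec$sparsity <= 1),
            n_studies >= 1, batch_sd >= 0, noise_sd >= 0, baseline_sd >= 0)
  if (sum(group_spec$n_samples) == 0) stop("total sample count is 0")
  if (anyDuplicated(group_spec$label)) stop("duplicate group labels")
  if (!is.null(minority_spec)) {
    stopifnot(minority_spec$fraction > 0, minority_spec$fraction < 1,
              minority_spec$effect_size >= 0)
    if (is.null(minority_spec$large_scale_group))
      minority_spec$large_scale_group <- "other"
    if (is.null(minority_spec$sparsity)) minority_spec$sparsity <- 0.1
    n_min <- round(minority_spec$fraction / (1 - minority_spec$fraction) *
                     sum(group_spec$n_samples))
    if (n_min == 0)
      stop("minority fraction ", minority_spec$fraction,
           " yields 0 samples at this dataset size")
    minority_spec$n_samples <- n_min
  }
  if (!is.null(genetic_spec)) {
    stopifnot(genetic_spec$n_genes >= 1, genetic_spec$n_genes <= n_genes,
              genetic_spec$carrier_fraction >= 0,
              genetic_spec$carrier_fraction <= 1)
  }
  structure(list(n_genes = as.integer(n_genes), group_spec = group_spec,
                 large_scale_effect = large_scale_effect,
                 large_scale_sparsity = large_scale_sparsity,
                 minority_spec = minority_spec, genetic_spec = genetic_spec,
                 effect_continuum = effect_continuum,
                 n_studies = as.integer(n_studies), batch_sd = batch_sd,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# One sparse unit-norm direction vector, orthogonalized against previously
# drawn directions. Without the orthogonalization step the random ~1/sqrt(m)
# overlap between sparse directions, multiplied by the large cluster effect
# sizes, couples otherwise unrelated signatures at O(1) and mixes their
# principal components; planted signatures are meant to be distinct axes, so
# exact orthogonality is part of the model (it perturbs the nominal sparsity
# only slightly).
draw_direction <- function(n_genes, sparsity, continuum, basis = NULL) {
  support <- sample.int(n_genes, max(1L, round(sparsity * n_genes)))
  mag <- if (continuum) stats::rexp(length(support)) else rep(1, length(support))
  v <- numeric(n_genes)
  v[support] <- mag * sample(c(-1, 1), length(support), replace = TRUE)
  if (!is.null(basis) && ncol(basis) > 0)
    v <- drop(v - basis %*% crossprod(basis, v))
  v / sqrt(sum(v^2))
}

#' Generate a synthetic expression compendium with ground truth
#'
#' Draws one dataset from the generative model described in
#' [synthetic_config()]. All randomness flows from `config$seed`; identical
#' configs give identical output. Passing the `directions` element of a
#' previous run's truth re-uses its signature directions, minority
#' direction, genetic gene set and baselines, which is how independent
#' validation cohorts sharing the same biology are generated.
#'
#' @param config a `synthetic_config`.
#' @param directions optional `truth$directions` list from a previous run.
#' @return list with
#'   \describe{
#'     \item{expression}{genes x samples matrix (see [as_expression()]).}
#'     \item{annotation}{sample annotation data frame (`sample_id`, `group`,
#'       `large_scale_group`, `sex` when a genetic signal is configured,
#'       `study_id`).}
#'     \item{truth}{ground truth: `directions` (list of `large_scale`,
#'       `group`, `minority`, `genetic_gene_ids`, `baseline`),
#'       `carriers`, `config`.}
#'   }
#' @examples
#' sim <- simulate_expression(synthetic_preset("compendium", n_genes = 300,
#'                                             scale = 0.2))
#' dim(sim$expression)
#' table(sim$annotation$large_scale_group)
#' @export
simulate_expression <- function(config, directions = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  gs <- config$group_spec
  gs <- gs[gs$n_samples > 0, , drop = FALSE]
  n_genes <- config$n_genes
  groups <- gs$label
  lsg <- unique(c(gs$large_scale_group,
                  if (!is.null(config$minority_spec))
                    config$minority_spec$large_scale_group))
  ls_eff <- config$large_scale_effect
  if (is.null(names(ls_eff))) {
    ls_eff <- stats::setNames(rep(ls_eff[1], length(lsg)), lsg)
  } else {
    ls_eff <- stats::setNames(
      ifelse(lsg %in% names(ls_eff), ls_eff[lsg], 0), lsg)
  }

  with_seed(config$seed, {
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    if (is.null(directions)) {
      baseline <- stats::rnorm(n_genes, config$baseline_mean, config$baseline_sd)
      basis <- matrix(0, n_genes, 0)
      take <- function(v) { basis <<- cbind(basis, v); v }
      ls_dirs <- vapply(lsg, function(l) {
        if (ls_eff[[l]] > 0)
          take(draw_direction(n_genes, config$large_scale_sparsity,
                              config$effect_continuum, basis))
        else numeric(n_genes)
      }, numeric(n_genes))
      grp_dirs <- vapply(seq_len(nrow(gs)), function(i) {
        if (gs$effect_size[i] > 0)
          take(draw_direction(n_genes, gs$sparsity[i],
                              config$effect_continuum, basis))
        else numeric(n_genes)
      }, numeric(n_genes))
      colnames(grp_dirs) <- groups
      minority_dir <- if (!is.null(config$minority_spec))
        take(draw_direction(n_genes, config$minority_spec$sparsity,
                            config$effect_continuum, basis)) else NULL
      # genetic genes drawn outside the signature supports so the few-gene
      # signal is not confounded with group structure
      genetic_idx <- NULL
      if (!is.null(config$genetic_spec)) {
        used <- which(rowSums(abs(cbind(ls_dirs, grp_dirs))) > 0)
        free <- setdiff(seq_len(n_genes), used)
        pool <- if (length(free) >= config$genetic_spec$n_genes) free
                else seq_len(n_genes)
        genetic_idx <- sort(sample(pool, config$genetic_spec$n_genes))
      }
      directions <- list(
        large_scale = ls_dirs, group = grp_dirs,
        minority = minority_dir,
        genetic_gene_ids = gene_ids[genetic_idx],
        baseline = baseline)
    } else {
      baseline <- directions$baseline
      ls_dirs <- directions$large_scale
      grp_dirs <- directions$group
      minority_dir <- directions$minority
      genetic_idx <- match(directions$genetic_gene_ids, gene_ids)
    }

    n_per_group <- gs$n_samples
    group_of <- rep(groups, n_per_group)
    lsg_of <- rep(gs$large_scale_group, n_per_group)
    if (!is.null(config$minority_spec)) {
      ms <- config$minority_spec
      group_of <- c(group_of, rep(ms$label, ms$n_samples))
      lsg_of <- c(lsg_of, rep(ms$large_scale_group, ms$n_samples))
    }
    n <- length(group_of)
    sample_ids <- sprintf("S%04d", seq_len(n))

    x <- matrix(baseline, n_genes, n,
                dimnames = list(gene_ids, sample_ids))
    for (l in lsg) {
      if (ls_eff[[l]] > 0)
        x[, lsg_of == l] <- x[, lsg_of == l] + ls_eff[[l]] * ls_dirs[, l]
    }
    for (i in seq_len(nrow(gs))) {
      if (gs$effect_size[i] > 0)
        x[, group_of == groups[i]] <- x[, group_of == groups[i]] +
          gs$effect_size[i] * grp_dirs[, groups[i]]
    }
    if (!is.null(config$minority_spec) && config$minority_spec$effect_size > 0)
      x[, group_of == config$minority_spec$label] <-
        x[, group_of == config$minority_spec$label] +
        config$minority_spec$effect_size * minority_dir

    sex <- rep(NA_character_, n)
    carriers <- logical(n)
    if (!is.null(config$genetic_spec)) {
      # carriers stratified by group: the genetic contrast is independent of
      # group structure by construction, so the per-group carrier fraction is
      # matched (up to rounding) rather than left to sampling fluctuation,
      # which at desk-scale group sizes would confound group axes with
      # carrier status
      cf <- config$genetic_spec$carrier_fraction
      n_car <- round(cf * n)
      exact <- vapply(split(seq_len(n), group_of), length, integer(1)) * cf
      base_k <- floor(exact)
      extra <- order(exact - base_k, decreasing = TRUE)
      base_k[extra[seq_len(max(0, n_car - sum(base_k)))]] <-
        base_k[extra[seq_len(max(0, n_car - sum(base_k)))]] + 1L
      for (gname in names(base_k)) {
        idx <- which(group_of == gname)
        if (base_k[[gname]] > 0)
          carriers[sample(idx, base_k[[gname]])] <- TRUE
      }
      x[genetic_idx, carriers] <- x[genetic_idx, carriers] +
        config$genetic_spec$shift
      sex <- ifelse(carriers, "male", "female")
    }

    study <- sample(rep_len(seq_len(config$n_studies), n))
    if (config$batch_sd > 0) {
      beta <- matrix(stats::rnorm(n_genes * config$n_studies, 0,
                                  config$batch_sd),
                     n_genes, config$n_studies)
      x <- x + beta[, study, drop = FALSE]
    }
    if (config$noise_sd > 0)
      x <- x + matrix(stats::rnorm(n_genes * n, 0, config$noise_sd),
                      n_genes, n)

    annotation <- data.frame(
      sample_id = sample_ids, group = group_of, large_scale_group = lsg_of,
      sex = sex, study_id = sprintf("ST%02d", study),
      stringsAsFactors = FALSE)
    list(expression = as_expression(x), annotation = annotation,
         truth = list(directions = directions,
                      carriers = stats::setNames(carriers, sample_ids),
                      config = config))
  })
}

#' Ready-made synthetic study configurations
#'
#' Presets encoding the study conditions exercised throughout the package,
#' at desk scale (about 600 samples, 1000-2000 genes; every analysis runs
#' in seconds to minutes on one CPU). Effect sizes were fixed by
#' spiked-covariance eigenvalue design so that each preset embodies the
#' mechanism it is named for; the methods vignette derives the numbers.
#'
#' \describe{
#'   \item{compendium}{Three strong large-scale clusters (hematopoietic,
#'     brain, cell-line analogs) with fine subtypes hidden beneath the
#'     leading components, a 4\% minority group (liver analog), a 5-gene
#'     genetic signal, mild batch structure.}
#'   \item{liver_scan}{The sample-size failure mode: a minority group at
#'     3.9\% of samples whose principal-component visibility collapses when
#'     its sample count is reduced to 60\% or less, with a competing
#'     muscle-analog signature occupying the contested component.}
#'   \item{sex_lymphoma}{The effect-size failure mode: 208 lymphoma samples
#'     (90 vs 118 carriers), five subtype signatures dominating the leading
#'     components, and a 10-gene large-per-gene-shift bimodal signal (sex
#'     analog) invisible to the top components.}
#'   \item{cancer_subset}{Cluster structure plus three cancer subtypes
#'     (colorectal/hepatocellular/ovarian analogs) that only residual
#'     subset PCA resolves.}
#'   \item{brain_subset}{As `cancer_subset` with three brain-region analog
#'     subtypes.}
#' }
#'
#' @param name preset name.
#' @param n_genes override the preset's gene count.
#' @param scale multiply all group sample counts by this factor (smaller,
#'   faster datasets for examples and unit tests; acceptance-scale runs use
#'   `scale = 1`).
#' @param seed override the preset's embedded seed.
#' @return a `synthetic_config`.
#' @export
synthetic_preset <- function(name = c("compendium", "liver_scan",
                                      "sex_lymphoma", "cancer_subset",
                                      "brain_subset"),
                             n_genes = NULL, scale = 1, seed = NULL) {
  if (!is.character(name) || !name[1] %in%
      c("compendium", "liver_scan", "sex_lymphoma", "cancer_subset",
        "brain_subset"))
    stop("unknown preset '", name[1], "'; available: compendium, ",
         "liver_scan, sex_lymphoma, cancer_subset, brain_subset")
  name <- name[1]
  ns <- function(n) pmax(2L, as.integer(round(n * scale)))
  cfg <- switch(name,
    compendium = synthetic_config(
      n_genes = if (is.null(n_genes)) 2000 else n_genes,
      group_spec = data.frame(
        label = c("b_cell", "t_cell", "myeloid",
                  "cortex", "cerebellum", "hypothalamus",
                  "carcinoma_line", "leukemia_line", "other_tissue"),
        large_scale_group = c(rep("hematopoietic", 3), rep("brain", 3),
                              rep("cell_line", 2), "other"),
        n_samples = ns(c(27, 27, 26, 27, 27, 26, 30, 30, 356)),
        effect_size = c(rep(24, 8), 0),
        sparsity = 0.1),
      large_scale_effect = c(hematopoietic = 80, brain = 64, cell_line = 48),
      large_scale_sparsity = 0.2,
      minority_spec = list(label = "liver", large_scale_group = "other",
                           fraction = 0.04, effect_size = 6, sparsity = 0.1),
      genetic_spec = list(n_genes = 5, shift = 3, carrier_fraction = 0.5),
      effect_continuum = TRUE,
      n_studies = 6, batch_sd = 0.1, noise_sd = 0.3,
      seed = if (is.null(seed)) 20101 else seed),
    liver_scan = synthetic_config(
      n_genes = if (is.null(n_genes)) 2000 else n_genes,
      group_spec = data.frame(
        label = c("hematopoietic_t", "brain_t", "cell_line_t", "muscle_t",
                  "other_tissue"),
        large_scale_group = c("hematopoietic", "brain", "cell_line",
                              "muscle", "other"),
        n_samples = ns(c(90, 80, 70, 12, 348)),
        effect_size = c(0, 0, 0, 8.8, 0),
        sparsity = 0.1),
      large_scale_effect = c(hematopoietic = 50, brain = 40, cell_line = 30),
      large_scale_sparsity = 0.2,
      minority_spec = list(label = "liver", large_scale_group = "other",
                           fraction = 0.039, effect_size = 7, sparsity = 0.1),
      effect_continuum = FALSE,
      n_studies = 6, batch_sd = 0.03, noise_sd = 0.25,
      seed = if (is.null(seed)) 20102 else seed),
    sex_lymphoma = synthetic_config(
      n_genes = if (is.null(n_genes)) 1000 else n_genes,
      group_spec = data.frame(
        label = paste0("lymphoma_subtype_", 1:5),
        large_scale_group = "hematopoietic",
        n_samples = ns(c(42, 42, 42, 41, 41)),
        effect_size = 18,
        sparsity = 0.1),
      large_scale_effect = 0,
      genetic_spec = list(n_genes = 10, shift = 3.5,
                          carrier_fraction = 118 / 208),
      effect_continuum = FALSE,
      n_studies = 8, batch_sd = 0.15, noise_sd = 0.3,
      seed = if (is.null(seed)) 20103 else seed),
    cancer_subset = synthetic_config(
      n_genes = if (is.null(n_genes)) 2000 else n_genes,
      group_spec = data.frame(
        label = c("hematopoietic_t", "brain_t", "colorectal_ca",
                  "hepatocellular_ca", "ovarian_ca", "other_tissue"),
        large_scale_group = c("hematopoietic", "brain", rep("cancer", 3),
                              "other"),
        n_samples = ns(c(120, 120, 40, 40, 40, 216)),
        effect_size = c(0, 0, 16, 16, 16, 0),
        sparsity = 0.1),
      large_scale_effect = c(hematopoietic = 50, brain = 40, cancer = 30),
      large_scale_sparsity = 0.2,
      effect_continuum = FALSE,
      n_studies = 6, batch_sd = 0.1, noise_sd = 0.3,
      seed = if (is.null(seed)) 20104 else seed),
    brain_subset = synthetic_config(
      n_genes = if (is.null(n_genes)) 2000 else n_genes,
      group_spec = data.frame(
        label = c("hematopoietic_t", "cell_line_t", "hypothalamus",
                  "cerebral_cortex", "cerebellum", "other_tissue"),
        large_scale_group = c("hematopoietic", "cell_line", rep("brain", 3),
                              "other"),
        n_samples = ns(c(120, 120, 40, 40, 40, 216)),
        effect_size = c(0, 0, 16, 16, 16, 0),
        sparsity = 0.1),
      large_scale_effect = c(hematopoietic = 50, cell_line = 30, brain = 40),
      large_scale_sparsity = 0.2,
      effect_continuum = FALSE,
      n_studies = 6, batch_sd = 0.1, noise_sd = 0.3,
      seed = if (is.null(seed)) 20105 else seed))
  cfg
}
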