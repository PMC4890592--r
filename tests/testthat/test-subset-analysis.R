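test_that("residual subset PCA on all samples recovers parent PCs k+1..", {
  x <- random_matrix(10, 9, seed = 51)
  parent <- fit_pca(x, 8)
  dec <- decompose_expression(x, parent, 3)
  sp <- residual_subset_pca(dec$residual, colnames(x), m = 3, parent_k = 3)
  for (j in 1:3) {
    expect_equal(abs(sum(sp$residual_model$loadings[, j] *
                           parent$loadings[, 3 + j])), 1, tolerance = 1e-6)
  }
  expect_equal(sp$residual_model$eigenvalues[1:3], parent$eigenvalues[4:6],
               tolerance = 1e-8)
  expect_error(residual_subset_pca(dec$residual, colnames(x)[1], m = 2),
               "too small")
  expect_error(residual_subset_pca(dec$residual, c("nope"), m = 1),
               "not in residual")
})

test_that("external validation reproduces the training subset scores", {
  sim <- simulate_expression(synthetic_preset("cancer_subset", scale = 0.4))
  x <- sim$expression; ann <- sim$annotation
  parent <- fit_pca(x, 3)
  dec <- decompose_expression(x, parent, 3)
  ids <- ann$sample_id[ann$large_scale_group == "cancer"]
  sp <- residual_subset_pca(dec$residual, ids, m = 2, parent_k = 3)
  back <- validate_on_external(x[, ids], parent$loadings, sp)
  expect_equal(back, sp$residual_model$scores, tolerance = 1e-8)
  # data orthogonal to the subset loadings scores to zero
  l <- sp$residual_model$loadings
  basis <- cbind(parent$loadings, l)
  y <- random_matrix(nrow(x), 6, seed = 3)
  rownames(y) <- rownames(x)
  y_orth <- y - basis %*% crossprod(basis, y)
  y_orth <- y_orth - rowMeans(y_orth)   # keep gene means at zero
  y_orth <- y_orth - basis %*% crossprod(basis, y_orth)
  expect_lt(max(abs(validate_on_external(as_expression(y_orth),
                                         parent$loadings, sp))), 1e-6)
  expect_error(validate_on_external(x[1:5, ids], parent$loadings, sp),
               "not aligned")
})

test_that("hidden subtypes separate on residual subset PCs and validate", {
  sim <- simulate_expression(synthetic_preset("cancer_subset", scale = 0.5))
  x <- sim$expression; ann <- sim$annotation
  parent <- fit_pca(x, 3)
  dec <- decompose_expression(x, parent, 3)
  ids <- ann$sample_id[ann$large_scale_group == "cancer"]
  sp <- residual_subset_pca(dec$residual, ids, m = 2, parent_k = 3)
  lab <- ann$group[match(rownames(sp$residual_model$scores), ann$sample_id)]
  sil <- cluster::silhouette(as.integer(factor(lab)),
                             dist(sp$residual_model$scores))
  expect_gt(mean(sil[, 3]), 0.5)
  # independently generated cohort with the same biology
  cfg2 <- synthetic_preset("cancer_subset", scale = 0.5, seed = 31415)
  sim2 <- simulate_expression(cfg2, directions = sim$truth$directions)
  ids2 <- sim2$annotation$sample_id[
    sim2$annotation$large_scale_group == "cancer"]
  vs <- validate_on_external(sim2$expression[, ids2], parent$loadings, sp)
  lab2 <- sim2$annotation$group[match(rownames(vs),
                                      sim2$annotation$sample_id)]
  cent <- aggregate(vs, list(lab2), mean)[, -1]
  min_centroid_dist <- min(dist(cent))
  spread <- mean(unlist(lapply(split(as.data.frame(vs), lab2), function(d)
    sqrt(rowSums(sweep(as.matrix(d), 2, colMeans(d))^2)))))
  expect_gt(min_centroid_dist, 2 * spread)
})

test_that("downsampling hits requested per-group counts reproducibly", {
  set.seed(61)
  ann <- data.frame(
    sample_id = sprintf("s%03d", 1:120),
    group = "t",
    large_scale_group = sample(rep(c("A", "B", "C"), c(50, 40, 30))))
  sel <- downsample_to_proportions(ann, c(B = 10, C = 5), keep_all = "A",
                                   seed = 9)
  got <- table(ann$large_scale_group[match(sel, ann$sample_id)])
  expect_equal(as.integer(got[c("A", "B", "C")]), c(50L, 10L, 5L))
  # same seed identical, different seed different but same sizes
  expect_identical(sel, downsample_to_proportions(ann, c(B = 10, C = 5),
                                                  keep_all = "A", seed = 9))
  sel2 <- downsample_to_proportions(ann, c(B = 10, C = 5), keep_all = "A",
                                    seed = 10)
  expect_false(identical(sel, sel2))
  expect_equal(length(sel2), length(sel))
  # row order of the annotation must not matter
  perm <- sample(nrow(ann))
  expect_identical(sel, downsample_to_proportions(ann[perm, ],
                                                  c(B = 10, C = 5),
                                                  keep_all = "A", seed = 9))
  # requesting 0 from every group except one
  only_b <- downsample_to_proportions(ann, c(B = 40), seed = 1)
  expect_setequal(only_b, ann$sample_id[ann$large_scale_group == "B"])
  expect_error(downsample_to_proportions(ann, c(B = 41), seed = 1),
               "'B' has only 40")
})

test_that("a strong minority group is found by the size scan at full count", {
  set.seed(71)
  n_genes <- 150
  x <- random_matrix(n_genes, 50, seed = 71, sd = 0.3)
  w <- c(rep(1 / sqrt(10), 10), rep(0, n_genes - 10))
  x[, 41:50] <- x[, 41:50] + 10 * w
  ann <- data.frame(sample_id = colnames(x),
                    group = rep(c("bg", "minority"), c(40, 10)),
                    large_scale_group = "all")
  scan <- sample_size_scan(x, ann, "minority", fractions = c(0.5, 1),
                           n_top_pcs = 2, seed = 5)
  expect_gt(scan$alignment[2], 0.9)
  expect_equal(scan$n_target, c(5L, 10L))
  # degenerate: the target group is every sample, indicator constant
  ann2 <- ann; ann2$group <- "minority"
  scan2 <- sample_size_scan(x, ann2, "minority", fractions = 1,
                            n_top_pcs = 2, seed = 5)
  expect_equal(scan2$alignment, 0)
  expect_error(sample_size_scan(x, ann, "minority", fractions = c(0, 1)),
               "fractions")
})
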