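test_that("per-gene Welch p-values match stats::t.test", {
  x <- random_matrix(8, 11, seed = 17)
  a <- paste0("s", 1:5); b <- paste0("s", 6:11)
  p <- group_pvalues(x, a, b)
  for (g in rownames(x)) {
    expect_equal(unname(p[g]),
                 t.test(x[g, a], x[g, b], var.equal = FALSE)$p.value,
                 tolerance = 1e-12)
  }
  pp <- group_pvalues(x, a, b, var_equal = TRUE)
  for (g in rownames(x)[1:3]) {
    expect_equal(unname(pp[g]),
                 t.test(x[g, a], x[g, b], var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("degenerate genes follow the documented conventions", {
  # identical value sets in both groups: p = 1 everywhere
  x <- tiny_matrix(c(1, 2, 1, 2), 1, 4)
  x <- rbind(x, g2 = c(3, 3, 3, 3))
  expect_equal(unname(group_pvalues(x, c("s1", "s2"), c("s3", "s4"))),
               c(1, 1))
  # zero variance but different means: floored, not NaN
  y <- tiny_matrix(c(0, 0, 5, 5), 1, 4)
  expect_equal(unname(group_pvalues(y, c("s1", "s2"), c("s3", "s4"))),
               1e-300)
  expect_error(group_pvalues(y, "s1", c("s2", "s3")), "at least 2")
  expect_error(group_pvalues(y, c("s1", "s2"), c("s2", "s3")), "disjoint")
})

test_that("information ratio follows the summed -log10 p formula", {
  # 3 genes with -log10 p of (1,2,3) projected and (2,4,6) residual
  expect_equal(information_ratio(10^-(1:3), 10^-(2 * (1:3))), 12 / 18,
               tolerance = 1e-12)
  p <- c(0.5, 0.01, 0.2)
  expect_equal(information_ratio(p, p), 0.5)
  expect_equal(information_ratio(rep(1, 4), c(1e-5, 1, 1, 1)), 1)
  expect_equal(information_ratio(rep(1, 3), rep(1, 3)), 0.5)
  expect_error(information_ratio(c(0.1, 0.2), 0.1), "equal length")
})

test_that("planted signals partition between subspaces as expected", {
  # difference along the dominant axis: captured by PC1, low IR
  # (large shift so the score-level contrast dominates the axis variance)
  d_in <- planted_split_data(alpha = 0, shift = 80, n_per_group = 30,
                             seed = 4)
  fit <- fit_pca(d_in$x, 10)
  r_in <- ir_for_groups(d_in$x, fit, 3, d_in$annotation, "a", "b")
  expect_lt(r_in$ir, 0.1)
  # difference orthogonal to the top PCs: high IR
  d_out <- planted_split_data(alpha = 1, seed = 4)
  fit2 <- fit_pca(d_out$x, 10)
  r_out <- ir_for_groups(d_out$x, fit2, 3, d_out$annotation, "a", "b")
  expect_gt(r_out$ir, 0.9)
  # k = 0: projected space empty, all information residual
  expect_equal(ir_for_groups(d_out$x, fit2, 0, d_out$annotation, "a", "b")$ir, 1)
  expect_error(ir_for_groups(d_out$x, fit2, 3, d_out$annotation, "a", "zz"),
               "unknown group")
  # scatter data has one row per gene with finite log10 p
  expect_equal(nrow(r_in$scatter), nrow(d_in$x))
  expect_true(all(is.finite(r_in$scatter$log10_residual)))
})

test_that("IR increases with the residual energy fraction of the signal", {
  alphas <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  irs <- vapply(alphas, function(a) {
    d <- planted_split_data(alpha = a, seed = 8)
    fit <- fit_pca(d$x, 5)
    ir_for_groups(d$x, fit, 1, d$annotation, "a", "b")$ir
  }, numeric(1))
  expect_true(all(diff(irs) > 0))
})

test_that("dimension scan brackets where a signal lives in the spectrum", {
  d <- planted_split_data(alpha = 1, seed = 12)
  fit <- fit_pca(d$x, 39)        # full rank for 40 samples
  scan <- ir_dimension_scan(d$x, fit, d$annotation, "a", "b",
                            k_values = c(0, 1, 3, 4, 10, 39))
  expect_equal(scan$ir[1], 1)              # k = 0: all information residual
  expect_gt(scan$ir[3], 0.9)               # signal beyond the 3 dominant axes
  expect_lt(scan$ir[4], 0.1)               # k = 4 swallows the signal axis
  expect_equal(scan$ir[6], 0)              # full rank: residual empty
  # signal concentrated on a single component: IR non-increasing in k
  # (up to background-level jitter once the signal has been absorbed)
  expect_true(all(diff(scan$ir) <= 0.01))
})

test_that("label permutation leaves no subspace preference", {
  irs <- vapply(1:4, function(i) {
    x <- random_matrix(300, 40, seed = 33 + i)
    ann <- two_group_annotation(20, 20)
    set.seed(133 + i)
    ann$group <- sample(ann$group)   # break any accidental structure
    fit <- fit_pca(x, 10)
    r <- ir_for_groups(x, fit, 3, ann, "a", "b")
    # p-values in the residual space are roughly uniform under the null
    expect_gt(ks.test(r$p_residual, "punif")$p.value, 1e-4)
    r$ir
  }, numeric(1))
  # no systematic preference for either subspace across permutations
  expect_gt(median(irs), 0.25)
  expect_lt(median(irs), 0.75)
})

test_that("pairwise IR matrix is symmetric, bounded and filtered", {
  d <- planted_split_data(alpha = 1, seed = 19)
  ann <- d$annotation
  fit <- fit_pca(d$x, 10)
  m <- pairwise_ir_matrix(d$x, fit, 3, ann, min_group_size = 10)
  expect_identical(m, t(m))
  off <- m[upper.tri(m)]
  expect_true(all(off >= 0 & off <= 1))
  expect_true(all(is.na(diag(m))))
  expect_error(pairwise_ir_matrix(d$x, fit, 3, ann, min_group_size = 1000),
               "fewer than 2 groups")
})
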