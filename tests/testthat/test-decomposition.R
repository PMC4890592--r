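# Brute-force oracle: eigendecomposition of the sample covariance matrix
# (samples as observations, genes as variables), independent of the SVD path.
eigen_oracle <- function(x) {
  xc <- t(x - rowMeans(x))          # samples x genes, gene-centered
  eigen(stats::cov(xc), symmetric = TRUE)
}

test_that("PCA matches the brute-force covariance eigendecomposition", {
  for (dims in list(c(5, 4), c(10, 7), c(8, 10))) {
    x <- random_matrix(dims[1], dims[2], seed = dims[1] * 100 + dims[2])
    k <- min(dims[2] - 1, dims[1])
    fit <- fit_pca(x, k)
    or <- eigen_oracle(x)
    r <- min(dims[2] - 1, dims[1])
    expect_equal(fit$eigenvalues[seq_len(r)], or$values[seq_len(r)],
                 tolerance = 1e-8)
    # loadings agree up to sign
    for (j in seq_len(r)) {
      expect_equal(abs(sum(fit$loadings[, j] * or$vectors[, j])), 1,
                   tolerance = 1e-6)
    }
    # variance conservation
    expect_equal(sum(fit$eigenvalues), fit$total_variance, tolerance = 1e-8)
    # orthonormal loadings
    expect_equal(crossprod(fit$loadings), diag(k), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # scores are centered-data projections
    expect_equal(fit$scores, crossprod(x - rowMeans(x), fit$loadings),
                 tolerance = 1e-10)
  }
})

test_that("PCA agrees with prcomp as an independent cross-check", {
  x <- random_matrix(30, 12, seed = 7)
  fit <- fit_pca(x, 5)
  pr <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  expect_equal(fit$eigenvalues[1:5], unname(pr$sdev[1:5]^2), tolerance = 1e-8)
  expect_equal(abs(diag(crossprod(fit$loadings, pr$rotation[, 1:5]))),
               rep(1, 5), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two distinct samples span a single component", {
  x <- tiny_matrix(c(1, 2, 3, 4, 6, 8), 3, 2)
  fit <- fit_pca(x, 1)
  expect_equal(fit$explained_fraction, 1, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PCA rejects out-of-range k and constant input", {
  x <- random_matrix(6, 4)
  expect_error(fit_pca(x, 4), "exceeds the maximum")
  expect_error(fit_pca(x, 0), "positive integer")
  expect_error(fit_pca(tiny_matrix(5, 3, 4), 2), "constant matrix")
})

test_that("projected plus residual reconstructs the centered matrix", {
  x <- random_matrix(40, 15, seed = 11)
  xc <- x - rowMeans(x)
  fit <- fit_pca(x, 14)
  scale_f <- norm(xc, "F")
  for (k in c(0, 3, 14)) {
    dec <- decompose_expression(x, fit, k)
    expect_lt(norm(dec$projected + dec$residual - xc, "F") / scale_f, 1e-8)
    expect_lt(abs(sum(diag(crossprod(dec$projected, dec$residual)))) /
                scale_f^2, 1e-8)
    if (k > 0) expect_lte(qr(dec$projected)$rank, k)
  }
  expect_equal(decompose_expression(x, fit, 0)$projected, xc * 0,
               ignore_attr = TRUE)
  expect_lt(norm(decompose_expression(x, fit, 14)$residual, "F") / scale_f,
            1e-8)
})

test_that("projection is idempotent at fixed k", {
  x <- random_matrix(25, 10, seed = 5)
  fit <- fit_pca(x, 4)
  dec <- decompose_expression(x, fit, 3)
  # re-decomposing the projected matrix (shifted back to intensity scale)
  x2 <- dec$projected + fit$center
  dec2 <- decompose_expression(as_expression(x2), fit, 3)
  expect_equal(dec2$projected, dec$projected, tolerance = 1e-8)
  expect_lt(norm(dec2$residual, "F"), 1e-8 * norm(dec$projected, "F"))
})

test_that("decompose_expression validates its inputs", {
  x <- random_matrix(10, 6)
  fit <- fit_pca(x, 3)
  expect_error(decompose_expression(x, fit, 5), "between 0 and")
  y <- x; rownames(y) <- paste0("other", 1:10)
  expect_error(decompose_expression(y, fit, 2), "gene set")
})

test_that("external projection centers by the new dataset's own means", {
  x <- random_matrix(20, 8, seed = 13)
  fit <- fit_pca(x, 3)
  # projecting the training matrix reproduces its scores
  expect_equal(project_external(x, fit$loadings), fit$scores,
               tolerance = 1e-8)
  # a sample equal to the gene-mean vector gets zero scores
  xm <- cbind(x[, 1:7], mean_s = rowMeans(x[, 1:7]))
  sc <- project_external(xm, fit$loadings)
  expect_equal(unname(sc["mean_s", ]), rep(0, 3), tolerance = 1e-8)
  # hand scalar product on a 2-gene toy
  toy <- tiny_matrix(c(1, 0, -1, 0), 2, 2)   # centered sample 1 = (1, 0)
  l <- matrix(c(0.6, 0.8), 2, 1, dimnames = list(c("g1", "g2"), "PC1"))
  expect_equal(drop(project_external(toy, l)), c(s1 = 0.6, s2 = -0.6),
               tolerance = 1e-12)
  expect_error(project_external(x[1:5, ], fit$loadings), "not aligned")
})

test_that("loading regression R-squared matches the normal equations", {
  set.seed(21)
  n <- 60
  p1 <- rnorm(n); p2 <- rnorm(n)
  target <- 0.5 * p1 + rnorm(n, sd = 0.7)
  preds <- cbind(p1, p2)
  # normal-equations oracle
  a <- cbind(1, preds)
  beta <- solve(crossprod(a), crossprod(a, target))
  rss <- sum((target - a %*% beta)^2)
  tss <- sum((target - mean(target))^2)
  expect_equal(loading_r2(target, preds), 1 - rss / tss, tolerance = 1e-8)

  expect_equal(loading_r2(p1, preds), 1, tolerance = 1e-10)
  orth <- residuals(lm(rnorm(n) ~ p1 + p2))
  expect_equal(loading_r2(orth, preds), 0, tolerance = 1e-8)
  # invariance to invertible recombination of predictor columns
  m <- matrix(c(2, 1, -1, 3), 2, 2)
  expect_equal(loading_r2(target, preds %*% m), loading_r2(target, preds),
               tolerance = 1e-10)
  expect_error(loading_r2(target[1:2], preds[1:2, ]), "underdetermined")
})

test_that("loading signs are deterministic", {
  x <- random_matrix(15, 9, seed = 31)
  f1 <- fit_pca(x, 4)
  f2 <- fit_pca(x, 4)
  expect_identical(f1$loadings, f2$loadings)
  expect_true(all(apply(f1$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})
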