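# Small in-code fixtures shared across test files.

tiny_matrix <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
         dimnames = list(sprintf("g%d", seq_len(n_genes)),
                         sprintf("s%d", seq_len(n_samples))))
}

random_matrix <- function(n_genes, n_samples, seed = 1, sd = 1) {
  set.seed(seed)
  tiny_matrix(rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples)
}

two_group_annotation <- function(n_a, n_b, labels = c("a", "b")) {
  n <- n_a + n_b
  data.frame(sample_id = sprintf("s%d", seq_len(n)),
             group = rep(labels, c(n_a, n_b)),
             large_scale_group = rep(labels, c(n_a, n_b)),
             stringsAsFactors = FALSE)
}

# A dataset with three dominant variance axes (occupying the first three
# PCs) plus a two-group mean shift whose energy is split between the first
# dominant axis and a fourth, orthogonal axis with fractions
# (1 - alpha, alpha). The shift variance stays well below the dominant axes,
# so at k = 3 the alpha fraction of the signal sits in the residual space.
# All axes are dense over 40-gene blocks so the planted evidence dominates
# the uniform p-value background. Used for the planted-signal information-
# ratio tests.
planted_split_data <- function(alpha, n_genes = 200, n_per_group = 20,
                               dominant_sd = 12, shift = 12, noise_sd = 0.3,
                               seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  block <- function(i) {
    v <- numeric(n_genes)
    v[((i - 1) * 40 + 1):(i * 40)] <- 1 / sqrt(40)
    v
  }
  u1 <- block(1); u2 <- block(2); u3 <- block(3); w <- block(4)
  x <- matrix(rnorm(n_genes * n, sd = noise_sd), n_genes, n)
  # dominant-axis coefficients repeated across the two groups, so the axes
  # carry variance but exactly zero group difference
  bal <- function() rep(rnorm(n_per_group, sd = dominant_sd), 2)
  x <- x + u1 %o% bal() + u2 %o% bal() + u3 %o% bal()
  grp <- rep(c(0, 1), each = n_per_group)
  delta <- shift * (sqrt(1 - alpha) * u1 + sqrt(alpha) * w)
  x <- x + outer(delta, grp)
  dimnames(x) <- list(sprintf("g%d", seq_len(n_genes)),
                      sprintf("s%d", seq_len(n)))
  list(x = x, annotation = two_group_annotation(n_per_group, n_per_group))
}
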