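---
title: "Residual-space analysis of expression compendia: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-space analysis of expression compendia: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(residualscope)
```

## The problem

Principal components analysis of a large, heterogeneous gene-expression
compendium concentrates most variance in a handful of leading components,
and those components track coarse cluster structure: hematopoietic samples,
neural tissue, cell lines. It is tempting to conclude that the data are
intrinsically low-dimensional and that everything beyond the first few
components is noise. This package implements the counter-analysis: decompose
the centered expression matrix $X_c$ into a rank-$k$ *projected* matrix
$P = L_k L_k^\top X_c$ (with $L_k$ the first $k$ loading vectors) and the
*residual* $R = X_c - P$, then ask — quantitatively — how much biological
information each part holds.

Three measurement tools operate on the decomposition:

* **Information ratio (IR).** For a two-group contrast, per-gene Welch
  t-test p-values are computed in the projected and residual matrices and
  summarised as $\mathrm{IR} = S_R / (S_P + S_R)$ with
  $S_\bullet = \sum_g -\log_{10} p_\bullet(g)$. Values near 0 mean the
  contrast lives in the leading components; values near 1 mean it lives in
  the residual space. The 0–1 range and its directionality follow the
  published description of the statistic; the exact aggregation formula was
  not restated there, so the summed $-\log_{10}p$ form used here is a
  documented reconstruction, and printed IR values from the original
  analyses are not expected to be matched digit-for-digit.
* **Signature correlations.** A group's signature is the vector from the
  overall dataset mean to the group mean (`group_signatures()`); residual
  signatures use the residual matrix, whose overall mean is numerically
  zero. Comparing Pearson correlations between signatures, and mean
  correlations between samples within a group, before and after
  decomposition shows which correlation structure the leading components
  actually carry.
* **Residual subset PCA.** PCA on the *whole* residual matrix only
  reproduces components $k+1, k+2, \dots$ of the parent analysis (this
  orthogonal-complement identity is tested). PCA on a residual *sample
  subset*, re-centered within the subset, can instead surface axes —
  disease subtypes, regional brain differences — that whole-dataset PCA
  never ranks highly. `validate_on_external()` projects an independent
  cohort onto those axes: the cohort is centered by its own gene means, the
  parent-$k$ projection is removed, and the remainder is scored against the
  subset loadings.

Two auxiliary screens address contrasts that PCA misses entirely:
`rank_bimodal()` ranks genes by ascending moment-ratio kurtosis
$m_4/m_2^2$ (a balanced two-mode gene attains the minimum of 1, a normal
gives 3), which finds few-gene genetic signals such as sex; and
`score_samples()` projects centered sample deviations onto predefined
biological direction sets, a simplified linear variant of atlas-based
physiological scoring (the original method's rank-based internals are out
of scope; this variant is a documented replacement, not a reproduction).

## Conventions and numerical choices

* PCA treats samples as observations and genes as variables: per-gene
  centering, **no** unit-variance scaling (log2 RMA intensities carry
  meaningful variance). The fit uses the SVD of the centered matrix, stable
  for genes ≫ samples.
* Sign convention: each loading column is flipped so its largest-magnitude
  entry is positive, first index winning ties. PC signs are arbitrary in
  principle; fixing them makes every downstream number reproducible.
* `explained_fraction` divides by total variance, so the fractions of a
  truncated fit deliberately do not sum to 1.
* Reconstruction identities ($P + R = X_c$, trace orthogonality) are held
  to 1e-8 relative to the Frobenius norm of $X_c$ and enforced by tests.
* Welch's unequal-variance t-test is the per-gene default — the safer
  choice for heterogeneous compendia — with a pooled-variance option
  (`var_equal = TRUE`). P-values are floored at 1e-300 so logs stay finite.
  A gene constant in both groups contributes $p = 1$ (no evidence), not
  `NaN`. A numerically empty subspace (k = 0, or full rank leaving only
  floating-point residue, Frobenius norm below 1e-10 of the centered data)
  contributes $p = 1$ for every gene rather than t-tests on rounding noise;
  consequently IR is exactly 1 at $k = 0$ and exactly 0 at full rank
  whenever any signal exists, and 0.5 when both subspaces are empty.
* Hierarchical clustering of signatures uses euclidean distance and
  complete linkage; `hclust`'s deterministic leaf order (original index
  breaks ties) fixes the heatmap ordering. Kurtosis ties rank
  lexicographically by gene id. The single-gene split uses 1-D 2-means with
  deterministic min/max initialisation, so it needs no seed.
* Downsampling sorts candidate ids before drawing, making the draw a
  function of annotation content and seed only. All randomness in recipes
  flows from one top-level seed through fixed per-stage child seeds.

Default tunables: `k = 3` parent components (the standard choice for
large compendia, where the first three components carry the coarse
clusters); `min_group_size = 10` for any per-group statistic (smaller
groups give unstable means and correlations); mislabel flagging uses
median/MAD robust z-scores with threshold 3 (inspection-based flagging in
the original analyses is replaced by this explicit rule).

## The synthetic generator

`simulate_expression()` draws from

$$x_{gs} = \mu_g + \textstyle\sum_L 1[s \in L]\,\delta_L u_L(g)
 + \sum_c 1[s \in c]\,\delta_c u_c(g) + 1[s \in m]\,\delta_m w(g)
 + 1[s \text{ carrier}]\,d\,1[g \in G] + \beta_{\mathrm{study}(s),g}
 + \varepsilon_{gs}$$

with unit-norm direction vectors, so each $\delta$ is the total log2
"energy" of a signature and `sparsity` sets how many genes carry it;
`effect_continuum = TRUE` draws the nonzero entries with exponential
magnitudes, mimicking the observed continuum of per-gene effect sizes.
Baselines default to $\mu_g \sim N(7, 1.5^2)$ log2 units (typical RMA
output), noise to $\sigma = 0.25$–$0.3$, batch offsets to
$\sigma_b = 0.03$–$0.15$ per study and gene.

Two generator choices deserve emphasis because they were forced by the
mathematics rather than convenience:

* **Directions are orthogonalized at draw time.** Independent sparse
  random directions overlap by $\sim 1/\sqrt{m}$; multiplied by
  large-cluster effect sizes of 40–80 log2 units this produces $O(1)$
  couplings that visibly mix the principal components of otherwise
  unrelated signatures. Planted signatures are meant to be distinct axes,
  so exact orthogonality is part of the model (it perturbs the nominal
  sparsity only slightly).
* **Carriers are stratified by group.** The genetic contrast (the sex
  analog) is independent of group structure by construction. At desk-scale
  group sizes, a fully random carrier draw leaves per-group carrier
  imbalances large enough to correlate subtype axes with carrier status
  (point-biserial ≈ 0.36 was observed from pure sampling noise), which is a
  confound of the simulation, not a property of the model. Stratification
  matches the per-group carrier fraction up to rounding.

### Presets as study conditions

The presets encode, at desk scale, the regimes the package is designed to
measure. Effect sizes were fixed by spiked-covariance eigenvalue design —
a planted signature with total effect $\delta$ carried by a sample fraction
$f$ contributes a covariance spike of roughly $f(1-f)\delta^2$, which
competes with other spikes and with the Marchenko–Pastur noise edge
$\approx p\sigma^2(1+\sqrt{n/p})^2/n$ — and then verified by simulation
across seeds. Grand-mean centering correlates all group indicators, with
coupling $\approx \delta_m \delta_c f_m f_c\,(1 + \sum_L f_L/(1-f_L))$
between any two signatures; this sets a floor on achievable eigenvector
purity and is why the presets keep large-group fractions modest.

* `liver_scan` (2000 genes × 624 samples): three strong cluster axes, a
  muscle-analog competitor (12 samples, $\delta = 8.8$, spike ≈ 1.5), and
  a liver-analog minority at 3.9% of samples ($\delta = 7$, spike ≈ 1.8 at
  full count, ≈ 1.2 at 60%). The minority's component therefore overtakes
  the competitor only above ~60–80% of the reference count: reducing the
  minority to 60% or less removes it from the top four components, the
  sample-size failure mode of PCA.
* `sex_lymphoma` (1000 genes × 208 samples, 90/118 carrier split): five
  subtype axes ($\delta = 18$, spikes ≈ 52) above a 10-gene carrier shift
  of 3.5 log2 units (spike ≈ 30, entering around component 5). No top-4
  component separates carriers, yet the per-gene evidence is enormous, so
  the IR stays high until $k$ passes the carrier component and the ten
  planted genes occupy the bottom kurtosis ranks — the effect-size failure
  mode.
* `compendium` (2000 genes × 600 samples): cluster axes at
  $\delta_L = 80/64/48$ with eight subtype axes at $\delta = 24$ hidden
  beneath them, a 4% minority, a 5-gene genetic signal, and mild batch
  structure. Used for signature-correlation and residual-information
  analyses; the $\delta$ ratio balances recovery of the cluster axes by
  the top-3 loadings against subtype visibility in the residual.
* `cancer_subset` / `brain_subset`: three-subtype variants for residual
  subset PCA and cross-cohort validation; passing one run's
  `truth$directions` into a second `simulate_expression()` call generates
  an independent cohort with the same biology.

### What the generator does and does not emulate

It reproduces the statistical skeleton the analyses rely on: dominant
cluster signatures, weaker nested signatures, a tunable minority group, a
few-gene bimodal contrast, study-wise batch offsets, i.i.d. Gaussian noise
on the log2 scale. It does **not** emulate probe-level artefacts, GC or
intensity-dependent biases, gene–gene regulatory correlation, heavy-tailed
noise, or annotation errors. Passing tests on synthetic data therefore
demonstrates that the *methods* behave as designed under the assumed model,
not that real compendia satisfy the model; on real data the same functions
apply unchanged (`read_expression()` consumes genes × samples TSV), but
thresholds such as "IR above 0.7" are descriptive, not calibrated
guarantees.

## Problem sizes

All shipped analyses run on one CPU in seconds: presets are about
600 samples × 1000–2000 genes, chosen so that the complete test suite and
the acceptance script finish within a few minutes while keeping every spike
comfortably away from the noise edge. `synthetic_preset(..., scale = s)`
shrinks sample counts proportionally for quick experiments.

## Known limitations

* The IR aggregation formula is a reconstruction (see above); comparisons
  across implementations should use its ordering, not its absolute values.
* The IR of low-rank projected data inherits strong inter-gene correlation:
  all genes share the handful of score patterns, so projected-space
  p-values move together and the null distribution of the IR is wide. Use
  permutation baselines rather than nominal p-value intuition.
* Kurtosis screening targets *balanced* two-mode genes; strongly unbalanced
  splits raise kurtosis above 3 and are invisible to this screen.
* The linear direction projection ignores the rank transforms of the
  original atlas-scoring method; scores are comparable within a direction
  set, not across methods.
* `map_genes()` averages multi-mapped probes (with a drop option); the
  original platform-translation behaviour of upstream studies is not
  specified, so cross-platform results can differ in multi-mapped genes.
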