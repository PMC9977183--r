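---
title: "Testing allometry as an evolutionary line of least resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing allometry as an evolutionary line of least resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llrmorph)
```

## The question and the model

A population's direction of greatest phenotypic variance — its *line of
least resistance* (LLR) — is where a response to selection is easiest. In
mammalian crania a strongly conserved candidate for such a line exists:
craniofacial evolutionary allometry (CREA), the pattern whereby larger
species carry proportionally longer faces. `llrmorph` implements, end to
end, the statistical machinery needed to ask whether a clade's allometric
axis behaves as an evolutionary LLR in 3D landmark data:

1. **Does shape covary with size across species?** A multivariate
   phylogenetic regression of tangent-space shape on log centroid size
   under Brownian motion (BM), with residual-randomization permutation
   (RRPP) significance. The unit-normalized row of size coefficients is the
   *allometric vector* `x`.
2. **Is within-species variation biased toward that axis?** Each species'
   phenotypic covariance matrix `P` is projected on `x`:
   `V_proj = x' P x`, the Hansen–Houle evolvability of `P` in that single
   direction, compared with the average over random unit directions
   (analytically `trace(P)/k`).
3. **Do species diverge along the axis, and farther when aligned with it?**
   Divergence is measured from each species to its subfamily's inferred
   ancestor, as a magnitude (Euclidean distance in ordination scores) and a
   direction (tangent-space difference vector) whose angle to `x` is
   compared with the null distribution of angles between random directions
   in `k` dimensions; scalar PGLS then relates divergence magnitude to
   `V_proj`, to integration (`Z_rel`), and to the angle.
4. **Does the clade overrun its BM expectation only along the axis?** A
   rate matrix `C` fitted to the leading ordination scores defines a
   multivariate normal distribution of tips centered on the ancestral
   state; 95% and 99% Mahalanobis contours flag the lineages that exceed
   it.

## Geometry: superimposition and tangent space

`gpa()` performs generalized Procrustes superimposition: translation to a
zero centroid, scaling to unit centroid size, and iterated proper rotation
(reflections are excluded — crania are chiral) onto the running consensus,
until the summed squared Procrustes distance changes by less than `tol`
(default `1e-10`). The converged solution is rotated onto the consensus'
principal axes, which makes the output invariant (to ~1e-8) to arbitrary
rigid motions and rescalings of the inputs. Scale is removed entirely and
analyzed separately through log centroid size, since allometry is the
object of study.

Shape statistics live in the tangent space at the consensus: the
`3p - 7`-dimensional orthogonal complement of the translation, scaling and
rotation directions. The basis is built by Gram–Schmidt over the projected
standard basis in a fixed order, a construction that varies continuously
with the consensus; an eigendecomposition of the projector would return an
arbitrary basis of the degenerate eigenspace and make results
seed-of-the-linear-algebra dependent. For small shape variation, Euclidean
distances between tangent vectors agree with Procrustes distances to well
under 1%, which is the regime in which the downstream angle and covariance
statistics are meaningful.

## Phylogenetic linear models

`pgls_fit()` whitens responses and design through the Cholesky factor of
the BM tip covariance and solves the resulting ordinary least squares;
sums of squares, `R2` and the Goodall-style `F` (summed over the `k`
response columns) are computed in the whitened space. Fits are invariant to
rescaling all branch lengths. Significance comes from `rrpp_significance()`:
rows of the whitened *reduced-model* residuals are permuted, the statistic
recomputed, and `P = (1 + #[F_null >= F_obs]) / (n_perm + 1)` — the +1
convention keeps the smallest attainable P at `1/(n_perm + 1)` and counts
the observed statistic within its own null. The effect size is
`Z = (F_obs - mean F_null) / sd F_null`; a log-F variant is available via
`z_transform = "log"` since conventions differ between software versions.
Slope heterogeneity between subfamilies is the same engine applied to the
contrast between the `size x group` interaction model and the common-slope
model. Zero-length terminal branches are inflated by `1e-8` times the tree
depth — enough to keep the covariance invertible, too small to move
estimates.

## Ordinations

Three ordinations of the species means are provided. `pca()` is the plain
covariance eigendecomposition. `phylo_pca()` centers on the GLS
(phylogenetic) mean — which equals the BM root estimate — and estimates the
covariance in the GLS metric; with `transform = TRUE` (the default) scores
are computed from the whitened residuals so that score distances are
phylogenetically independent. `paca()` aligns components with phylogenetic
signal instead: its leading axis maximizes `z' C_tree z` over unit loading
vectors, so axes are ordered by signal rather than variance; on a star
phylogeny the criterion degenerates to ordinary variance and the function
warns and flags the result. All axis signs follow one convention (largest
loading positive) so plots and tests are reproducible. Specimen-level
scores come from `project_specimens()`, and `family_density()` summarizes
them per family with each specimen weighted by the inverse of its species'
sample size, so densely sampled species do not dominate the density.

## Rates, ancestors and contours

`fit_bm_rate_matrix()` uses the closed-form GLS estimator of the
multivariate BM rate matrix (ML divisor `n`; REML `n - 1` as an option —
REML is the unbiased choice and is what the recovery tests use). It is fit
to the leading `n_pcs_rate_matrix = 5` ordination axes; the number of
"meaningful" axes is a configuration parameter, not something the package
infers. `ancestral_states()` returns the joint ML ancestral estimates from
the inverse-branch-length weighted graph Laplacian; the root equals the GLS
mean, and the implementation is cross-checked against an independent
likelihood maximization and against `phytools::fastAnc` in the tests.
`bm_tip_distribution()` and `ci_contour()` implement the Gaussian tip
distribution (covariance = depth x `C`, marginalized to the plotted axes
rather than refit in 2D) and its chi-square Mahalanobis contours. Trees
need not be ultrametric: each tip is evaluated at its own root-to-tip
depth, which reduces to the common depth when the tree is ultrametric.

## Bespoke statistics and their conventions

* `projected_variance()` reports both the raw `x' P x` and the
  trace-normalized proportion; the proportion is the default input to the
  divergence regressions because it is the scale on which "percent of
  within-species variation explained" statements live. Both are kept in the
  per-species records.
* Angles are reported unfolded in [0, 180] degrees by default
  (`fold_angles` folds them), because a divergence vector is a direction,
  not an axis; folded variants are used whenever the question is about an
  axis (e.g. alignment of a BM displacement that can run either way).
* `random_vector_null()` and `random_angle_null()` draw directions as
  normalized i.i.d. Gaussian vectors — the unique rotation-invariant
  choice. `angle_significance()` is one-sided (smaller angle = more aligned
  than chance), with the +1 convention.
* `integration_effect_size()` computes the relative eigenvalue variance
  `Vrel` (0 = isotropic, 1 = rank-1; equal to `r^2` for two equal-variance
  traits) and an effect size `Zrel` defined here as the Fisher z-transform
  of `sqrt(Vrel)` centered at its sampling expectation under independence,
  `atanh(sqrt(1/(n-1)))`, and scaled by `sqrt(n-3)`. Published variants of
  this effect size differ in their centering; `Vrel` itself is always
  reported so any alternative can be recomputed.
* `ks_angles_vs_null()` is the two-sided two-sample Kolmogorov–Smirnov
  test with asymptotic P.

## The synthetic generator and what it does (not) emulate

`simulate_study()` produces complete study bundles with full ground truth,
at the design scale of the motivating system: 130 species, 49 of them
sampled densely enough (27–100 specimens) to enter the intraspecific set,
28 landmarks (tangent dimension 77), a unit-depth pure-birth tree with
nested family/subfamily labels cut at relative heights 0.20 and 0.45.
Species means evolve by matrix-normal BM with a rate matrix whose leading
fraction (`eccentricity`, default 0.6 of a total rate 0.01 per unit depth)
lies along a designated "face elongation" direction; log centroid size is
the position along that direction divided by the allometric slope (0.1
shape units per log-size unit) plus independent BM noise (sd 0.15),
so shape–size coupling is an allometric line by construction; percent
grass is a logistic readout of relative size (coupling 2, 25% missing).
Populations draw specimens from per-species P-matrices of controlled trace
(0.015), eccentricity (0.3) and alignment to the allometric direction
(30 degrees), are mapped back to landmarks, perturbed by digitizing noise of
1% of the mean shape's centroid size, and given arbitrary rigid motions and
scales so that the superimposition is exercised for real. The
intraspecific defaults were set once so that biological variance dominates
digitizing noise (as in well-curated empirical data) and the projected
variance fractions land in a realistic few-percent range.

The generator emulates covariance structure, not anatomy: configurations
are random scatters, not crania; there is no sexual dimorphism,
measurement outliers, fossil tips, or evolution of `P` along the tree
(every species' `P` is drawn independently around the designated
direction). Passing tests therefore demonstrate that the estimators
recover the statistical structure they target, not that any biological
conclusion transfers to a particular empirical dataset.

## Numerical and design choices

* P-values never reach zero (+1 convention); permutations, random vectors
  and random angles are all seeded, and a full `run_full_analysis()` is
  byte-reproducible given `analysis_config(seed = )`.
* The KS comparison of divergence angles with the random-angle null
  assumes independent divergences; on a resolved phylogeny shared branches
  correlate the angles and inflate the test somewhat. The calibration
  tests therefore use star trees; on real trees the KS P-value should be
  read as descriptive.
* Species whose subfamily has fewer than two sampled members have no
  defined ancestor and carry `NA` divergence records; groups with fewer
  than three members are excluded from the slope-heterogeneity test with a
  warning.
* Degenerate inputs fail loudly: zero vectors have no direction, singular
  covariances no contour, single specimens no P-matrix, constant diet no
  ecological axis.
* Problem sizes in the test-suite simulations (40–130 species, 27–100
  specimens, 60–500 replicates) were chosen as the smallest designs at
  which the corresponding statistical claims have adequate power; the
  calibration checks state their Monte-Carlo standard errors explicitly.

## Known limitations

Semilandmarks, bilateral-symmetry decomposition and missing-landmark
estimation are out of scope, as are non-BM models of evolution (OU, early
burst, multi-rate) and G-matrix estimation proper — `P` stands in for `G`
throughout, inheriting the usual caveats. The PACA normalization follows
the alignment contract stated above; published variants differ in exact
loading normalization, so loadings (not the ordering or the signal
interpretation) should be treated as implementation-defined.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_study(n_species = 40, n_intraspecific = 10, seed = 7)
cfg <- analysis_config(n_perm = 999, seed = 5)
rep <- run_full_analysis(sim$study, cfg)
print(rep)
write_report(rep, "llr_report")
```
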