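#' Phenotypic variance-covariance matrix of one species
#'
#' Sample covariance (divisor `n - 1`) of a species' specimens in tangent
#' space; the phenotypic P-matrix used as a substitute for the additive
#' genetic G-matrix throughout the line-of-least-resistance statistics.
#'
#' @param tangent `n x k` matrix of one species' specimen tangent
#'   coordinates (`n >= 2`).
#' @param species_id optional species label.
#' @return Object of class `p_matrix`: `P` (`k x k`), `n`, `trace`,
#'   `species_id`.
#' @export
p_matrix <- function(tangent, species_id = NULL) {
  tangent <- as.matrix(tangent)
  if (nrow(tangent) < 2L)
    stop("at least 2 specimens are required for a P-matrix", call. = FALSE)
  P <- stats::cov(tangent)
  P <- (P + t(P)) / 2
  structure(list(P = P, n = nrow(tangent), trace = sum(diag(P)),
                 species_id = species_id,
                 basis = attr(tangent, "basis")),
            class = "p_matrix")
}

#' @export
print.p_matrix <- function(x, ...) {
  cat("p_matrix", if (!is.null(x$species_id)) paste0(" [", x$species_id, "]"),
      ": k = ", ncol(x$P), ", n = ", x$n,
      ", trace = ", format(x$trace, digits = 4), "\n", sep = "")
  invisible(x)
}

.as_P <- function(P) if (inherits(P, "p_matrix")) P$P else as.matrix(P)

#' Projected variance (evolvability) of P in a direction
#'
#' `V_proj = x' P x` for a unit direction `x`: the phenotypic variance the
#' population holds in that direction, Hansen-Houle evolvability for a
#' single direction. With `normalize = TRUE` the value is divided by
#' `trace(P)` and becomes the proportion of the species' total shape
#' variation explained by the direction.
#'
#' @param P a `p_matrix` or a symmetric `k x k` matrix.
#' @param x direction vector of length `k` (renormalized with a warning if
#'   not unit length).
#' @param normalize divide by `trace(P)`?
#' @return Non-negative scalar.
#' @export
projected_variance <- function(P, x, normalize = FALSE) {
  Pm <- .as_P(P)
  stopifnot(length(x) == ncol(Pm))
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("direction vector has zero length", call. = FALSE)
  if (abs(nrm - 1) > 1e-8) {
    warning("direction renormalized to unit length", call. = FALSE)
    x <- x / nrm
  }
  v <- as.numeric(t(x) %*% Pm %*% x)
  if (normalize) v / sum(diag(Pm)) else v
}

#' Random-vector null distribution of projected variance
#'
#' Projected variance of P along vectors drawn uniformly on the unit sphere
#' (i.i.d. standard normal coordinates, normalized -- the rotation-invariant
#' choice). The analytic expectation of the raw statistic is
#' `trace(P) / k`.
#'
#' @param P a `p_matrix` or symmetric matrix.
#' @param n_vectors number of random directions (default 499).
#' @param seed integer seed.
#' @param normalize as in [projected_variance()].
#' @return List with `mean`, `values` (length `n_vectors`), `n_vectors`,
#'   `seed`, `normalize`.
#' @export
random_vector_null <- function(P, n_vectors = 499L, seed = NULL,
                               normalize = FALSE) {
  Pm <- .as_P(P)
  k <- ncol(Pm)
  if (!is.null(seed)) set.seed(seed)
  V <- matrix(stats::rnorm(k * n_vectors), k, n_vectors)
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  vals <- colSums(V * (Pm %*% V))
  if (normalize) vals <- vals / sum(diag(Pm))
  list(mean = mean(vals), values = vals, n_vectors = n_vectors,
       seed = seed, normalize = normalize)
}

#' Relative eigenvalue variance and its integration effect size
#'
#' `Vrel` is the variance of the eigenvalues of P scaled by its maximum
#' attainable value given the trace and dimension, so `Vrel = 0` for an
#' isotropic matrix and `Vrel = 1` for a rank-1 (fully integrated) matrix;
#' for two traits of equal variance and correlation `r`, `Vrel = r^2`. The
#' effect size `Zrel` is the Fisher z-transform of `sqrt(Vrel)` centered at
#' its sampling expectation under independence (`sqrt(1/(n-1))`, when the
#' specimen count `n` is known) and scaled by `sqrt(n - 3)`.
#'
#' @param P a `p_matrix` or symmetric `k x k` matrix with `k >= 2`.
#' @param n specimen count behind P (taken from a `p_matrix` automatically).
#' @return List with `Vrel` and `Zrel`.
#' @export
integration_effect_size <- function(P, n = NULL) {
  if (inherits(P, "p_matrix") && is.null(n)) n <- P$n
  Pm <- .as_P(P)
  k <- ncol(Pm)
  if (k < 2L) stop("Vrel is undefined for a single trait", call. = FALSE)
  ev <- pmax(eigen(Pm, symmetric = TRUE, only.values = TRUE)$values, 0)
  tr <- sum(ev)
  if (tr <= 0) stop("P has zero trace", call. = FALSE)
  vmax <- tr^2 * (k - 1) / k
  Vrel <- sum((ev - tr / k)^2) / vmax
  Vrel <- min(max(Vrel, 0), 1)
  z <- atanh(sqrt(Vrel) * (1 - 1e-12))
  Zrel <- if (!is.null(n) && n > 3) {
    (z - atanh(sqrt(1 / (n - 1)))) * sqrt(n - 3)
  } else z
  list(Vrel = Vrel, Zrel = Zrel)
}

#' Euclidean divergence magnitude between score vectors
#'
#' Distance in ordination-score space between a species and its subfamily's
#' inferred ancestor.
#'
#' @param species_scores,ancestor_scores numeric vectors over the same axes
#'   (names, when present, must agree).
#' @return Non-negative scalar.
#' @export
divergence_magnitude <- function(species_scores, ancestor_scores) {
  if (length(species_scores) != length(ancestor_scores))
    stop("axis mismatch: score vectors differ in length", call. = FALSE)
  if (!is.null(names(species_scores)) && !is.null(names(ancestor_scores)) &&
      !identical(names(species_scores), names(ancestor_scores)))
    stop("axis mismatch: score vectors are on different axes", call. = FALSE)
  sqrt(sum((species_scores - ancestor_scores)^2))
}

#' Divergence vector of a species from its ancestor
#'
#' Per-coordinate difference between a species' shape and its subfamily's
#' inferred ancestral shape, in a shared (tangent) basis, plus a
#' unit-normalized copy for angle statistics.
#'
#' @param species_tangent,ancestor_tangent numeric vectors in the same basis.
#' @return List with `raw`, `unit` (`NA`s when degenerate), `magnitude`, and
#'   a `degenerate` flag for the zero-vector case.
#' @export
divergence_vector <- function(species_tangent, ancestor_tangent) {
  if (length(species_tangent) != length(ancestor_tangent))
    stop("basis mismatch: vectors differ in length", call. = FALSE)
  d <- as.numeric(species_tangent) - as.numeric(ancestor_tangent)
  mag <- sqrt(sum(d^2))
  list(raw = d,
       unit = if (mag > 0) d / mag else rep(NA_real_, length(d)),
       magnitude = mag, degenerate = mag == 0)
}

#' Angle between two vectors, in degrees
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @param fold map angles above 90 degrees to `180 - angle` (treating the
#'   two vectors as axes rather than directions)?
#' @return Angle in `[0, 180]` degrees (`[0, 90]` when folded).
#' @export
vector_angle <- function(a, b, fold = FALSE) {
  if (length(a) != length(b))
    stop("vectors differ in length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector has no direction", call. = FALSE)
  ct <- sum(a * b) / (na * nb)
  th <- acos(min(max(ct, -1), 1)) * 180 / pi
  if (fold) min(th, 180 - th) else th
}

#' Null distribution of angles between random directions
#'
#' Angles between pairs of independent uniform unit vectors in `k`
#' dimensions. In high dimensions the distribution concentrates around 90
#' degrees with standard deviation shrinking in `k`; at `k = 2` it is
#' uniform on `[0, 180]`.
#'
#' @param k dimension (`>= 2`).
#' @param n number of angle draws (default 10000).
#' @param seed integer seed.
#' @return Object of class `angle_null`: `k`, `samples` (degrees), `mean`,
#'   `sd`, `n`, `seed`.
#' @export
random_angle_null <- function(k, n = 10000L, seed = NULL) {
  stopifnot(k >= 2L)
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::rnorm(n * k), n, k)
  B <- matrix(stats::rnorm(n * k), n, k)
  ct <- rowSums(A * B) / (sqrt(rowSums(A^2)) * sqrt(rowSums(B^2)))
  samples <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi
  structure(list(k = as.integer(k), samples = samples,
                 mean = mean(samples), sd = stats::sd(samples),
                 n = as.integer(n), seed = seed),
            class = "angle_null")
}

#' @export
print.angle_null <- function(x, ...) {
  cat(sprintf("angle_null: k = %d, n = %d; mean = %.2f deg, sd = %.2f deg\n",
              x$k, x$n, x$mean, x$sd))
  invisible(x)
}

#' Significance of alignment between two directions
#'
#' One-sided test of whether the observed angle between two `k`-dimensional
#' vectors is smaller (more aligned) than expected between random
#' directions: `P` is the fraction of the random-angle null at or below the
#' observed angle, with the +1 convention.
#'
#' @param a,b vectors of equal dimension.
#' @param n_random size of the random-angle null (default 10000).
#' @param seed integer seed.
#' @param null optionally, a precomputed `angle_null` of matching `k`.
#' @return List with `angle` (degrees), `P`, and the `null` used.
#' @export
angle_significance <- function(a, b, n_random = 10000L, seed = NULL,
                               null = NULL) {
  obs <- vector_angle(a, b)
  if (is.null(null)) {
    null <- random_angle_null(length(a), n = n_random, seed = seed)
  } else if (null$k != length(a)) {
    stop("null dimension (", null$k, ") does not match vectors (",
         length(a), ")", call. = FALSE)
  }
  P <- (1 + sum(null$samples <= obs)) / (null$n + 1)
  list(angle = obs, P = P, null = null)
}

#' Two-sample KS test of observed angles against a random-angle null
#'
#' Two-sided Kolmogorov-Smirnov comparison of the observed divergence-angle
#' distribution with the angles expected between random directions in the
#' same dimension; a significant shift toward small angles indicates that
#' divergence is more aligned with the reference direction than chance.
#'
#' @param observed_angles numeric vector of at least 5 observed angles
#'   (degrees).
#' @param null an `angle_null`.
#' @return List with `D` (the KS statistic) and `P` (asymptotic two-sided).
#' @export
ks_angles_vs_null <- function(observed_angles, null) {
  stopifnot(inherits(null, "angle_null"))
  observed_angles <- observed_angles[is.finite(observed_angles)]
  if (length(observed_angles) < 5L)
    stop("at least 5 observed angles are required", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(observed_angles, null$samples,
                                        exact = FALSE))
  list(D = unname(kt$statistic), P = kt$p.value)
}

#' Shape axis of an ecological gradient
#'
#' PGLS of shape on an ecological covariate (percent grass in diet, the
#' browser-grazer proxy); the coefficient row, unit-normalized, is the shape
#' direction associated with the gradient, comparable by angle to the
#' allometric axis. Species missing the covariate are excluded.
#'
#' @param Y `n x k` species-mean shape matrix with species rownames.
#' @param percent_grass named numeric vector in `[0, 100]` (`NA` allowed).
#' @param tree an [ape::phylo].
#' @return List with `axis` (unit vector), `fit` (a `pgls_fit`), `n_used`.
#' @export
ecology_axis <- function(Y, percent_grass, tree) {
  Y <- as.matrix(Y)
  pg <- percent_grass[rownames(Y)]
  keep <- rownames(Y)[is.finite(pg)]
  if (length(keep) < 3L) stop("too few species with diet data", call. = FALSE)
  if (length(keep) < 10L)
    warning("fewer than 10 species with diet data; axis will be noisy",
            call. = FALSE)
  pg <- pg[keep]
  if (stats::sd(pg) == 0)
    stop("diet covariate is constant; ecological axis undefined", call. = FALSE)
  X <- matrix(pg, ncol = 1, dimnames = list(keep, "percent_grass"))
  fit <- pgls_fit(Y[keep, , drop = FALSE], X, ape::keep.tip(tree, keep))
  axis <- allometric_vector(fit, "percent_grass")
  list(axis = axis, fit = fit, n_used = length(keep))
}

#' Polynomial trend surface of a response over two ordination axes
#'
#' Least-squares fit of a second-degree polynomial surface (basis
#' `1, u, v, u^2, uv, v^2`) to a response (e.g. percent grass) over PC1/PC2
#' scores, with significance by permutation of the response rows.
#'
#' @param pc_scores `n x 2` matrix of scores.
#' @param response numeric response vector of length `n` (rows with `NA`
#'   dropped).
#' @param degree polynomial degree (currently 1 or 2).
#' @param n_perm,seed permutation settings.
#' @return Object of class `trend_surface`: `coefficients`, `r_squared`,
#'   `P`, `n`, and `evaluate(u, v)` returning fitted surface values.
#' @export
trend_surface <- function(pc_scores, response, degree = 2L, n_perm = 999L,
                          seed = NULL) {
  pc_scores <- as.matrix(pc_scores)
  stopifnot(ncol(pc_scores) == 2L, degree %in% c(1L, 2L))
  keep <- is.finite(response)
  u <- pc_scores[keep, 1]; v <- pc_scores[keep, 2]
  y <- response[keep]
  n <- length(y)
  if (n < 10L) stop("at least 10 observations are required", call. = FALSE)
  basis <- if (degree == 2L) {
    cbind(1, u, v, u^2, u * v, v^2)
  } else cbind(1, u, v)
  colnames(basis) <- if (degree == 2L)
    c("(Intercept)", "u", "v", "u2", "uv", "v2") else c("(Intercept)", "u", "v")
  if (qr(basis)$rank < ncol(basis))
    stop("rank-deficient polynomial basis (degenerate score configuration)",
         call. = FALSE)
  fit <- stats::lm.fit(basis, y)
  coefs <- fit$coefficients
  r2_of <- function(yy) {
    f <- stats::lm.fit(basis, yy)
    1 - sum(f$residuals^2) / sum((yy - mean(yy))^2)
  }
  r2 <- r2_of(y)
  if (!is.null(seed)) set.seed(seed)
  null_r2 <- vapply(seq_len(n_perm), function(i) r2_of(sample(y)), numeric(1))
  P <- (1 + sum(null_r2 >= r2)) / (n_perm + 1)
  evaluate <- function(u, v) {
    bb <- if (degree == 2L) cbind(1, u, v, u^2, u * v, v^2) else cbind(1, u, v)
    as.numeric(bb %*% coefs)
  }
  structure(list(coefficients = coefs, r_squared = r2, P = P, n = n,
                 n_perm = n_perm, degree = degree, evaluate = evaluate),
            class = "trend_surface")
}

#' @export
print.trend_surface <- function(x, ...) {
  cat(sprintf("trend_surface (degree %d): R2 = %.4f, P = %.4g (n = %d)\n",
              x$degree, x$r_squared, x$P, x$n))
  invisible(x)
}
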