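#' Fit a multivariate Brownian-motion rate matrix to ordination scores
#'
#' Maximum-likelihood fit of the multivariate Brownian-motion model to tip
#' scores: the root (ancestral) state is the GLS mean and the rate matrix is
#' the GLS cross-product of the root-centered data,
#' `C = (Y - 1a')' C_tree^{-1} (Y - 1a') / n` (ML divisor `n`; REML divisor
#' `n - 1` available). The diagonal holds the evolutionary rate of each axis
#' (score units^2 per unit branch length) and the off-diagonal the pairwise
#' coevolutionary rates.
#'
#' @param scores `n x m` matrix of tip scores with species rownames.
#' @param tree an [ape::phylo].
#' @param method `"ML"` (default) or `"REML"`.
#' @return Object of class `rate_matrix`: `rates` (`m x m`), `root` (length
#'   `m`), `m`, `n`, `loglik`, `method`.
#' @export
fit_bm_rate_matrix <- function(scores, tree, method = c("ML", "REML")) {
  method <- match.arg(method)
  Y <- as.matrix(scores)
  if (is.null(rownames(Y))) stop("scores must have species rownames", call. = FALSE)
  n <- nrow(Y); m <- ncol(Y)
  if (n <= m) warning("more axes than species: rate matrix is rank deficient",
                      call. = FALSE)
  C <- .tree_vcv(tree, rownames(Y))
  w <- .whitener(C)
  ones_t <- w(matrix(1, n, 1))
  Yt <- w(Y)
  root <- as.numeric(crossprod(ones_t, Yt) / sum(ones_t^2))
  names(root) <- colnames(Y)
  Rt <- Yt - ones_t %*% rbind(root)
  div <- if (method == "ML") n else n - 1L
  R <- crossprod(Rt) / div
  R <- (R + t(R)) / 2
  ldetC <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  ldetR <- tryCatch(as.numeric(determinant(R, logarithm = TRUE)$modulus),
                    error = function(e) NA_real_)
  tr_term <- sum(diag(tryCatch(solve(R, crossprod(Rt)),
                               error = function(e) diag(NA_real_, m))))
  loglik <- -0.5 * (n * m * log(2 * pi) + m * ldetC + n * ldetR + tr_term)
  structure(list(rates = R, root = root, m = m, n = n,
                 loglik = loglik, method = method),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("rate_matrix (", x$method, "): ", x$m, " axes, ", x$n, " tips; ",
      "trace = ", format(sum(diag(x$rates)), digits = 5),
      ", loglik = ", format(x$loglik, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Ancestral state estimates under Brownian motion
#'
#' Joint ML/GLS ancestral estimates: the internal-node values maximizing the
#' Brownian-motion likelihood given the tips, obtained from the
#' inverse-branch-length weighted graph Laplacian of the tree. The root
#' estimate equals the GLS (phylogenetic) mean of the tips.
#'
#' @param values `n x m` matrix (or named vector) of tip values with species
#'   rownames.
#' @param tree an [ape::phylo].
#' @param node internal node to return: an ape node number, `"root"`, or
#'   `NULL` to return the full internal-node matrix.
#' @return Length-`m` vector for a single node, otherwise an
#'   `Nnode x m` matrix with ape node numbers as rownames.
#' @export
ancestral_states <- function(values, tree, node = NULL) {
  if (is.null(dim(values))) values <- cbind(trait = values)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("values must carry species names", call. = FALSE)
  if (!all(tree$tip.label %in% rownames(values)))
    stop("values missing for some tips", call. = FALSE)
  Y <- values[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  depth <- max(ape::node.depth.edgelength(tree))
  wts <- 1 / pmax(tree$edge.length, 1e-8 * depth)
  L <- matrix(0, nn, nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; we <- wts[e]
    L[a, a] <- L[a, a] + we
    L[b, b] <- L[b, b] + we
    L[a, b] <- L[a, b] - we
    L[b, a] <- L[b, a] - we
  }
  idx_t <- seq_len(ntip)
  idx_i <- (ntip + 1L):nn
  anc <- solve(L[idx_i, idx_i, drop = FALSE],
               -L[idx_i, idx_t, drop = FALSE] %*% Y)
  rownames(anc) <- as.character(idx_i)
  colnames(anc) <- colnames(values)
  if (is.null(node)) return(anc)
  if (identical(node, "root")) node <- ntip + 1L
  node <- as.integer(node)
  if (!as.character(node) %in% rownames(anc))
    stop("unknown internal node: ", node, call. = FALSE)
  anc[as.character(node), ]
}

#' Brownian-motion tip distribution in morphospace
#'
#' Under Brownian motion a tip at depth `t` from the root is multivariate
#' normal, centered at the ancestral (root) state with covariance `t * C`.
#' Optionally marginalized to a subset of axes (e.g. the two plotted PCs).
#'
#' @param rm a `rate_matrix`.
#' @param depth root-to-tip depth (> 0), in the tree's branch-length units.
#' @param axes integer indices of the axes to marginalize to (default: all).
#' @return Object of class `morphospace_distribution` with `mean`, `cov`,
#'   `axes`, `depth`, and a `density(points)` evaluator.
#' @export
bm_tip_distribution <- function(rm, depth, axes = NULL) {
  stopifnot(inherits(rm, "rate_matrix"), depth > 0)
  if (is.null(axes)) axes <- seq_len(rm$m)
  if (length(axes) == 0L) stop("axes must be non-empty", call. = FALSE)
  mu <- rm$root[axes]
  S <- depth * rm$rates[axes, axes, drop = FALSE]
  mdim <- length(axes)
  dens <- function(points) {
    points <- rbind(points)
    d2 <- stats::mahalanobis(points, mu, S)
    ldet <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    exp(-0.5 * (mdim * log(2 * pi) + ldet + d2))
  }
  structure(list(mean = mu, cov = S, axes = axes, depth = depth,
                 density = dens),
            class = "morphospace_distribution")
}

#' Confidence contour of a morphospace distribution
#'
#' Mahalanobis contour of the Brownian-motion tip distribution at a given
#' probability level: a point lies inside iff its squared Mahalanobis
#' distance from the mean is at most the chi-square quantile with as many
#' degrees of freedom as marginalized dimensions. For two dimensions the
#' plotting ellipse (center, semi-axes, orientation) is also returned.
#'
#' @param dist a `morphospace_distribution`.
#' @param level coverage probability in (0, 1).
#' @return List with `level`, `df`, `radius2` (the chi-square quantile),
#'   `inside(points)` membership predicate, and -- when `df == 2` --
#'   `ellipse` (`center`, `semi_axes`, `angle` in radians) plus an
#'   `outline(n)` function returning polygon coordinates.
#' @export
ci_contour <- function(dist, level) {
  stopifnot(inherits(dist, "morphospace_distribution"),
            level > 0, level < 1)
  S <- dist$cov
  if (any(!is.finite(S)) || min(eigen(S, symmetric = TRUE,
                                      only.values = TRUE)$values) <= 0)
    stop("singular covariance: contour undefined", call. = FALSE)
  mdim <- length(dist$mean)
  r2 <- stats::qchisq(level, df = mdim)
  mu <- dist$mean
  inside <- function(points) {
    stats::mahalanobis(rbind(points), mu, S) <= r2
  }
  out <- list(level = level, df = mdim, radius2 = r2, inside = inside)
  if (mdim == 2L) {
    e <- eigen(S, symmetric = TRUE)
    out$ellipse <- list(center = mu,
                        semi_axes = sqrt(e$values * r2),
                        angle = atan2(e$vectors[2, 1], e$vectors[1, 1]))
    out$outline <- function(n = 200L) {
      th <- seq(0, 2 * pi, length.out = n)
      circ <- rbind(sqrt(e$values[1] * r2) * cos(th),
                    sqrt(e$values[2] * r2) * sin(th))
      t(e$vectors %*% circ + mu)
    }
  }
  out
}

# matrix square root for a possibly semi-definite symmetric matrix
.mat_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate Brownian-motion tip data on a tree
#'
#' Draws replicate tip datasets jointly from the matrix-normal distribution
#' with row covariance given by the tree's Brownian-motion tip covariance
#' and column covariance given by the rate matrix, centered at the root
#' state.
#'
#' @param rm a `rate_matrix` (positive semidefinite `rates` allowed).
#' @param tree an [ape::phylo].
#' @param n_reps number of replicate datasets.
#' @param seed integer seed.
#' @return `n_tips x m x n_reps` array with tip labels as rownames.
#' @export
simulate_bm_tips <- function(rm, tree, n_reps = 1L, seed = NULL) {
  stopifnot(inherits(rm, "rate_matrix"))
  C <- .tree_vcv(tree, tree$tip.label)
  A <- t(chol(C))
  Bc <- .mat_sqrt(rm$rates)
  n <- nrow(C); m <- rm$m
  if (!is.null(seed)) set.seed(seed)
  out <- array(NA_real_, c(n, m, n_reps),
               dimnames = list(tree$tip.label, names(rm$root), NULL))
  for (r in seq_len(n_reps)) {
    Z <- matrix(stats::rnorm(n * m), n, m)
    out[, , r] <- rep(rm$root, each = n) + A %*% Z %*% Bc
  }
  out
}
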