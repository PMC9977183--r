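.fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

.new_ordination <- function(vectors, scores, var_fraction, center, method,
                            transform_applied = FALSE, extra = list()) {
  colnames(vectors) <- colnames(scores) <-
    paste0(switch(method, pca = "PC", ppca = "pPC", paca = "PaC"),
           seq_len(ncol(vectors)))
  structure(c(list(vectors = vectors, scores = scores,
                   var_fraction = var_fraction, center = center,
                   method = method, transform_applied = transform_applied),
              extra),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("ordination (", x$method, "): ", nrow(x$scores), " observations, ",
      ncol(x$scores), " axes; leading var fractions: ",
      paste(sprintf("%.3f", utils::head(x$var_fraction, 3)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Principal component analysis of species-mean shapes
#'
#' Eigen-decomposition of the covariance matrix of the mean-centered data.
#' Axis signs follow the convention that each eigenvector's
#' largest-magnitude loading is positive.
#'
#' @param Y `n x k` matrix (rows = species means).
#' @param m number of axes to retain (default `min(n - 1, k)`).
#' @return An `ordination` with `vectors` (`k x m`), `scores` (`n x m`),
#'   `var_fraction`, `center`, `method = "pca"`.
#' @export
pca <- function(Y, m = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  stopifnot(n >= 2L)
  if (is.null(m)) m <- min(n - 1L, k)
  center <- colMeans(Y)
  Yc <- sweep(Y, 2, center)
  s <- svd(Yc, nu = 0)
  ev <- s$d^2 / (n - 1)
  m <- min(m, sum(s$d > max(s$d) * 1e-12))
  V <- .fix_signs(s$v[, seq_len(m), drop = FALSE])
  scores <- Yc %*% V
  rownames(scores) <- rownames(Y)
  .new_ordination(V, scores, (ev / sum(ev))[seq_len(m)], center, "pca",
                  extra = list(eigenvalues = ev[seq_len(m)],
                               total_variance = sum(ev)))
}

#' Phylogenetic principal component analysis
#'
#' Ordination of species means accounting for phylogenetic non-independence:
#' the data are centered on the GLS (phylogenetic) mean, the covariance is
#' estimated in the GLS metric weighted by the inverse Brownian-motion tip
#' covariance, and -- when `transform = TRUE` -- the scores are computed from
#' the phylogenetically whitened residuals so that downstream distances
#' between scores are independent of phylogeny.
#'
#' @param Y `n x k` matrix with species rownames matching tree tips.
#' @param tree an [ape::phylo].
#' @param gls_center center on the GLS mean (default) or the ordinary mean.
#' @param transform whiten the residuals before scoring (default `TRUE`).
#' @param m number of axes to retain.
#' @return An `ordination` with `method = "ppca"`.
#' @export
phylo_pca <- function(Y, tree, gls_center = TRUE, transform = TRUE, m = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  if (is.null(rownames(Y))) stop("Y must have species rownames", call. = FALSE)
  C <- .tree_vcv(tree, rownames(Y))
  w <- .whitener(C)
  ones <- matrix(1, n, 1)
  center <- if (gls_center) {
    Ct1 <- solve(C, ones)
    as.numeric(crossprod(Ct1, Y) / as.numeric(crossprod(ones, Ct1)))
  } else colMeans(Y)
  Yc <- sweep(Y, 2, center)
  Ytc <- w(Yc)
  R <- crossprod(Ytc) / (n - 1)
  e <- eigen(R, symmetric = TRUE)
  pos <- sum(e$values > max(e$values) * 1e-12)
  if (is.null(m)) m <- min(n - 1L, k)
  m <- min(m, pos)
  V <- .fix_signs(e$vectors[, seq_len(m), drop = FALSE])
  scores <- (if (transform) Ytc else Yc) %*% V
  rownames(scores) <- rownames(Y)
  .new_ordination(V, scores, (e$values / sum(pmax(e$values, 0)))[seq_len(m)],
                  center, "ppca", transform_applied = transform,
                  extra = list(eigenvalues = e$values[seq_len(m)]))
}

#' Phylogenetically aligned component analysis
#'
#' Components are chosen to maximize the covariation between the centered
#' data and phylogenetic signal: the leading axis maximizes `z' C_tree z`
#' over unit loading vectors (`z` the axis scores, `C_tree` the
#' Brownian-motion tip covariance), so axes are ordered by phylogenetic
#' signal rather than by variance. On a star phylogeny the criterion is
#' proportional to ordinary variance and the analysis collapses to PCA
#' (flagged as `degenerate`).
#'
#' @param Y `n x k` matrix with species rownames.
#' @param tree an [ape::phylo].
#' @param m number of axes to retain.
#' @return An `ordination` with `method = "paca"`, plus per-axis `signal`
#'   (`z' C z`) and a `degenerate` flag for the star-tree case.
#' @export
paca <- function(Y, tree, m = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  if (is.null(rownames(Y))) stop("Y must have species rownames", call. = FALSE)
  C <- .tree_vcv(tree, rownames(Y))
  offdiag <- C[upper.tri(C)]
  degenerate <- all(abs(offdiag) < 1e-12 * mean(diag(C)))
  center <- colMeans(Y)
  Yc <- sweep(Y, 2, center)
  S <- crossprod(Yc, C %*% Yc)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  pos <- sum(e$values > max(e$values) * 1e-12)
  if (is.null(m)) m <- min(n - 1L, k)
  m <- min(m, pos)
  V <- .fix_signs(e$vectors[, seq_len(m), drop = FALSE])
  scores <- Yc %*% V
  rownames(scores) <- rownames(Y)
  total_var <- sum(Yc^2)
  var_fraction <- colSums(scores^2) / total_var
  if (degenerate)
    warning("star phylogeny: no phylogenetic signal to align to; ",
            "result reduces to PCA", call. = FALSE)
  .new_ordination(V, scores, var_fraction, center, "paca",
                  extra = list(signal = e$values[seq_len(m)],
                               degenerate = degenerate))
}

#' Project specimens into an existing morphospace
#'
#' Centers the supplied tangent-space vectors on the ordination's center and
#' projects them onto its axes; used to place individual specimens into the
#' interspecific morphospace, or the members of one clade into another
#' clade's space.
#'
#' @param ord an `ordination`.
#' @param specimens `n x k` matrix of tangent coordinates in the same basis
#'   as the data the ordination was built from.
#' @return `n x m` score matrix.
#' @export
project_specimens <- function(ord, specimens) {
  stopifnot(inherits(ord, "ordination"))
  specimens <- rbind(specimens)
  if (ncol(specimens) != length(ord$center))
    stop("basis mismatch: specimens have ", ncol(specimens),
         " coordinates but the ordination lives in ", length(ord$center),
         call. = FALSE)
  ob <- attr(ord$scores, "source_basis")
  sb <- attr(specimens, "basis")
  if (!is.null(ob) && !is.null(sb) && !identical(ob, sb))
    stop("basis mismatch: '", sb, "' vs '", ob, "'", call. = FALSE)
  sweep(specimens, 2, ord$center) %*% ord$vectors
}

#' Sample-size weighted per-family score densities
#'
#' Kernel density of specimen scores along one ordination axis, estimated
#' per family with each specimen down-weighted by its species' specimen
#' count, so that every species contributes equal mass regardless of how
#' many specimens represent it. Bandwidth is Silverman's rule.
#'
#' @param scores numeric vector of specimen scores along the chosen axis.
#' @param species character vector of species labels per specimen.
#' @param family character vector of family labels per specimen.
#' @param n_grid grid resolution of the returned densities.
#' @return Data frame with columns `family`, `x`, `density`; each family's
#'   density integrates to 1.
#' @export
family_density <- function(scores, species, family, n_grid = 512L) {
  stopifnot(length(scores) == length(species),
            length(scores) == length(family))
  counts <- table(species)
  w <- 1 / as.numeric(counts[species])
  out <- lapply(split(seq_along(scores), family), function(idx) {
    wi <- w[idx] / sum(w[idx])
    bw <- if (length(idx) >= 2L && stats::sd(scores[idx]) > 0)
      "nrd0" else max(abs(scores[idx[1]]) * 0.05, 1e-3)
    d <- suppressWarnings(
      stats::density(scores[idx], weights = wi, bw = bw, n = n_grid))
    data.frame(family = unname(family[idx[1]]), x = d$x, density = d$y)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
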