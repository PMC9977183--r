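#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid; the standard geometric-morphometric body-size proxy.
#'
#' @param coords numeric `p x 3` matrix.
#' @return Non-negative scalar (zero for a fully degenerate configuration).
#' @export
centroid_size <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L, all(is.finite(coords)))
  cen <- colMeans(coords)
  sqrt(sum(sweep(coords, 2, cen)^2))
}

# best proper rotation (det = +1) taking X onto target C, both p x 3
.rotate_onto <- function(X, C) {
  s <- svd(crossprod(X, C))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  X %*% R
}

#' Generalized Procrustes superimposition
#'
#' Separates shape from location, scale and orientation: each configuration
#' is translated to a zero centroid, scaled to unit centroid size, and
#' iteratively rotated onto the running consensus (proper rotations only --
#' reflections are excluded, as crania are chiral). The consensus is the
#' arithmetic mean of the aligned configurations and the iteration stops when
#' the summed squared Procrustes distance to the consensus changes by less
#' than `tol`.
#'
#' @param x a [landmark_set()] or a `p x 3 x n` array.
#' @param tol convergence tolerance on the change in summed squared
#'   Procrustes distance.
#' @param max_iter maximum number of consensus updates.
#' @param tangent `"orthogonal"` (default) to attach tangent-space
#'   coordinates via [tangent_project()], or `"none"`.
#' @return An object of class `gpa_result`: `aligned` (`p x 3 x n`),
#'   `consensus`, `centroid_size`, `log_cs`, `tangent` (`n x k`,
#'   `k = 3p - 7`), `basis` (`3p x k` orthonormal tangent basis), `species_id`
#'   and `specimen_id` (when available), `iterations`, `converged`, and the
#'   per-iteration `ss_history`.
#' @export
gpa <- function(x, tol = 1e-10, max_iter = 100L,
                tangent = c("orthogonal", "none")) {
  tangent <- match.arg(tangent)
  if (inherits(x, "landmark_set")) {
    coords <- x$coords; specimen_id <- x$specimen_id; species_id <- x$species_id
  } else {
    coords <- x
    specimen_id <- dimnames(coords)[[3]]
    species_id <- NULL
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  p <- dim(coords)[1]; n <- dim(coords)[3]
  if (n < 2L) stop("GPA needs at least 2 configurations", call. = FALSE)

  cs <- numeric(n)
  A <- array(0, dim(coords))
  for (i in seq_len(n)) {
    ci <- sweep(coords[, , i], 2, colMeans(coords[, , i]))
    s <- sqrt(sum(ci^2))
    if (s <= 0) stop("degenerate configuration (all landmarks identical): ",
                     if (!is.null(specimen_id)) specimen_id[i] else i,
                     call. = FALSE)
    cs[i] <- s
    A[, , i] <- ci / s
  }

  consensus <- apply(A, c(1, 2), mean)
  ss_history <- numeric(0)
  ss_old <- Inf
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    for (i in seq_len(n)) A[, , i] <- .rotate_onto(A[, , i], consensus)
    consensus <- apply(A, c(1, 2), mean)
    ss <- sum(sweep(A, c(1, 2), consensus)^2)
    ss_history <- c(ss_history, ss)
    if (abs(ss_old - ss) < tol) { converged <- TRUE; break }
    ss_old <- ss
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations", call. = FALSE)

  # canonical orientation: rotate the whole solution onto the consensus'
  # principal axes so the result is invariant to the inputs' orientations
  e <- eigen(crossprod(consensus), symmetric = TRUE)
  V <- e$vectors
  for (j in 1:2) {
    cj <- consensus %*% V[, j]
    if (cj[which.max(abs(cj))] < 0) V[, j] <- -V[, j]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  consensus <- consensus %*% V
  for (i in seq_len(n)) A[, , i] <- A[, , i] %*% V

  dimnames(A) <- dimnames(coords)
  dimnames(consensus) <- dimnames(coords)[1:2]
  res <- structure(list(aligned = A, consensus = consensus,
                        centroid_size = cs, log_cs = log(cs),
                        tangent = NULL, basis = NULL, k = NA_integer_,
                        specimen_id = specimen_id, species_id = species_id,
                        iterations = iterations, converged = converged,
                        ss_history = ss_history),
                   class = "gpa_result")
  if (tangent == "orthogonal") {
    res$basis <- tangent_basis(consensus)
    res$tangent <- tangent_project(res, mode = "orthogonal")
    res$k <- ncol(res$basis)
  }
  res
}

#' @export
print.gpa_result <- function(x, ...) {
  cat("gpa_result: ", dim(x$aligned)[3], " configurations, ",
      dim(x$aligned)[1], " landmarks; ", x$iterations, " iterations (",
      if (x$converged) "converged" else "NOT converged", ")",
      if (!is.null(x$tangent)) paste0("; tangent dimension k = ", x$k), "\n",
      sep = "")
  invisible(x)
}

# orthonormal basis of the 7 nuisance directions at a centered consensus:
# 3 translations, 1 scaling (the consensus direction itself), 3 infinitesimal
# rotations. Columns of the returned 3p x 7 matrix are orthonormal.
.nuisance_basis <- function(consensus) {
  p <- nrow(consensus)
  v <- as.numeric(consensus)
  N <- matrix(0, 3L * p, 7L)
  for (a in 1:3) N[((a - 1L) * p + 1L):(a * p), a] <- 1
  N[, 4] <- v
  j <- 5L
  for (g in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
    w <- numeric(3L * p)
    a <- g[1]; b <- g[2]
    w[((a - 1L) * p + 1L):(a * p)] <- -consensus[, b]
    w[((b - 1L) * p + 1L):(b * p)] <- consensus[, a]
    N[, j] <- w
    j <- j + 1L
  }
  qr.Q(qr(N))
}

#' Orthonormal tangent-space basis at a consensus shape
#'
#' Basis of the `3p - 7` dimensional shape tangent space at the (centered,
#' unit-size) consensus: the orthogonal complement of the translation,
#' scaling and rotation directions. Column signs are fixed so that each
#' basis vector's largest-magnitude loading is positive.
#'
#' @param consensus centered `p x 3` consensus configuration.
#' @return `3p x (3p - 7)` matrix with orthonormal columns.
#' @export
tangent_basis <- function(consensus) {
  p3 <- 3L * nrow(consensus)
  N <- .nuisance_basis(consensus)
  k <- p3 - ncol(N)
  # Gram-Schmidt over the projected standard basis, in fixed order, so the
  # basis varies continuously with the consensus (an eigendecomposition of
  # the projector would pick an arbitrary basis of its degenerate eigenspace)
  B <- matrix(0, p3, k)
  got <- 0L
  for (j in seq_len(p3)) {
    v <- numeric(p3); v[j] <- 1
    for (pass in 1:2) {
      v <- v - N %*% crossprod(N, v)
      if (got > 0L) {
        Bg <- B[, seq_len(got), drop = FALSE]
        v <- v - Bg %*% crossprod(Bg, v)
      }
    }
    nv <- sqrt(sum(v^2))
    if (nv > 1e-6) {
      got <- got + 1L
      B[, got] <- v / nv
    }
    if (got == k) break
  }
  if (got < k) stop("degenerate consensus: tangent basis incomplete",
                    call. = FALSE)
  for (j in seq_len(k)) {
    i <- which.max(abs(B[, j]))
    if (B[i, j] < 0) B[, j] <- -B[, j]
  }
  B
}

#' Project superimposed configurations into tangent space
#'
#' With `mode = "orthogonal"` (the default basis for all downstream angle and
#' covariance statistics) the aligned configurations are expressed, after
#' subtracting the consensus, in the orthonormal tangent basis at the
#' consensus, dropping the 7 degenerate dimensions. With `mode = "none"` the
#' mean-centered flattened coordinates are returned unprojected.
#'
#' @param g a `gpa_result`.
#' @param mode `"orthogonal"` or `"none"`.
#' @return `n x k` matrix (`k = 3p - 7` for orthogonal mode, `3p` otherwise)
#'   with a `basis` attribute tagging the space.
#' @export
tangent_project <- function(g, mode = c("orthogonal", "none")) {
  stopifnot(inherits(g, "gpa_result"))
  mode <- match.arg(mode)
  n <- dim(g$aligned)[3]
  flat <- t(apply(g$aligned, 3, as.numeric))
  if (n == 1L) flat <- matrix(flat, nrow = 1L)
  cvec <- as.numeric(g$consensus)
  X <- sweep(flat, 2, cvec)
  if (mode == "none") {
    attr(X, "basis") <- "flat"
    rownames(X) <- g$specimen_id
    return(X)
  }
  B <- if (!is.null(g$basis)) g$basis else tangent_basis(g$consensus)
  out <- X %*% B
  attr(out, "basis") <- paste0("tangent:p", nrow(g$consensus))
  rownames(out) <- g$specimen_id
  out
}

#' Pairwise partial Procrustes distance between two configurations
#'
#' Both configurations are centered and scaled to unit centroid size, the
#' optimal proper rotation of the first onto the second is applied, and the
#' root summed squared difference is returned.
#'
#' @param a,b `p x 3` matrices with the same `p`.
#' @return Non-negative scalar distance.
#' @export
procrustes_distance <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  ca <- sweep(a, 2, colMeans(a)); ca <- ca / sqrt(sum(ca^2))
  cb <- sweep(b, 2, colMeans(b)); cb <- cb / sqrt(sum(cb^2))
  sqrt(sum((.rotate_onto(ca, cb) - cb)^2))
}

#' Species means of tangent coordinates and centroid size
#'
#' Arithmetic per-species means of the tangent-space shape coordinates and of
#' centroid size; size is averaged on the raw scale and logged afterwards.
#'
#' @param g a `gpa_result` with tangent coordinates.
#' @param species optional character vector of species labels (defaults to
#'   the labels stored in `g`).
#' @return List with `shape` (`m x k` matrix, rownames = species),
#'   `centroid_size` and `log_cs` (named length-`m` vectors), and
#'   `n_specimens`.
#' @export
species_means <- function(g, species = NULL) {
  stopifnot(inherits(g, "gpa_result"))
  if (is.null(species)) species <- g$species_id
  if (is.null(species)) stop("species labels required", call. = FALSE)
  if (is.null(g$tangent)) stop("gpa_result has no tangent coordinates",
                               call. = FALSE)
  f <- factor(species)
  counts <- as.integer(table(f))
  shape <- rowsum(unclass(g$tangent), f) / counts
  cs <- as.numeric(rowsum(g$centroid_size, f) / counts)
  names(cs) <- levels(f)
  attr(shape, "basis") <- attr(g$tangent, "basis")
  list(shape = shape, centroid_size = cs, log_cs = log(cs),
       n_specimens = stats::setNames(counts, levels(f)))
}
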