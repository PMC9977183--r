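#' @importFrom stats sd var cov setNames rnorm runif qchisq quantile
NULL

# Brownian-motion covariance of the tips, rows/cols ordered as `rows`.
# Zero-length terminal branches are inflated by 1e-8 * tree depth so the
# matrix stays invertible without materially changing estimates.
.tree_vcv <- function(tree, rows) {
  ntip <- length(tree$tip.label)
  term <- tree$edge[, 2] <= ntip
  if (any(tree$edge.length[term] == 0)) {
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length[term & tree$edge.length == 0] <- 1e-8 * depth
    warning("zero-length terminal branches inflated by 1e-8 * tree depth",
            call. = FALSE)
  }
  C <- ape::vcv(tree)
  missing <- setdiff(rows, rownames(C))
  if (length(missing) > 0L)
    stop("tips absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  C[rows, rows]
}

# GLS-to-OLS whitening transform: returns function(y) solving L w = y where
# C = L L' (lower Cholesky), so that transformed errors are iid.
.whitener <- function(C) {
  U <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance matrix is not positive definite", call. = FALSE))
  function(y) {
    out <- forwardsolve(t(U), y)
    if (is.matrix(y)) colnames(out) <- colnames(y)
    out
  }
}

.design_matrix <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  has_int <- any(apply(X, 2, function(cc) all(cc == cc[1] & cc[1] != 0)))
  if (!has_int) {
    X <- cbind("(Intercept)" = 1, X)
  }
  X
}

#' Multivariate phylogenetic generalized least squares under Brownian motion
#'
#' Fits `Y = X B + E` where the rows of `E` are correlated according to the
#' Brownian-motion covariance implied by the tree's shared branch lengths.
#' Estimation is by a Cholesky transform to ordinary least squares; all sums
#' of squares (and hence `R2` and `F`) live in the GLS-transformed space and
#' are summed over the `k` response columns (Goodall-style statistics).
#'
#' @param Y `n x k` response matrix with rownames matching tip labels.
#' @param X design matrix (an intercept column is prepended when absent).
#' @param tree an [ape::phylo] containing all rownames of `Y` as tips.
#' @return An object of class `pgls_fit` with `coefficients` (`q x k`),
#'   `fitted`, `residuals`, `R2`, `F`, `SS_model`, `SS_resid`, `SS_total`,
#'   `df_model`, `df_resid`, and the cached GLS-space matrices used by
#'   [rrpp_significance()].
#' @export
pgls_fit <- function(Y, X, tree) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) stop("Y must have species rownames", call. = FALSE)
  X <- .design_matrix(X)
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ", call. = FALSE)
  C <- .tree_vcv(tree, rownames(Y))
  w <- .whitener(C)
  Yt <- w(Y)
  Xt <- w(X)
  q <- qr(Xt)
  if (q$rank < ncol(Xt)) {
    drop_cols <- colnames(Xt)[q$pivot[(q$rank + 1L):ncol(Xt)]]
    stop("singular design matrix; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(q, Yt)
  X0t <- w(matrix(1, nrow(Y), 1, dimnames = list(rownames(Y), "(Intercept)")))
  q0 <- qr(X0t)
  fit_full <- qr.fitted(q, Yt)
  fit_red <- qr.fitted(q0, Yt)
  SS_resid <- sum((Yt - fit_full)^2)
  SS_total <- sum((Yt - fit_red)^2)
  SS_model <- sum((fit_full - fit_red)^2)
  df_model <- q$rank - 1L
  df_resid <- nrow(Y) - q$rank
  Fstat <- if (df_model > 0 && df_resid > 0)
    (SS_model / df_model) / (SS_resid / df_resid) else NA_real_
  structure(list(coefficients = B, fitted = X %*% B,
                 residuals = Y - X %*% B,
                 R2 = SS_model / SS_total, F = Fstat,
                 SS_model = SS_model, SS_resid = SS_resid, SS_total = SS_total,
                 df_model = df_model, df_resid = df_resid,
                 terms = colnames(X), n = nrow(Y), k = ncol(Y),
                 gls = list(Yt = Yt, Xt = Xt, X0t = X0t)),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("pgls_fit: n = ", x$n, ", k = ", x$k,
      sprintf("; R2 = %.4f, F = %.4f (df %d, %d)\n",
              x$R2, x$F, x$df_model, x$df_resid), sep = "")
  invisible(x)
}

# shared RRPP engine: permutes rows of the reduced-model GLS-space residuals,
# recomputes the F statistic contrasting qf (full) against qr_ (reduced).
.rrpp_engine <- function(Yt, Xt_full, Xt_red, n_perm, seed,
                         z_transform = c("identity", "log")) {
  z_transform <- match.arg(z_transform)
  if (n_perm < 99L) warning("n_perm < 99 gives a very coarse P value",
                            call. = FALSE)
  qf <- qr(Xt_full)
  qr_ <- qr(Xt_red)
  df_model <- qf$rank - qr_$rank
  df_resid <- nrow(Yt) - qf$rank
  f_of <- function(Ym) {
    rf <- Ym - qr.fitted(qf, Ym)
    rr <- Ym - qr.fitted(qr_, Ym)
    ssm <- sum(rr^2) - sum(rf^2)
    (ssm / df_model) / (sum(rf^2) / df_resid)
  }
  F_obs <- f_of(Yt)
  fit_red <- qr.fitted(qr_, Yt)
  E <- Yt - fit_red
  if (!is.null(seed)) set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    f_of(fit_red + E[sample.int(nrow(E)), , drop = FALSE])
  }, numeric(1))
  P <- (1 + sum(null_stats >= F_obs)) / (n_perm + 1)
  g <- if (z_transform == "log") log else identity
  Z <- (g(F_obs) - mean(g(null_stats))) / sd(g(null_stats))
  structure(list(P = P, Z = Z, F = F_obs, n_perm = n_perm,
                 null_stats = null_stats, seed = seed,
                 z_transform = z_transform,
                 df_model = df_model, df_resid = df_resid),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: F = %.4f, Z = %.3f, P = %.4g (%d permutations)\n",
              x$F, x$Z, x$P, x$n_perm))
  invisible(x)
}

#' Residual-randomization significance for a PGLS fit
#'
#' Permutes the GLS-transformed residuals of the reduced (intercept-only)
#' model, recomputing the model F each time. The P value uses the +1
#' convention, counting the observed statistic within its own null, so the
#' smallest attainable P is `1/(n_perm + 1)`. The standardized effect size is
#' `Z = (g(F_obs) - mean g(F_null)) / sd g(F_null)` with `g` the identity by
#' default (`z_transform = "log"` for log-F).
#'
#' @param fit a `pgls_fit`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for reproducible permutations.
#' @param z_transform `"identity"` (default) or `"log"`.
#' @return A `permutation_result` with `P`, `Z`, `F`, `null_stats`, `seed`.
#' @export
rrpp_significance <- function(fit, n_perm = 999L, seed = NULL,
                              z_transform = c("identity", "log")) {
  stopifnot(inherits(fit, "pgls_fit"))
  .rrpp_engine(fit$gls$Yt, fit$gls$Xt, fit$gls$X0t, n_perm, seed,
               match.arg(z_transform))
}

#' Unit allometric vector from a PGLS fit
#'
#' The row of regression coefficients belonging to the (scalar) size
#' predictor, normalized to unit length. This is the evolutionary allometric
#' axis: the direction in shape space toward which shapes move per unit
#' increase in log centroid size.
#'
#' @param fit a `pgls_fit` of shape on (at least) log centroid size.
#' @param predictor name of the size column in the design matrix.
#' @return Unit-length numeric vector of length `k` with a `basis` attribute
#'   inherited from the responses when available.
#' @export
allometric_vector <- function(fit, predictor = "log_cs") {
  stopifnot(inherits(fit, "pgls_fit"))
  if (!predictor %in% rownames(fit$coefficients))
    stop("predictor '", predictor, "' not in the design", call. = FALSE)
  x <- fit$coefficients[predictor, ]
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("allometric coefficient row has zero length", call. = FALSE)
  x / nrm
}

#' Test for heterogeneity of allometric slopes between groups
#'
#' Contrasts the full model `shape ~ size * group` against the common-slope
#' model `shape ~ size + group` by a GLS-space F statistic, with significance
#' by residual randomization of the reduced model. Groups with fewer than 3
#' members are excluded with a warning.
#'
#' @param Y `n x k` shape matrix with species rownames.
#' @param log_cs named numeric vector of log centroid sizes.
#' @param group factor or character vector of group (e.g. subfamily) labels.
#' @param tree an [ape::phylo].
#' @param n_perm,seed,z_transform passed to the permutation engine.
#' @return A `permutation_result` for the interaction term.
#' @export
slope_heterogeneity_test <- function(Y, log_cs, group, tree, n_perm = 999L,
                                     seed = NULL,
                                     z_transform = c("identity", "log")) {
  Y <- as.matrix(Y)
  group <- factor(group)
  keep_groups <- names(which(table(group) >= 3L))
  if (length(keep_groups) < length(levels(group)))
    warning("groups with < 3 members excluded: ",
            paste(setdiff(levels(group), keep_groups), collapse = ", "),
            call. = FALSE)
  if (length(keep_groups) < 2L)
    stop("slope heterogeneity needs at least 2 groups with >= 3 members",
         call. = FALSE)
  sel <- group %in% keep_groups
  Y <- Y[sel, , drop = FALSE]
  group <- droplevels(group[sel])
  log_cs <- log_cs[rownames(Y)]
  d <- data.frame(log_cs = log_cs, group = group)
  X_full <- stats::model.matrix(~ log_cs * group, d)
  X_red <- stats::model.matrix(~ log_cs + group, d)
  rownames(X_full) <- rownames(X_red) <- rownames(Y)
  C <- .tree_vcv(ape::keep.tip(tree, rownames(Y)), rownames(Y))
  w <- .whitener(C)
  .rrpp_engine(w(Y), w(X_full), w(X_red), n_perm, seed,
               match.arg(z_transform))
}

#' Scalar phylogenetic regression with permutation significance
#'
#' Convenience wrapper for a univariate response: PGLS of `y` on `x` under
#' Brownian motion, plus residual-randomization significance.
#'
#' @param y,x named numeric vectors over the same species.
#' @param tree an [ape::phylo].
#' @param n_perm,seed passed to [rrpp_significance()].
#' @return List with elements `fit` (a `pgls_fit`; slope under `coefficients`)
#'   and `perm` (a `permutation_result`).
#' @export
pgls_scalar <- function(y, x, tree, n_perm = 999L, seed = NULL) {
  if (is.null(names(y))) stop("y must be a named vector", call. = FALSE)
  sp <- names(y)
  Y <- matrix(y, ncol = 1, dimnames = list(sp, "y"))
  X <- matrix(x[sp], ncol = 1, dimnames = list(sp, "x"))
  fit <- pgls_fit(Y, X, tree)
  perm <- rrpp_significance(fit, n_perm = n_perm, seed = seed)
  list(fit = fit, perm = perm)
}
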