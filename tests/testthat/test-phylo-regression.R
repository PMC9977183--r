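sim_star_data <- function(n = 20, k = 3, seed = 1) {
  set.seed(seed)
  sp <- paste0("t", seq_len(n))
  x <- rnorm(n)
  B <- matrix(seq_len(2 * k), 2, k)
  Y <- cbind(1, x) %*% B + matrix(rnorm(n * k, 0, 0.5), n, k)
  rownames(Y) <- sp
  list(tree = fix_star(n, sp), x = setNames(x, sp), Y = Y, B = B)
}

test_that("PGLS on a star phylogeny equals ordinary least squares", {
  d <- sim_star_data()
  X <- matrix(d$x, ncol = 1, dimnames = list(names(d$x), "x"))
  fit <- pgls_fit(d$Y, X, d$tree)
  ols <- lm(d$Y ~ d$x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-9)
  # and the Goodall F/R2 match the OLS sums of squares summed over columns
  res <- residuals(ols)
  tot <- sweep(d$Y, 2, colMeans(d$Y))
  expect_equal(fit$SS_resid, sum(res^2), tolerance = 1e-9)
  expect_equal(fit$R2, 1 - sum(res^2) / sum(tot^2), tolerance = 1e-9)
})

test_that("exact linear data give R2 = 1 and zero residuals", {
  tr <- simulate_tree(12, seed = 3)
  sp <- tr$tip.label
  x <- setNames(seq_along(sp), sp)
  Y <- cbind(2 + 3 * x, -1 + 0.5 * x)
  rownames(Y) <- sp
  fit <- pgls_fit(Y, matrix(x, ncol = 1, dimnames = list(sp, "x")), tr)
  expect_equal(fit$R2, 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_equal(unname(fit$coefficients["x", ]), c(3, 0.5), tolerance = 1e-9)
})

test_that("4-taxon GLS coefficients match hand-solved normal equations", {
  tr <- fix_tree4()
  sp <- c("A", "B", "C", "D")
  set.seed(7)
  Y <- matrix(rnorm(8), 4, 2, dimnames = list(sp, c("y1", "y2")))
  x <- setNames(c(0.3, -1.2, 0.5, 2.0), sp)
  X <- cbind("(Intercept)" = 1, x = x)

  # oracle: form C explicitly from shared branch lengths and solve
  # B = (X' C^-1 X)^-1 X' C^-1 Y with plain solve()
  C <- rbind(c(2, 1, 0, 0), c(1, 2, 0, 0), c(0, 0, 2, 1), c(0, 0, 1, 2))
  Ci <- solve(C)
  B_ref <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% Y)

  fit <- pgls_fit(Y, X, tr)
  expect_equal(unname(fit$coefficients), unname(B_ref), tolerance = 1e-10)

  # GLS-metric sums of squares decompose additively
  expect_equal(fit$SS_model + fit$SS_resid, fit$SS_total,
               tolerance = 1e-8 * fit$SS_total)
})

test_that("GLS fit is invariant to rescaling all branch lengths", {
  tr <- simulate_tree(15, seed = 5)
  sp <- tr$tip.label
  set.seed(8)
  Y <- matrix(rnorm(30), 15, 2, dimnames = list(sp, NULL))
  x <- setNames(rnorm(15), sp)
  X <- matrix(x, ncol = 1, dimnames = list(sp, "x"))
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 37.5
  f1 <- pgls_fit(Y, X, tr)
  f2 <- pgls_fit(Y, X, tr2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  expect_equal(f1$R2, f2$R2, tolerance = 1e-9)
  expect_equal(f1$F, f2$F, tolerance = 1e-9)
})

test_that("singular designs are rejected with the collinear column named", {
  d <- sim_star_data(n = 10)
  X <- cbind(x = d$x, x_copy = d$x)
  expect_error(pgls_fit(d$Y, X, d$tree), "x_copy")
})

test_that("RRPP: deterministic data reach the minimal attainable P", {
  tr <- simulate_tree(10, seed = 2)
  sp <- tr$tip.label
  x <- setNames(rnorm(10), sp)
  Y <- matrix(2 * x + 1, ncol = 1, dimnames = list(sp, "y"))
  fit <- pgls_fit(Y, matrix(x, ncol = 1, dimnames = list(sp, "x")), tr)
  pr <- rrpp_significance(fit, n_perm = 199, seed = 4)
  expect_equal(pr$P, 1 / 200)
})

test_that("RRPP is bit-reproducible under a fixed seed", {
  d <- sim_star_data(n = 15, seed = 9)
  fit <- pgls_fit(d$Y, matrix(d$x, ncol = 1,
                              dimnames = list(names(d$x), "x")), d$tree)
  p1 <- rrpp_significance(fit, n_perm = 299, seed = 11)
  p2 <- rrpp_significance(fit, n_perm = 299, seed = 11)
  expect_identical(p1$P, p2$P)
  expect_identical(p1$Z, p2$Z)
  expect_identical(p1$null_stats, p2$null_stats)
})

test_that("RRPP type-I error is nominal for independent data", {
  n <- 40; nrep <- 500; nperm <- 99
  tr <- fix_star(n)
  sp <- tr$tip.label
  rej <- logical(nrep)
  set.seed(100)
  seeds <- sample.int(1e6, nrep)
  for (r in seq_len(nrep)) {
    set.seed(seeds[r])
    x <- rnorm(n)
    Y <- matrix(rnorm(2 * n), n, 2, dimnames = list(sp, NULL))
    fit <- pgls_fit(Y, matrix(x, ncol = 1, dimnames = list(sp, "x")), tr)
    rej[r] <- rrpp_significance(fit, n_perm = nperm,
                                seed = seeds[r] + 1)$P <= 0.05
  }
  se <- sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(mean(rej) - 0.05), 2 * se + 1e-12)
})

test_that("allometric vector: normalization, recovery, antisymmetry", {
  # closed-form normalization
  fit <- structure(list(coefficients = rbind("(Intercept)" = c(0, 0),
                                             log_cs = c(3, 4))),
                   class = "pgls_fit")
  expect_equal(allometric_vector(fit), c(0.6, 0.8))

  # recovery of a known direction at n = 100 species with strong signal
  tr <- simulate_tree(100, seed = 14)
  sp <- tr$tip.label
  k <- 8
  set.seed(15)
  u <- rnorm(k); u <- u / sqrt(sum(u^2))
  x <- setNames(rnorm(100, 0, 1), sp)
  Y <- outer(x, u) + matrix(rnorm(100 * k, 0, 0.15), 100, k)
  rownames(Y) <- sp
  f <- pgls_fit(Y, matrix(x, ncol = 1, dimnames = list(sp, "log_cs")), tr)
  v <- allometric_vector(f)
  expect_gt(abs(sum(v * u)), 0.95)

  # negated slopes flip the vector
  f2 <- pgls_fit(-Y, matrix(x, ncol = 1, dimnames = list(sp, "log_cs")), tr)
  expect_equal(allometric_vector(f2), -v, tolerance = 1e-9)
})

test_that("slope heterogeneity: power, type-I calibration and guards", {
  n <- 40
  tr <- fix_star(n)
  sp <- tr$tip.label
  grp <- rep(c("g1", "g2"), each = n / 2)

  # orthogonal true slopes, strong signal: minimal P
  set.seed(21)
  x <- setNames(rnorm(n), sp)
  Y <- matrix(NA_real_, n, 2, dimnames = list(sp, NULL))
  Y[grp == "g1", ] <- cbind(x[grp == "g1"], 0)
  Y[grp == "g2", ] <- cbind(0, x[grp == "g2"])
  Y <- Y + matrix(rnorm(2 * n, 0, 0.01), n, 2)
  het <- slope_heterogeneity_test(Y, x, grp, tr, n_perm = 199, seed = 3)
  expect_equal(het$P, 1 / 200)

  # identical slopes in all groups: rejection rate ~ alpha
  nrep <- 400
  rej <- logical(nrep)
  set.seed(300)
  seeds <- sample.int(1e6, nrep)
  for (r in seq_len(nrep)) {
    set.seed(seeds[r])
    x <- setNames(rnorm(n), sp)
    Y <- cbind(2 * x, -x) + matrix(rnorm(2 * n, 0, 0.3), n, 2)
    rownames(Y) <- sp
    rej[r] <- slope_heterogeneity_test(Y, x, grp, tr, n_perm = 99,
                                       seed = seeds[r] + 1)$P <= 0.05
  }
  se <- sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(mean(rej) - 0.05), 2 * se + 1e-12)

  # single usable group: error; tiny group: excluded with warning
  expect_error(suppressWarnings(
    slope_heterogeneity_test(Y, x, rep("g1", n), tr, n_perm = 99, seed = 1)),
    "at least 2 groups")
  grp3 <- grp; grp3[1:2] <- "tiny"
  expect_warning(
    slope_heterogeneity_test(Y, x, grp3, tr, n_perm = 99, seed = 1), "tiny")
})

test_that("scalar PGLS: exact fits, star-tree OLS and unbiased slope", {
  tr <- simulate_tree(10, seed = 31)
  sp <- tr$tip.label
  x <- setNames(rnorm(10), sp)
  res <- pgls_scalar(setNames(2 * x, sp), x, tr, n_perm = 99, seed = 1)
  expect_equal(unname(res$fit$coefficients["x", 1]), 2, tolerance = 1e-9)
  expect_equal(res$fit$R2, 1, tolerance = 1e-10)

  # BM-correlated noise on a 30-tip tree: slope unbiased over replicates
  tr30 <- simulate_tree(30, seed = 32)
  sp30 <- tr30$tip.label
  C <- ape::vcv(tr30)
  L <- t(chol(C))
  slope_true <- 0.8
  nrep <- 500
  est <- numeric(nrep)
  set.seed(33)
  for (r in seq_len(nrep)) {
    x <- setNames(as.numeric(L %*% rnorm(30)), sp30)
    y <- slope_true * x + as.numeric(L %*% rnorm(30, 0, 0.6))
    X <- matrix(x, ncol = 1, dimnames = list(sp30, "x"))
    est[r] <- pgls_fit(cbind(y = y), X, tr30)$coefficients["x", 1]
  }
  expect_lt(abs(mean(est) - slope_true), 2 * sd(est) / sqrt(nrep))
})
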