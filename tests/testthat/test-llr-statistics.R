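rand_psd <- function(k, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(k * k), k)
  crossprod(A) / k
}

test_that("P-matrix: two-point covariance, degenerate and sampling recovery", {
  v <- c(1, -2, 0.5)
  X <- rbind(v, -v)  # two specimens at +/- v around zero
  P <- p_matrix(X)
  expect_equal(P$P, 2 * tcrossprod(v), ignore_attr = TRUE)
  expect_equal(qr(P$P)$rank, 1L)

  expect_lt(max(abs(p_matrix(rbind(v, v, v))$P)), 1e-15)
  expect_error(p_matrix(rbind(v)), "at least 2")

  # 50 draws from a known Gaussian: Frobenius error shrinks with n
  S <- rand_psd(4, seed = 2)
  set.seed(3)
  frob <- sapply(c(50, 5000), function(n)
    norm(p_matrix(MASS::mvrnorm(n, rep(0, 4), S))$P - S, "F"))
  expect_lt(frob[2], frob[1])
  expect_lt(frob[1], norm(S, "F"))
})

test_that("projected variance: identity, Rayleigh extremum, brute-force sum", {
  k <- 6
  x <- rnorm(k); x <- x / sqrt(sum(x^2))
  expect_equal(projected_variance(diag(k), x), 1, tolerance = 1e-12)
  expect_equal(projected_variance(diag(k), x, normalize = TRUE), 1 / k,
               tolerance = 1e-12)

  P <- rand_psd(k, seed = 5)
  e <- eigen(P, symmetric = TRUE)
  expect_equal(projected_variance(P, e$vectors[, 1]), e$values[1],
               tolerance = 1e-10)

  set.seed(6)
  y <- rnorm(k); y <- y / sqrt(sum(y^2))
  brute <- 0
  for (i in 1:k) for (j in 1:k) brute <- brute + y[i] * P[i, j] * y[j]
  expect_equal(projected_variance(P, y), brute, tolerance = 1e-12)

  expect_warning(projected_variance(P, 2 * y), "renormalized")
})

test_that("Rayleigh bounds hold over random directions", {
  P <- rand_psd(5, seed = 7)
  e <- eigen(P, symmetric = TRUE)$values
  set.seed(8)
  for (i in 1:50) {
    x <- rnorm(5); x <- x / sqrt(sum(x^2))
    v <- projected_variance(P, x)
    expect_gte(v, min(e) - 1e-12)
    expect_lte(v, max(e) + 1e-12)
  }
  # normalized projected variance over an orthonormal basis sums to 1
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  tot <- sum(sapply(1:5, function(j)
    projected_variance(P, Q[, j], normalize = TRUE)))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("random-vector null matches the analytic mean trace(P)/k", {
  k <- 8
  P <- rand_psd(k, seed = 9)
  nv <- random_vector_null(P, n_vectors = 20000, seed = 10)
  mc_se <- sd(nv$values) / sqrt(nv$n_vectors)
  expect_lt(abs(nv$mean - sum(diag(P)) / k), 4 * mc_se)

  # isotropic P: every direction gives exactly sigma^2
  iso <- random_vector_null(diag(0.3, k), n_vectors = 100, seed = 11)
  expect_lt(max(abs(iso$values - 0.3)), 1e-12)

  # seeded determinism
  a <- random_vector_null(P, n_vectors = 499, seed = 12)
  b <- random_vector_null(P, n_vectors = 499, seed = 12)
  expect_identical(a$values, b$values)
})

test_that("Vrel: isotropic 0, rank-1 1, equals r^2 for two equal traits", {
  expect_equal(integration_effect_size(diag(4), n = 50)$Vrel, 0)
  v <- c(1, 2, -1, 0.5)
  expect_equal(integration_effect_size(tcrossprod(v), n = 50)$Vrel, 1,
               tolerance = 1e-12)
  for (r in seq(0.1, 0.9, by = 0.2)) {
    P2 <- rbind(c(1, r), c(r, 1))
    # eigen-oracle: direct eigenvalue computation
    ev <- eigen(P2, only.values = TRUE)$values
    vrel_ref <- sum((ev - mean(ev))^2) / (sum(ev)^2 * (2 - 1) / 2)
    got <- integration_effect_size(P2, n = 50)$Vrel
    expect_equal(got, r^2, tolerance = 1e-10)
    expect_equal(got, vrel_ref, tolerance = 1e-12)
  }
  expect_error(integration_effect_size(matrix(1, 1, 1)), "single trait")
  # Zrel increases with Vrel at fixed n
  z <- sapply(c(0.2, 0.5, 0.8), function(r)
    integration_effect_size(rbind(c(1, r), c(r, 1)), n = 40)$Zrel)
  expect_true(all(diff(z) > 0))
})

test_that("divergence magnitude and vector match elementary oracles", {
  expect_equal(divergence_magnitude(c(1, 2), c(1, 2)), 0)
  expect_equal(divergence_magnitude(c(3, 4), c(0, 0)), 5)
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(divergence_magnitude(a, b), sqrt(sum((a - b)^2)),
                 tolerance = 1e-12)
    dv <- divergence_vector(a, b)
    expect_equal(dv$raw, a - b, tolerance = 1e-15)
    expect_equal(sqrt(sum(dv$unit^2)), 1, tolerance = 1e-12)
  }
  expect_error(divergence_magnitude(1:3, 1:4), "axis mismatch")
  expect_true(divergence_vector(c(1, 2), c(1, 2))$degenerate)

  # ancestor + c * x diverges at zero angle to x
  x <- rnorm(6); x <- x / sqrt(sum(x^2))
  anc <- rnorm(6)
  dv <- divergence_vector(anc + 0.3 * x, anc)
  expect_equal(vector_angle(dv$raw, x), 0, tolerance = 1e-5)
})

test_that("vector angles: closed forms, symmetry, scale invariance, folding", {
  expect_equal(vector_angle(c(1, 1), c(1, 1)), 0, tolerance = 1e-5)
  expect_equal(vector_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(vector_angle(c(1, 0), c(1, 1) / sqrt(2)), 45, tolerance = 1e-10)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(vector_angle(a, b), vector_angle(b, a))
  expect_equal(vector_angle(3.7 * a, b), vector_angle(a, 0.21 * b),
               tolerance = 1e-10)
  expect_equal(vector_angle(a, -a), 180)
  expect_equal(vector_angle(a, -a, fold = TRUE), 0, tolerance = 1e-6)
  expect_error(vector_angle(a, rep(0, 5)), "zero vector")
})

test_that("random angles are uniform at k = 2 and concentrate near 90 at high k", {
  nl <- random_angle_null(2, n = 10000, seed = 14)
  ks <- suppressWarnings(stats::ks.test(nl$samples, "punif", 0, 180))
  expect_gt(ks$p.value, 0.01)

  hi <- random_angle_null(75, n = 10000, seed = 15)
  expect_lt(abs(hi$mean - 90), 0.5)

  sds <- sapply(c(3, 10, 30, 75), function(k)
    random_angle_null(k, n = 4000, seed = 100 + k)$sd)
  expect_true(all(diff(sds) < 0))
})

test_that("alignment significance: identical vectors minimal P, 90 deg is null center", {
  a <- rnorm(10)
  s <- angle_significance(a, a, n_random = 999, seed = 16)
  expect_equal(s$P, 1 / 1000)
  expect_equal(s$angle, 0)

  # an observed right angle in high dimension sits mid-null
  b <- c(1, rep(0, 39)); d <- c(0, 1, rep(0, 38))
  s90 <- angle_significance(b, d, n_random = 20000, seed = 17)
  expect_lt(abs(s90$P - 0.5), 0.02)

  s1 <- angle_significance(a, a + 0.5, n_random = 999, seed = 18)
  s2 <- angle_significance(a, a + 0.5, n_random = 999, seed = 18)
  expect_identical(s1$P, s2$P)
})

test_that("KS against the angle null: type-I rate, extreme shift, ECDF oracle", {
  # observed sampled from the very same process: rejection ~ alpha
  nrep <- 400
  rej <- logical(nrep)
  set.seed(19)
  seeds <- sample.int(1e6, nrep)
  for (r in seq_len(nrep)) {
    null <- random_angle_null(10, n = 1000, seed = seeds[r])
    obs <- random_angle_null(10, n = 100, seed = seeds[r] + 1)$samples
    rej[r] <- ks_angles_vs_null(obs, null)$P <= 0.05
  }
  se <- sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(mean(rej) - 0.05), 2 * se + 1e-12)

  # all-zero observed angles: D near 1, P ~ 0
  null <- random_angle_null(20, n = 5000, seed = 20)
  ex <- ks_angles_vs_null(rep(0, 20), null)
  expect_gt(ex$D, 0.99)
  expect_lt(ex$P, 1e-6)

  # D equals the brute-force maximum ECDF gap
  obs <- random_angle_null(5, n = 50, seed = 21)$samples
  got <- ks_angles_vs_null(obs, null)
  grid <- sort(c(obs, null$samples))
  gap <- max(abs(ecdf(obs)(grid) - ecdf(null$samples)(grid)))
  expect_equal(got$D, gap, tolerance = 1e-12)

  expect_error(ks_angles_vs_null(c(1, 2), null), "at least 5")
})

test_that("ecology axis recovers a planted diet direction", {
  tr <- simulate_tree(80, seed = 22)
  sp <- tr$tip.label
  k <- 10
  set.seed(23)
  u <- rnorm(k); u <- u / sqrt(sum(u^2))
  pos <- setNames(rnorm(80, 0, 1), sp)
  Y <- outer(pos, u) + matrix(rnorm(80 * k, 0, 0.05), 80, k)
  rownames(Y) <- sp
  pg <- setNames(50 + 20 * pos, sp)      # exact linear readout of position
  eco <- ecology_axis(Y, pg, tr)
  expect_lt(vector_angle(eco$axis, u, fold = TRUE), 5)
  expect_equal(eco$n_used, 80L)

  # species with missing diet are excluded
  pg2 <- pg; pg2[1:30] <- NA
  expect_equal(ecology_axis(Y, pg2, tr)$n_used, 50L)

  expect_error(ecology_axis(Y, setNames(rep(40, 80), sp), tr), "constant")
})

test_that("trend surface: exact quadratic recovery and normal-equations oracle", {
  set.seed(24)
  uv <- matrix(rnorm(60), 30, 2)
  beta <- c(2, 1, -1, 0.5, 0.25, -0.75)
  y <- cbind(1, uv[, 1], uv[, 2], uv[, 1]^2, uv[, 1] * uv[, 2],
             uv[, 2]^2) %*% beta
  ts <- trend_surface(uv, as.numeric(y), n_perm = 99, seed = 25)
  expect_equal(unname(ts$coefficients), beta, tolerance = 1e-8)
  expect_equal(ts$r_squared, 1, tolerance = 1e-10)
  expect_equal(ts$P, 1 / 100)
  expect_equal(ts$evaluate(0.5, -0.5),
               sum(beta * c(1, 0.5, -0.5, 0.25, -0.25, 0.25)),
               tolerance = 1e-8)

  # noisy response: coefficients equal an independent normal-equations solve
  y2 <- as.numeric(y) + rnorm(30, 0, 0.5)
  ts2 <- trend_surface(uv, y2, n_perm = 99, seed = 26)
  Bm <- cbind(1, uv[, 1], uv[, 2], uv[, 1]^2, uv[, 1] * uv[, 2], uv[, 2]^2)
  ref <- solve(t(Bm) %*% Bm, t(Bm) %*% y2)
  expect_equal(unname(ts2$coefficients), as.numeric(ref), tolerance = 1e-8)

  # constant response: non-intercept coefficients all zero
  ts3 <- trend_surface(uv, rep(4, 30), n_perm = 99, seed = 27)
  expect_lt(max(abs(ts3$coefficients[-1])), 1e-10)
})
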