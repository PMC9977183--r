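#' Simulate a pure-birth phylogeny rescaled to unit depth
#'
#' @param n_tips number of tips (`>= 3`).
#' @param seed integer seed.
#' @return Ultrametric [ape::phylo] with unit root-to-tip depth and tips
#'   labelled `sp001, sp002, ...`.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  stopifnot(n_tips >= 3L)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tr
}

#' Reference shape system for simulation
#'
#' A reproducible mean landmark configuration with an orthonormal basis of
#' its shape tangent space, one basis direction of which is designated the
#' "face elongation" (allometric) direction: the tangent-space component of
#' a uniform stretch of the configuration along its first coordinate axis.
#' All simulated shape variation is expressed in this basis.
#'
#' @param p number of landmarks (`>= 8`; default 28, giving a tangent
#'   dimension `k = 3p - 7 = 77`).
#' @param seed integer seed.
#' @return List with `mean_shape` (`p x 3`, centered, unit centroid size),
#'   `basis` (`3p x k` orthonormal; column 1 is the allometric direction),
#'   `crea_tangent` (the allometric direction in basis coordinates, i.e.
#'   `e1`), `crea_flat` (the same direction as a `3p` displacement field),
#'   `p`, `k`.
#' @export
make_shape_system <- function(p = 28L, seed = 1L) {
  stopifnot(p >= 8L)
  if (!is.null(seed)) set.seed(seed)
  ms <- matrix(stats::rnorm(p * 3L), p, 3L)
  ms <- sweep(ms, 2, colMeans(ms))
  ms <- ms / sqrt(sum(ms^2))
  B0 <- tangent_basis(ms)
  k <- ncol(B0)
  # elongation along axis 1, projected into tangent space
  w <- as.numeric(cbind(ms[, 1], 0, 0))
  ct <- as.numeric(crossprod(B0, w))
  ct <- ct / sqrt(sum(ct^2))
  # rotate the basis so that the first coordinate is the allometric direction
  Q <- qr.Q(qr(cbind(ct, matrix(stats::rnorm(k * (k - 1L)), k))))
  if (sum(Q[, 1] * ct) < 0) Q[, 1] <- -Q[, 1]
  B <- B0 %*% Q
  crea_tangent <- c(1, rep(0, k - 1L))
  list(mean_shape = ms, basis = B, crea_tangent = crea_tangent,
       crea_flat = B[, 1], p = p, k = k)
}

#' Eccentric covariance matrix around a designated direction
#'
#' `trace * (ecc * v v' + (1 - ecc) / (k - 1) * (I - v v'))`: a PSD matrix
#' of given trace whose leading eigenvalue is the fraction `ecc` of the
#' trace, along direction `v`, with the remaining variance isotropic.
#'
#' @param k dimension.
#' @param eccentricity leading-eigenvalue fraction of the trace in `[1/k, 1]`.
#' @param trace total variance.
#' @param v unit direction of the leading axis (default `e1`).
#' @return `k x k` symmetric PSD matrix.
#' @export
eccentric_cov <- function(k, eccentricity, trace = 1, v = NULL) {
  stopifnot(eccentricity >= 0, eccentricity <= 1)
  if (is.null(v)) v <- c(1, rep(0, k - 1L))
  v <- v / sqrt(sum(v^2))
  vvt <- tcrossprod(v)
  trace * (eccentricity * vvt + (1 - eccentricity) / (k - 1) * (diag(k) - vvt))
}

# unit vector at a given angle (degrees) to `ref` within the span of
# ref and a random orthogonal complement direction
.vector_at_angle <- function(ref, angle_deg) {
  k <- length(ref)
  ref <- ref / sqrt(sum(ref^2))
  w <- stats::rnorm(k)
  w <- w - sum(w * ref) * ref
  w <- w / sqrt(sum(w^2))
  a <- angle_deg * pi / 180
  cos(a) * ref + sin(a) * w
}

#' Simulate species means, sizes and diet under Brownian motion
#'
#' Species-mean tangent shapes evolve by multivariate Brownian motion on the
#' tree with a rate matrix elongated along the allometric direction
#' (fraction `eccentricity` of the total rate). Log centroid size is the
#' species' position along that direction divided by the allometric slope,
#' plus independent Brownian noise, so that shape and size covary exactly as
#' an allometric line of least resistance implies. Percent grass in diet is
#' a logistic readout of relative size with coupling strength
#' `diet_coupling` (0 decouples diet from size entirely).
#'
#' @param tree [ape::phylo] (unit depth assumed for the default rates).
#' @param system a [make_shape_system()] result.
#' @param eccentricity fraction of the evolutionary rate along the
#'   allometric direction (default 0.6).
#' @param total_rate trace of the true rate matrix per unit branch length
#'   (default 0.01 squared shape units).
#' @param allometric_slope shape displacement per unit log centroid size
#'   (default 0.1).
#' @param size_bm_sd Brownian standard deviation of the size noise over unit
#'   depth (default 0.15 log units).
#' @param base_log_cs log centroid size at the root (default `log(10)`).
#' @param diet_coupling logistic coupling of diet to size (default 2).
#' @param grass_missing fraction of species with missing diet data
#'   (default 0.25).
#' @param seed integer seed.
#' @return List with `means` (`n x k`, rownames = tips), `log_cs`,
#'   `percent_grass` (named vectors), and `truth` (the generating
#'   parameters: `rate_matrix_true`, `crea_direction`, `allometric_slope`,
#'   `diet_coupling`, `seed`).
#' @export
simulate_species <- function(tree, system, eccentricity = 0.6,
                             total_rate = 0.01, allometric_slope = 0.1,
                             size_bm_sd = 0.15, base_log_cs = log(10),
                             diet_coupling = 2, grass_missing = 0.25,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- system$k
  n <- length(tree$tip.label)
  C_true <- eccentric_cov(k, eccentricity, trace = total_rate)
  rm <- structure(list(rates = C_true, root = rep(0, k), m = k,
                       n = n, loglik = NA_real_, method = "true"),
                  class = "rate_matrix")
  means <- simulate_bm_tips(rm, tree, n_reps = 1L)[, , 1]
  proj <- means[, 1]  # position along the allometric direction (= e1)
  Ctree <- ape::vcv(tree)
  size_noise <- as.numeric(t(chol(Ctree)) %*% stats::rnorm(n, 0, size_bm_sd))
  log_cs <- base_log_cs + proj / allometric_slope + size_noise
  names(log_cs) <- tree$tip.label
  zsize <- as.numeric(scale(log_cs))
  pg <- 100 * stats::plogis(diet_coupling * zsize + stats::rnorm(n))
  if (grass_missing > 0)
    pg[sample.int(n, round(grass_missing * n))] <- NA_real_
  names(pg) <- tree$tip.label
  list(means = means, log_cs = log_cs, percent_grass = pg,
       truth = list(rate_matrix_true = C_true,
                    crea_direction = system$crea_tangent,
                    eccentricity = eccentricity,
                    allometric_slope = allometric_slope,
                    diet_coupling = diet_coupling, seed = seed))
}

#' Simulate intraspecific specimen samples around species means
#'
#' Each species' specimens are drawn from a Gaussian P-matrix of controlled
#' trace, eccentricity and alignment (angle of its leading axis to the
#' allometric direction), mapped back into landmark space through the shape
#' system's deformation basis, perturbed by isotropic digitizing noise, and
#' finally given an arbitrary rigid motion and a scale of
#' `exp(log_cs + individual noise)` -- so that the downstream Procrustes
#' superimposition has real work to do.
#'
#' @param means `m x k` species-mean tangent matrix (rownames = species).
#' @param log_cs named species log centroid sizes.
#' @param system a [make_shape_system()] result.
#' @param n_specimens integer vector (recycled or named) of specimens per
#'   species.
#' @param p_trace trace of each species' true P-matrix (default 0.015).
#' @param p_eccentricity leading-eigenvalue fraction of each P (default 0.3).
#' @param alignment_deg angle, in degrees, of each P's leading axis to the
#'   allometric direction; vector recycled over species (default 30).
#' @param noise_sd digitizing noise standard deviation as a fraction of the
#'   mean shape's centroid size (default 0.01).
#' @param size_indiv_sd individual log-size standard deviation (default
#'   0.05).
#' @param seed integer seed.
#' @return List with `landmarks` (a [landmark_set()]) and `truth`
#'   (per-species `P_true` list, `alignment_true`, `eccentricity_true`).
#' @export
simulate_populations <- function(means, log_cs, system, n_specimens,
                                 p_trace = 0.015, p_eccentricity = 0.3,
                                 alignment_deg = 30, noise_sd = 0.01,
                                 size_indiv_sd = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  means <- as.matrix(means)
  spp <- rownames(means)
  m <- length(spp); k <- system$k; p <- system$p
  n_specimens <- rep_len(as.integer(n_specimens), m)
  alignment_deg <- rep_len(alignment_deg, m)
  stopifnot(all(n_specimens >= 1L))
  ms_flat <- as.numeric(system$mean_shape)
  P_true <- vector("list", m); names(P_true) <- spp
  cfgs <- list(); spec_id <- character(); spec_sp <- character()
  for (s in seq_len(m)) {
    v <- .vector_at_angle(system$crea_tangent, alignment_deg[s])
    P <- eccentric_cov(k, p_eccentricity, trace = p_trace, v = v)
    P_true[[s]] <- P
    ns <- n_specimens[s]
    dev <- if (ns > 0) MASS::mvrnorm(ns, mu = means[s, ], Sigma = P) else NULL
    dev <- rbind(dev)
    for (i in seq_len(ns)) {
      flat <- ms_flat + as.numeric(system$basis %*% dev[i, ])
      cfg <- matrix(flat, p, 3L)
      cfg <- cfg + matrix(stats::rnorm(p * 3L, 0, noise_sd), p, 3L)
      # arbitrary rigid motion + scale
      R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
      if (det(R) < 0) R[, 1] <- -R[, 1]
      size <- exp(log_cs[spp[s]] + stats::rnorm(1, 0, size_indiv_sd))
      cfg <- size * (cfg %*% R)
      cfg <- sweep(cfg, 2, stats::rnorm(3, 0, 5), "+")
      cfgs[[length(cfgs) + 1L]] <- cfg
      spec_id <- c(spec_id, sprintf("%s_%03d", spp[s], i))
      spec_sp <- c(spec_sp, spp[s])
    }
  }
  list(landmarks = landmark_set(cfgs, spec_id, spec_sp),
       truth = list(P_true = P_true,
                    alignment_true = stats::setNames(alignment_deg, spp),
                    eccentricity_true = p_eccentricity,
                    p_trace = p_trace, seed = seed))
}

# assign nested clade labels by cutting the tree at two heights
.clade_groups <- function(tree, h, prefix) {
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  grp <- rep(NA_character_, ntip)
  counter <- 0L
  crossing <- which(depths[tree$edge[, 1]] < h & depths[tree$edge[, 2]] >= h)
  for (e in crossing) {
    node <- tree$edge[e, 2]
    tips <- if (node <= ntip) tree$tip.label[node] else
      ape::extract.clade(tree, node)$tip.label
    counter <- counter + 1L
    grp[match(tips, tree$tip.label)] <- sprintf("%s%02d", prefix, counter)
  }
  stats::setNames(grp, tree$tip.label)
}

#' Simulate a complete study bundle with ground truth
#'
#' End-to-end generator mirroring the empirical design: ~130 species means
#' evolving under Brownian motion with a rate matrix elongated along the
#' allometric direction, a subset of species sampled densely enough to enter
#' the intraspecific set, nested family/subfamily labels cut from the tree,
#' log centroid size coupled to the allometric position, and percent grass
#' coupled to size.
#'
#' @param n_species total species count (default 130).
#' @param n_intraspecific species receiving dense specimen sampling
#'   (default 49).
#' @param specimens_range inclusive range of specimen counts for the densely
#'   sampled species (default `c(27, 100)`).
#' @param p number of landmarks (default 28).
#' @param min_n intraspecific threshold passed to [assemble_study()].
#' @param seed integer seed.
#' @param ... further arguments to [simulate_species()] and
#'   [simulate_populations()] (matched by name).
#' @return List with `study` (an `aligned_study`), `truth` (generator ground
#'   truth incl. the shape `system`), and `species_sim` (means, sizes, diet).
#' @export
simulate_study <- function(n_species = 130L, n_intraspecific = 49L,
                           specimens_range = c(27L, 100L), p = 28L,
                           min_n = 27L, seed = 1L, ...) {
  dots <- list(...)
  set.seed(seed)
  tree <- simulate_tree(n_species, seed = seed)
  system <- make_shape_system(p, seed = seed + 1L)
  sp_args <- dots[intersect(names(dots), names(formals(simulate_species)))]
  sim <- do.call(simulate_species,
                 c(list(tree = tree, system = system, seed = seed + 2L),
                   sp_args))
  set.seed(seed + 3L)
  dense <- sample(tree$tip.label, n_intraspecific)
  n_spec <- stats::setNames(rep(1L, n_species), tree$tip.label)
  n_spec[dense] <- sample(seq(specimens_range[1], specimens_range[2]),
                          n_intraspecific, replace = TRUE)
  pop_args <- dots[intersect(names(dots),
                             names(formals(simulate_populations)))]
  pops <- do.call(simulate_populations,
                  c(list(means = sim$means, log_cs = sim$log_cs,
                         system = system,
                         n_specimens = n_spec[rownames(sim$means)],
                         seed = seed + 4L),
                    pop_args))
  fam <- .clade_groups(tree, 0.20, "family_")
  subfam <- .clade_groups(tree, 0.45, "subfam_")
  taxa <- data.frame(species_id = tree$tip.label,
                     family = fam[tree$tip.label],
                     subfamily = subfam[tree$tip.label],
                     percent_grass = sim$percent_grass[tree$tip.label],
                     stringsAsFactors = FALSE)
  study <- assemble_study(pops$landmarks, taxa, tree, min_n = min_n)
  list(study = study,
       truth = c(sim$truth, pops$truth, list(system = system, tree = tree)),
       species_sim = sim)
}

#' Express a generator-space direction in an analysis tangent basis
#'
#' Maps a displacement direction defined at the generator's mean shape into
#' the tangent space of a fitted GPA: the generator mean is optimally
#' rotated onto the GPA consensus, the same rotation is applied to the
#' displacement field, and the result is projected onto the GPA tangent
#' basis and normalized. Used to compare estimated axes with generator
#' truth.
#'
#' @param flat_direction `3p` displacement vector at the generator mean
#'   (e.g. `system$crea_flat`).
#' @param system the generating [make_shape_system()].
#' @param g the `gpa_result` whose tangent basis is the target.
#' @return Unit vector of length `k` in the GPA tangent basis.
#' @export
truth_in_tangent <- function(flat_direction, system, g) {
  stopifnot(inherits(g, "gpa_result"), !is.null(g$basis))
  ms <- system$mean_shape
  ms <- sweep(ms, 2, colMeans(ms))
  ms <- ms / sqrt(sum(ms^2))
  s <- svd(crossprod(ms, g$consensus))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) { u <- s$u; u[, 3] <- -u[, 3]; R <- u %*% t(s$v) }
  D <- matrix(flat_direction, system$p, 3L) %*% R
  v <- as.numeric(crossprod(g$basis, as.numeric(D)))
  v / sqrt(sum(v^2))
}
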