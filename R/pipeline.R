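#' Analysis configuration
#'
#' Bundle of the tunable parameters of the full analysis, with the defaults
#' used throughout: the intraspecific threshold (27 specimens), 999
#' permutations, 499 random vectors per species, 10000 random angles, a
#' 5-axis rate matrix, and 95/99% confidence contours.
#'
#' @param min_n intraspecific specimen threshold.
#' @param n_perm permutations for all residual-randomization tests.
#' @param n_random_vectors random directions per species for the projected
#'   variance null.
#' @param n_random_angles draws for the random-angle null.
#' @param n_pcs_rate_matrix ordination axes fed to the rate matrix.
#' @param ci_levels confidence contour levels in (0, 1).
#' @param normalize_vproj report and test trace-normalized projected
#'   variance (the proportion interpretation)?
#' @param fold_angles fold angles to `[0, 90]` degrees?
#' @param divergence_axes axes used for divergence magnitudes (`NULL` = all
#'   retained axes).
#' @param z_transform effect-size transform of F (`"identity"` or `"log"`).
#' @param seed master integer seed; every stochastic stage derives its own
#'   seed from it.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(min_n = 27L, n_perm = 999L,
                            n_random_vectors = 499L,
                            n_random_angles = 10000L,
                            n_pcs_rate_matrix = 5L,
                            ci_levels = c(0.95, 0.99),
                            normalize_vproj = TRUE, fold_angles = FALSE,
                            divergence_axes = NULL,
                            z_transform = "identity", seed = 1L) {
  stopifnot(min_n >= 1L, n_perm >= 1L, n_random_vectors >= 1L,
            n_random_angles >= 1L, n_pcs_rate_matrix >= 1L,
            all(ci_levels > 0 & ci_levels < 1))
  structure(list(min_n = as.integer(min_n), n_perm = as.integer(n_perm),
                 n_random_vectors = as.integer(n_random_vectors),
                 n_random_angles = as.integer(n_random_angles),
                 n_pcs_rate_matrix = as.integer(n_pcs_rate_matrix),
                 ci_levels = ci_levels, normalize_vproj = normalize_vproj,
                 fold_angles = fold_angles, divergence_axes = divergence_axes,
                 z_transform = z_transform, seed = as.integer(seed)),
            class = "analysis_config")
}

# subfamily MRCA node for each species, NA when the subfamily has < 2 tips
.subfamily_mrca <- function(tree, species_tbl) {
  vapply(species_tbl$species_id, function(sp) {
    sf <- species_tbl$subfamily[species_tbl$species_id == sp]
    if (is.na(sf)) return(NA_integer_)
    tips <- species_tbl$species_id[!is.na(species_tbl$subfamily) &
                                     species_tbl$subfamily == sf]
    tips <- intersect(tips, tree$tip.label)
    if (length(tips) < 2L) return(NA_integer_)
    as.integer(ape::getMRCA(tree, tips))
  }, integer(1))
}

#' Run the complete line-of-least-resistance analysis
#'
#' Orchestrates every stage on an assembled study: joint Procrustes
#' superimposition of all specimens, species means, the evolutionary
#' allometry PGLS (with the subfamily slope-heterogeneity test), PCA /
#' phylogenetic PCA / phylogenetically aligned ordinations with specimen
#' projection and per-family densities, the Brownian-motion rate matrix with
#' confidence contours and per-species outlier flags, the per-species
#' projected-variance / integration / divergence records, the divergence
#' PGLS tests, and the ecology-axis statistics. Every stochastic stage is
#' seeded from `config$seed`.
#'
#' @param study an `aligned_study` (see [assemble_study()],
#'   [simulate_study()]).
#' @param config an [analysis_config()].
#' @return A list of class `llr_report`; see the elements `allometry`,
#'   `ordinations`, `rate_matrix`, `contours`, `llr`, `divergence_pgls`,
#'   `ecology`, `family_density`, plus the fitted `gpa` and `means`.
#' @export
run_full_analysis <- function(study, config = analysis_config()) {
  stopifnot(inherits(study, "aligned_study"))
  seed <- config$seed

  g <- gpa(study$landmarks)
  means <- species_means(g)
  spp <- rownames(means$shape)
  tree <- ape::keep.tip(study$tree, spp)

  ## -- evolutionary allometry -------------------------------------------
  X <- matrix(means$log_cs[spp], ncol = 1, dimnames = list(spp, "log_cs"))
  allo_fit <- pgls_fit(means$shape[spp, , drop = FALSE], X, tree)
  allo_perm <- rrpp_significance(allo_fit, n_perm = config$n_perm,
                                 seed = seed + 11L,
                                 z_transform = config$z_transform)
  crea <- allometric_vector(allo_fit, "log_cs")
  sf <- stats::setNames(study$species$subfamily, study$species$species_id)[spp]
  slope_het <- tryCatch(
    slope_heterogeneity_test(means$shape[spp, , drop = FALSE],
                             means$log_cs[spp], sf, tree,
                             n_perm = config$n_perm, seed = seed + 12L,
                             z_transform = config$z_transform),
    error = function(e) NULL)
  allometry <- data.frame(
    term = c("log_cs", if (!is.null(slope_het)) "log_cs:subfamily"),
    R2 = c(allo_fit$R2, if (!is.null(slope_het)) NA_real_),
    F = c(allo_perm$F, if (!is.null(slope_het)) slope_het$F),
    Z = c(allo_perm$Z, if (!is.null(slope_het)) slope_het$Z),
    P = c(allo_perm$P, if (!is.null(slope_het)) slope_het$P))

  ## -- ordinations -------------------------------------------------------
  ord_pca <- pca(means$shape)
  ord_ppca <- phylo_pca(means$shape, tree)
  ord_paca <- paca(means$shape, tree)
  spec_scores <- project_specimens(ord_pca, unclass(g$tangent))
  fam <- stats::setNames(study$species$family, study$species$species_id)
  dens <- family_density(spec_scores[, 1], g$species_id, fam[g$species_id])

  ## -- BM rate matrix and contours --------------------------------------
  m_rm <- min(config$n_pcs_rate_matrix, ncol(ord_pca$scores))
  rm_scores <- ord_pca$scores[, seq_len(m_rm), drop = FALSE]
  rmat <- fit_bm_rate_matrix(rm_scores, tree)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(depths) <- tree$tip.label
  contours <- lapply(config$ci_levels, function(lv) {
    inside <- vapply(spp, function(sp) {
      d <- bm_tip_distribution(rmat, depths[sp])
      ci_contour(d, lv)$inside(rm_scores[sp, ])
    }, logical(1))
    ell <- ci_contour(bm_tip_distribution(rmat, max(depths), axes = 1:2), lv)
    list(level = lv, inside = inside, ellipse = ell$ellipse,
         outline = ell$outline(200L))
  })
  names(contours) <- paste0("level_", config$ci_levels)

  ## -- per-species LLR records ------------------------------------------
  intra <- study$species$species_id[study$species$in_intraspecific_set]
  intra <- intersect(intra, spp)
  mrca <- .subfamily_mrca(tree, study$species[study$species$species_id %in%
                                                spp, , drop = FALSE])
  div_axes <- if (is.null(config$divergence_axes))
    seq_len(ncol(ord_pca$scores)) else config$divergence_axes
  anc_scores <- ancestral_states(ord_pca$scores, tree)
  anc_tangent <- ancestral_states(means$shape, tree)
  norm <- config$normalize_vproj
  llr <- do.call(rbind, lapply(seq_along(intra), function(i) {
    sp <- intra[i]
    tg <- unclass(g$tangent)[g$species_id == sp, , drop = FALSE]
    Pm <- p_matrix(tg, species_id = sp)
    node <- mrca[sp]
    if (!is.na(node)) {
      anc_s <- anc_scores[as.character(node), div_axes]
      D <- divergence_magnitude(ord_pca$scores[sp, div_axes], anc_s)
      dv <- divergence_vector(means$shape[sp, ],
                              anc_tangent[as.character(node), ])
      ang <- if (dv$degenerate) NA_real_ else
        vector_angle(dv$raw, crea, fold = config$fold_angles)
      vproj_div <- if (dv$degenerate) NA_real_ else
        projected_variance(Pm, dv$unit, normalize = norm)
    } else {
      D <- NA_real_; ang <- NA_real_; vproj_div <- NA_real_
    }
    nullv <- random_vector_null(Pm, n_vectors = config$n_random_vectors,
                                seed = seed + 1000L + i, normalize = norm)
    ies <- integration_effect_size(Pm)
    data.frame(species_id = sp,
               Vproj_crea = projected_variance(Pm, crea, normalize = FALSE),
               Vproj_crea_frac = projected_variance(Pm, crea, normalize = TRUE),
               Vproj_random_mean = nullv$mean,
               Vproj_divergence = vproj_div,
               Vrel = ies$Vrel, Zrel = ies$Zrel,
               divergence_D = D, angle_deg = ang,
               centroid_size = means$centroid_size[sp],
               n_specimens = Pm$n)
  }))

  ## -- divergence PGLS ---------------------------------------------------
  divergence_pgls <- NULL
  ok <- llr$species_id[is.finite(llr$divergence_D)]
  if (length(ok) >= 4L) {
    sub_tree <- ape::keep.tip(tree, ok)
    dd <- stats::setNames(llr$divergence_D, llr$species_id)[ok]
    preds <- list(
      Vproj_crea = if (norm) "Vproj_crea_frac" else "Vproj_crea",
      Zrel = "Zrel", angle = "angle_deg")
    divergence_pgls <- do.call(rbind, lapply(names(preds), function(nm) {
      xv <- stats::setNames(llr[[preds[[nm]]]], llr$species_id)[ok]
      if (!all(is.finite(xv))) return(NULL)
      res <- pgls_scalar(dd, xv, sub_tree, n_perm = config$n_perm,
                         seed = seed + 21L + match(nm, names(preds)))
      data.frame(predictor = nm, slope = res$fit$coefficients[2, 1],
                 R2 = res$fit$R2, F = res$perm$F, Z = res$perm$Z,
                 P = res$perm$P)
    }))
  }

  ## -- ecology -----------------------------------------------------------
  pg <- stats::setNames(study$species$percent_grass,
                        study$species$species_id)[spp]
  ecology <- NULL
  if (sum(is.finite(pg)) >= 10L) {
    eco <- ecology_axis(means$shape[spp, , drop = FALSE], pg, tree)
    ang <- angle_significance(crea, eco$axis,
                              n_random = config$n_random_angles,
                              seed = seed + 31L)
    surf <- trend_surface(ord_pca$scores[spp, 1:2], pg[spp],
                          n_perm = config$n_perm, seed = seed + 32L)
    ecology <- list(axis = eco$axis, n_used = eco$n_used,
                    angle_to_crea = ang$angle, angle_P = ang$P,
                    surface = surf)
  }

  ## -- divergence angles vs random-angle null ---------------------------
  ks <- NULL
  angs <- llr$angle_deg[is.finite(llr$angle_deg)]
  if (length(angs) >= 5L) {
    null <- random_angle_null(ncol(means$shape),
                              n = config$n_random_angles, seed = seed + 41L)
    ks <- c(ks_angles_vs_null(angs, null), list(null = null))
  }

  structure(list(allometry = allometry, crea = crea,
                 slope_heterogeneity = slope_het,
                 ordinations = list(pca = ord_pca, ppca = ord_ppca,
                                    paca = ord_paca),
                 specimen_scores = spec_scores,
                 family_density = dens,
                 rate_matrix = rmat, contours = contours,
                 llr = llr, divergence_pgls = divergence_pgls,
                 angle_ks = ks, ecology = ecology,
                 gpa = g, means = means, tree = tree, config = config),
            class = "llr_report")
}

#' @export
print.llr_report <- function(x, ...) {
  cat("llr_report\n")
  cat(sprintf("  allometry: R2 = %.3f, F = %.3f, Z = %.3f, P = %.4g\n",
              x$allometry$R2[1], x$allometry$F[1], x$allometry$Z[1],
              x$allometry$P[1]))
  cat(sprintf("  ordination: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$ordinations$pca$var_fraction[1],
              100 * x$ordinations$pca$var_fraction[2]))
  cat("  intraspecific species with LLR records:", nrow(x$llr), "\n")
  if (!is.null(x$ecology))
    cat(sprintf("  ecology axis angle to CREA: %.2f deg (P = %.4g)\n",
                x$ecology$angle_to_crea, x$ecology$angle_P))
  invisible(x)
}

#' Write an analysis report to a directory of CSV/JSON files
#'
#' @param report an `llr_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "llr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  w(report$allometry, "allometry.csv")
  for (nm in names(report$ordinations)) {
    o <- report$ordinations[[nm]]
    w(data.frame(species_id = rownames(o$scores), o$scores,
                 check.names = FALSE), paste0("scores_", nm, ".csv"))
  }
  w(report$llr, "llr_records.csv")
  if (!is.null(report$divergence_pgls))
    w(report$divergence_pgls, "divergence_pgls.csv")
  w(report$family_density, "family_density.csv")
  meta <- list(
    config = unclass(report$config),
    var_fraction = lapply(report$ordinations,
                          function(o) unname(o$var_fraction)),
    rate_matrix = list(rates = unname(report$rate_matrix$rates),
                       root = unname(report$rate_matrix$root),
                       loglik = report$rate_matrix$loglik),
    contours = lapply(report$contours, function(ct)
      list(level = ct$level, n_outside = sum(!ct$inside),
           outside = names(which(!ct$inside)))),
    ecology = if (!is.null(report$ecology))
      list(angle_to_crea = report$ecology$angle_to_crea,
           angle_P = report$ecology$angle_P,
           surface_r2 = report$ecology$surface$r_squared,
           surface_P = report$ecology$surface$P),
    angle_ks = if (!is.null(report$angle_ks))
      list(D = report$angle_ks$D, P = report$angle_ks$P))
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
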