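#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] adding the checks the downstream
#' comparative methods rely on: branch lengths present and non-negative,
#' rooted topology, unique tip labels. Ultrametricity is checked but only
#' reported as a warning, since non-ultrametric trees are usable (each tip
#' then carries its own root-to-tip depth).
#'
#' @param path path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path, call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; a time-calibrated tree is required",
         call. = FALSE)
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("tree has missing or negative branch lengths", call. = FALSE)
  if (length(tr$tip.label) < 3L)
    stop("tree must have at least 3 tips", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (!ape::is.rooted(tr))
    stop("tree must be rooted", call. = FALSE)
  if (!ape::is.ultrametric(tr, tol = 1e-6))
    warning("tree is not ultrametric; tip-specific depths will be used",
            call. = FALSE)
  tr
}

#' Assemble landmarks, trait table and tree into one analysis-ready study
#'
#' Reconciles the three inputs on the species key: the tree is pruned to the
#' species that have landmark data, species with landmarks but no tip are
#' dropped with a warning, and every species is flagged as belonging to the
#' intraspecific set when it has at least `min_n` specimens.
#'
#' @param landmarks a [landmark_set()].
#' @param taxa data frame with columns `species_id`, `family`, `subfamily`
#'   and optionally `percent_grass` (0-100, `NA` allowed).
#' @param tree an [ape::phylo], e.g. from [read_tree()].
#' @param min_n minimum specimen count for the intraspecific set (default 27;
#'   species with exactly `min_n` specimens are included).
#' @return An object of class `aligned_study`: `landmarks`, `taxa`, `tree`
#'   (pruned), and `species` (per-species table with `n_specimens` and
#'   `in_intraspecific_set`).
#' @export
assemble_study <- function(landmarks, taxa, tree, min_n = 27L) {
  stopifnot(inherits(landmarks, "landmark_set"), inherits(tree, "phylo"))
  taxa <- as.data.frame(taxa)
  if (!all(c("species_id", "family", "subfamily") %in% names(taxa)))
    stop("taxa must have columns species_id, family, subfamily", call. = FALSE)
  if (anyDuplicated(taxa$species_id))
    stop("taxa species_id must be unique", call. = FALSE)

  lm_species <- unique(landmarks$species_id)
  common <- intersect(lm_species, tree$tip.label)
  if (length(common) == 0L)
    stop("no species shared between landmark data and tree", call. = FALSE)
  dropped <- setdiff(lm_species, tree$tip.label)
  if (length(dropped) > 0L) {
    warning("species with landmarks but no tree tip dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    landmarks <- subset_landmarks(landmarks, landmarks$species_id %in% common)
  }
  if (length(common) < 3L)
    stop("fewer than 3 species shared between landmarks and tree", call. = FALSE)
  tree <- ape::keep.tip(tree, common)

  counts <- table(landmarks$species_id)
  species <- data.frame(species_id = tree$tip.label,
                        n_specimens = as.integer(counts[tree$tip.label]),
                        stringsAsFactors = FALSE)
  species$in_intraspecific_set <- species$n_specimens >= min_n
  m <- match(species$species_id, taxa$species_id)
  species$family <- taxa$family[m]
  species$subfamily <- taxa$subfamily[m]
  species$percent_grass <-
    if ("percent_grass" %in% names(taxa)) taxa$percent_grass[m] else NA_real_

  structure(list(landmarks = landmarks, taxa = taxa, tree = tree,
                 species = species, min_n = as.integer(min_n)),
            class = "aligned_study")
}

#' @export
print.aligned_study <- function(x, ...) {
  cat("aligned_study: ", nrow(x$species), " species (",
      sum(x$species$in_intraspecific_set), " in the intraspecific set, min_n = ",
      x$min_n, "), ", x$landmarks$n, " specimens, ", x$landmarks$p,
      " landmarks\n", sep = "")
  invisible(x)
}

#' Remove taxa from a study
#'
#' Drops the named species from both the landmark data and the tree, mirroring
#' the sensitivity re-analyses in which individual divergent genera are
#' excluded and all downstream statistics recomputed.
#'
#' @param study an `aligned_study`.
#' @param taxa character vector of species ids to remove.
#' @return The pruned `aligned_study`.
#' @export
exclude_taxa <- function(study, taxa) {
  stopifnot(inherits(study, "aligned_study"))
  if (length(taxa) == 0L) return(study)
  missing <- setdiff(taxa, study$species$species_id)
  if (length(missing) > 0L)
    stop("taxa not in study: ", paste(missing, collapse = ", "), call. = FALSE)
  keep <- setdiff(study$species$species_id, taxa)
  if (length(keep) < 3L)
    stop("excluding these taxa leaves fewer than 3 species", call. = FALSE)
  lms <- subset_landmarks(study$landmarks, study$landmarks$species_id %in% keep)
  assemble_study(lms, study$taxa, ape::keep.tip(study$tree, keep),
                 min_n = study$min_n)
}
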