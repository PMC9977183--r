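# small deterministic fixtures shared across test files

# a p-landmark 3D configuration with distinct, non-degenerate geometry
fix_config <- function(p = 5L, seed = 1L) {
  set.seed(seed)
  matrix(stats::rnorm(p * 3L), p, 3L)
}

# landmark_set of n specimens scattered around a common shape
fix_landmarks <- function(n = 3L, p = 5L, sd = 0.05, seed = 1L,
                          species = NULL) {
  set.seed(seed)
  base <- matrix(stats::rnorm(p * 3L), p, 3L)
  cfgs <- lapply(seq_len(n), function(i) base + matrix(rnorm(p * 3L, 0, sd), p, 3L))
  if (is.null(species)) species <- paste0("sp", seq_len(n))
  landmark_set(cfgs, paste0("spec", seq_len(n)), species)
}

# apply a random rigid motion + positive scale to a configuration
rigid_motion <- function(cfg, seed = 1L) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  exp(rnorm(1)) * (cfg %*% R) + matrix(rnorm(3, 0, 3), nrow(cfg), 3,
                                       byrow = TRUE)
}

# balanced 4-taxon tree used by the hand-solved GLS oracle
fix_tree4 <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# star phylogeny with unit branch lengths
fix_star <- function(n, labels = NULL) {
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  tr <- ape::stree(n, type = "star")
  tr$tip.label <- labels
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# independent patristic distances: sum of edge lengths along tip-tip paths,
# found by walking parent pointers (no calls into the package or cophenetic)
oracle_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  path_to_root <- function(i) {
    nodes <- i
    while (parent[i] != 0) { i <- parent[i]; nodes <- c(nodes, i) }
    nodes
  }
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1)) {
    pi_ <- path_to_root(i)
    for (j in (i + 1):ntip) {
      pj <- path_to_root(j)
      mrca <- intersect(pi_, pj)[1]
      di <- sum(elen[pi_[seq_len(which(pi_ == mrca) - 1)]])
      dj <- sum(elen[pj[seq_len(which(pj == mrca) - 1)]])
      D[i, j] <- D[j, i] <- di + dj
    }
  }
  D
}
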