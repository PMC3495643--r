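# Independent oracles and fixture builders shared across the suite.

# Naive set-algebra re-implementation of the edge rules, kept deliberately
# literal: a side agrees if it *is* the full member set of some family,
# is neutral if it is a proper subset of some family's member set, and the
# edge disagrees if any family has members on both sides.
naive_classify_edge <- function(side_a, side_b, fam) {
  leaves <- c(side_a, side_b)
  fams <- unique(unname(fam[leaves]))
  members <- lapply(fams, function(f) leaves[fam[leaves] == f])
  names(members) <- fams
  agree <- neutral <- FALSE
  for (side in list(side_a, side_b)) {
    for (f in fams) {
      if (setequal(side, members[[f]])) agree <- TRUE
      else if (all(side %in% members[[f]])) neutral <- TRUE
    }
  }
  if (agree) return("AGREE")
  if (neutral) return("NEUTRAL")
  for (f in fams)
    if (any(members[[f]] %in% side_a) && any(members[[f]] %in% side_b))
      return("DISAGREE")
  "CONSISTENT_MULTI"
}

# Random unrooted tree with positive branch lengths plus its additive
# (path-length) distance matrix.
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.2, 2)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Unrooted topologies match?
same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Toy 2-superfamily, 5-family, 12-domain hierarchy used for exhaustive
# placement enumeration.
toy_hierarchy <- function() {
  scop_labels(
    domain = c("a1", "a2", "a3", "b1", "b2", "c1", "c2",
               "x1", "x2", "y1", "y2", "y3"),
    family = c("FA", "FA", "FA", "FB", "FB", "FC", "FC",
               "FX", "FX", "FY", "FY", "FY"),
    superfamily = c(rep("S1", 7), rep("S2", 5)))
}

# Two families of two leaves each; the classic quartet fixture.
quartet_labels <- function() {
  scop_labels(c("a", "b", "c", "d"),
              c("F", "F", "G", "G"),
              rep("SF", 4))
}

# Percent-identity matrix from explicit pairwise values (symmetric fill).
identity_from_pairs <- function(ids, pairs) {
  m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  for (p in pairs) m[p[[1]], p[[2]]] <- m[p[[2]], p[[1]]] <- p[[3]]
  m
}

# All assignments of n leaves to at most kmax families, enumerated as
# restricted growth strings (set partitions): one representative per
# family-renaming equivalence class, which is exhaustive for the verdict
# rules since they only compare label equality.
rgs_labelings <- function(n, kmax = 3) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(min(mx + 1L, kmax))) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# Brute-force minimum RMSD over rotations: best of many random proper
# rotations refined by optimisation over an axis-angle parameterisation.
brute_force_rmsd <- function(A, B, n_starts = 300, seed = 1) {
  A0 <- scale(A, scale = FALSE); B0 <- scale(B, scale = FALSE)
  rot <- function(v) {
    theta <- sqrt(sum(v^2))
    if (theta < 1e-12) return(diag(3))
    k <- v / theta
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
  }
  obj <- function(v) sqrt(mean(rowSums((B0 - A0 %*% t(rot(v)))^2)))
  set.seed(seed)
  best <- Inf; best_v <- c(0, 0, 0)
  for (i in seq_len(n_starts)) {
    v <- stats::runif(3, -pi, pi)
    val <- obj(v)
    if (val < best) { best <- val; best_v <- v }
  }
  opt <- stats::optim(best_v, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}
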