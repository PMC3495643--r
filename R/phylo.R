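#' @importFrom ape nj unroot consensus read.tree write.tree
NULL

# --- distance matrix validation ---------------------------------------------

#' Validate a square dissimilarity matrix
#'
#' Checks the invariants every distance matrix in this package must satisfy:
#' square, labelled, symmetric (within `tol`), non-negative, zero diagonal.
#' Small asymmetries within tolerance are symmetrised by averaging.
#'
#' @param m numeric matrix with identical row and column names.
#' @param tol symmetry tolerance (default 1e-8).
#' @return The validated (symmetrised) matrix.
#' @export
as_dist_matrix <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m)) && is.null(colnames(m)))
    stop("distance matrix must have row/column names")
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (!identical(rownames(m), colnames(m)))
    stop("row and column names differ")
  if (anyDuplicated(rownames(m))) stop("duplicate identifiers")
  if (any(!is.finite(m))) stop("non-finite distances")
  if (max(abs(m - t(m))) > tol)
    stop("matrix not symmetric within tolerance ", tol)
  m <- (m + t(m)) / 2
  if (any(diag(m) != 0)) stop("diagonal must be zero")
  if (any(m < 0)) stop("negative distances")
  m
}

# --- neighbour joining -------------------------------------------------------

#' Neighbour-joining tree from a distance matrix
#'
#' Agglomerative distance-based reconstruction; on an additive matrix it
#' recovers the generating topology and branch lengths exactly.  Negative
#' branch-length estimates (a known NJ artefact on noisy matrices) are
#' clamped to zero.
#'
#' @param d square symmetric dissimilarity matrix with at least 3 ids
#'   (see [as_dist_matrix]).
#' @return An unrooted `phylo` tree over the matrix ids.
#' @export
nj_tree <- function(d) {
  d <- as_dist_matrix(d)
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) tr$edge.length[neg] <- 0
  tr
}

# --- bipartitions ------------------------------------------------------------

split_key <- function(side) paste(sort(side), collapse = "\x1f")

#' Enumerate the bipartitions of a tree
#'
#' Every edge of the (unrooted) tree splits the leaves into two sides.  The
#' canonical representation stores as `side_a` the side containing the
#' lexicographically smallest leaf.  Pendant edges (one side a single leaf)
#' are included and flagged.
#'
#' @param tree a `phylo` object; rooted trees are unrooted first.
#' @return A data frame with one row per edge: `key` (canonical id of the
#'   smaller-leaf side), list-columns `side_a` and `side_b`, `length`,
#'   `confidence` (numeric node label of the edge's internal child node, `NA`
#'   where absent), and `is_pendant`.
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree has fewer than 2 leaves")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tips <- tree$tip.label
  ntip <- length(tips)
  child <- tree$edge[, 2L]
  desc <- phangorn::Descendants(tree, child, type = "tips")
  min_tip <- min(tips)
  rows <- lapply(seq_along(child), function(i) {
    side <- tips[desc[[i]]]
    other <- setdiff(tips, side)
    if (!(min_tip %in% side)) { tmp <- side; side <- other; other <- tmp }
    conf <- NA_real_
    if (child[i] > ntip && !is.null(tree$node.label)) {
      lab <- tree$node.label[child[i] - ntip]
      conf <- suppressWarnings(as.numeric(lab))
    }
    list(key = split_key(side), side_a = list(side), side_b = list(other),
         length = if (is.null(tree$edge.length)) NA_real_
                  else tree$edge.length[i],
         confidence = conf,
         is_pendant = child[i] <= ntip)
  })
  out <- data.frame(key = vapply(rows, `[[`, "", "key"),
                    length = vapply(rows, `[[`, 0, "length"),
                    confidence = vapply(rows, `[[`, 0, "confidence"),
                    is_pendant = vapply(rows, `[[`, TRUE, "is_pendant"),
                    stringsAsFactors = FALSE)
  out$side_a <- lapply(rows, function(r) r$side_a[[1L]])
  out$side_b <- lapply(rows, function(r) r$side_b[[1L]])
  out[!duplicated(out$key), , drop = FALSE]
}

# internal: canonical keys of the internal (non-pendant) splits of a tree
internal_split_keys <- function(tree) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tips <- tree$tip.label
  ntip <- length(tips)
  child <- tree$edge[, 2L]
  int <- which(child > ntip)
  if (!length(int)) return(character(0))
  desc <- phangorn::Descendants(tree, child[int], type = "tips")
  min_tip <- min(tips)
  keys <- vapply(desc, function(ix) {
    side <- tips[ix]
    if (length(side) <= 1L || length(side) >= ntip - 1L) return(NA_character_)
    if (!(min_tip %in% side)) side <- setdiff(tips, side)
    split_key(side)
  }, character(1))
  unique(keys[!is.na(keys)])
}

# --- bootstrap ---------------------------------------------------------------

#' Bootstrap replicate trees from an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the sequence
#' distance matrix (see [sequence_distance_matrix]) and runs neighbour
#' joining, once per replicate.
#'
#' @param alignment character matrix of aligned residues, rows named by
#'   sequence id.
#' @param n_replicates number of bootstrap replicates (default 300).
#' @param seed integer seed; all resampling derives from it.
#' @param model distance model passed to [sequence_distance_matrix].
#' @return List of `phylo` trees of length `n_replicates`.
#' @export
bootstrap_trees <- function(alignment, n_replicates = 300L, seed = 1L,
                            model = c("poisson_corrected", "p_distance")) {
  model <- match.arg(model)
  alignment <- as_alignment(alignment)
  if (nrow(alignment) < 3L) stop("need at least 3 sequences")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  ncol_a <- ncol(alignment)
  set.seed(seed)
  lapply(seq_len(n_replicates), function(i) {
    idx <- sample.int(ncol_a, ncol_a, replace = TRUE)
    nj_tree(sequence_distance_matrix(alignment[, idx, drop = FALSE],
                                     model = model))
  })
}

# --- consensus ---------------------------------------------------------------

#' Strict-majority consensus tree with per-edge support
#'
#' Builds the majority-rule consensus of a set of replicate trees (an
#' internal split is retained only if present in more than half of the
#' replicates) and annotates each internal edge with its support:
#' `100 * occurrences / n_replicates`, stored as the node label of the
#' edge's child node.
#'
#' @param trees list of `phylo` trees over one common leaf set.
#' @return An unrooted `phylo` consensus tree whose internal node labels are
#'   bootstrap-style percentages in (50, 100].
#' @export
majority_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1L) stop("no trees supplied")
  ref <- sort(trees[[1L]]$tip.label)
  ok <- vapply(trees, function(t) identical(sort(t$tip.label), ref), TRUE)
  if (!all(ok)) stop("trees do not share one leaf set")
  n <- length(trees)
  counts <- table(unlist(lapply(trees, internal_split_keys)))
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5, rooted = FALSE)
  cons$node.label <- NULL
  ntip <- length(cons$tip.label)
  labs <- rep("", cons$Nnode)
  child <- cons$edge[, 2L]
  int <- which(child > ntip)
  if (length(int)) {
    desc <- phangorn::Descendants(cons, child[int], type = "tips")
    min_tip <- min(cons$tip.label)
    for (j in seq_along(int)) {
      side <- cons$tip.label[desc[[j]]]
      if (length(side) <= 1L || length(side) >= ntip - 1L) next
      if (!(min_tip %in% side)) side <- setdiff(cons$tip.label, side)
      k <- split_key(side)
      cnt <- if (k %in% names(counts)) counts[[k]] else 0L
      labs[child[int[j]] - ntip] <- sprintf("%.17g", 100 * cnt / n)
    }
  }
  cons$node.label <- labs
  cons
}
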