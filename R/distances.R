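# Sequence, structural (SAS) and binary annotation distances.

GAP_CHARS <- c("-", ".")

# internal: coerce to a character matrix of aligned residues
as_alignment <- function(x) {
  if (is.matrix(x) && is.character(x)) {
    if (is.null(rownames(x))) stop("alignment rows must be named")
    return(x)
  }
  if (is.character(x) && !is.null(names(x))) {
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) stop("sequences have unequal lengths")
    m <- do.call(rbind, strsplit(x, ""))
    rownames(m) <- names(x)
    return(m)
  }
  stop("alignment must be a named character matrix or named string vector")
}

#' Percent identity between two aligned sequences
#'
#' Compares positions that are ungapped in both sequences
#' (pairwise deletion) and returns `100 * identical / compared`.  When no
#' position is comparable there is no alignment to score: the value is
#' reported as 0 and carries the attribute `no_alignment = TRUE`, mirroring
#' how undetectable homology collapses to the zero-identity bin.
#'
#' @param seq1,seq2 equal-length character vectors of residues (or single
#'   strings), gaps as `-` or `.`.
#' @return Numeric percentage in `[0, 100]`; attribute `no_alignment` is set
#'   when no columns could be compared.
#' @export
percent_identity <- function(seq1, seq2) {
  if (is.character(seq1) && length(seq1) == 1L) seq1 <- strsplit(seq1, "")[[1L]]
  if (is.character(seq2) && length(seq2) == 1L) seq2 <- strsplit(seq2, "")[[1L]]
  if (!length(seq1) || !length(seq2)) stop("empty sequence")
  if (length(seq1) != length(seq2)) stop("sequences must be aligned (equal length)")
  ok <- !(seq1 %in% GAP_CHARS) & !(seq2 %in% GAP_CHARS)
  if (!any(ok)) {
    out <- 0
    attr(out, "no_alignment") <- TRUE
    return(out)
  }
  100 * sum(seq1[ok] == seq2[ok]) / sum(ok)
}

#' Pairwise percent-identity matrix of an alignment
#'
#' @param alignment character matrix of aligned residues, rows named.
#' @return Symmetric matrix of percent identities with 100 on the diagonal;
#'   attribute `no_alignment` is a logical matrix flagging pairs with no
#'   comparable columns (their identity is reported as 0).
#' @export
identity_matrix <- function(alignment) {
  a <- as_alignment(alignment)
  n <- nrow(a)
  ids <- rownames(a)
  gap <- matrix(a %in% GAP_CHARS, nrow = n)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  flag <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) {
      m[i, j] <- m[j, i] <- 0
      flag[i, j] <- flag[j, i] <- TRUE
    } else {
      m[i, j] <- m[j, i] <- 100 * sum(a[i, ok] == a[j, ok]) / sum(ok)
    }
  }
  attr(m, "no_alignment") <- flag
  m
}

#' Pairwise sequence distance matrix
#'
#' Distances under the p-distance model (proportion of differing comparable
#' positions) or its Poisson correction `-log(1 - p)`.  Columns gapped in
#' either member of a pair are ignored (pairwise deletion).  Saturated pairs
#' (`p` at or beyond `1 - exp(-ceiling)`) and pairs with no comparable
#' columns are set to `ceiling`, with a warning for the latter.
#'
#' @param alignment character matrix of aligned residues (>= 3 rows).
#' @param model `"p_distance"` or `"poisson_corrected"` (default).
#' @param ceiling maximum corrected distance (default 10).
#' @return Symmetric distance matrix (see [as_dist_matrix]).
#' @export
sequence_distance_matrix <- function(alignment,
                                     model = c("poisson_corrected",
                                               "p_distance"),
                                     ceiling = 10) {
  model <- match.arg(model)
  a <- as_alignment(alignment)
  if (nrow(a) < 3L) stop("need at least 3 sequences")
  idm <- identity_matrix(a)
  p <- 1 - idm / 100
  if (any(attr(idm, "no_alignment")))
    warning("some pairs had no comparable columns; set to ceiling distance")
  if (model == "p_distance") {
    d <- p
    d[attr(idm, "no_alignment")] <- 1
  } else {
    d <- -log(pmax(1 - p, exp(-ceiling)))
    d[attr(idm, "no_alignment")] <- ceiling
  }
  diag(d) <- 0
  as_dist_matrix(d)
}

#' Least-squares superposition RMSD (Kabsch)
#'
#' Optimal rigid-body superposition of two matched coordinate sets: both are
#' centred, the optimal proper rotation is obtained from the SVD of the
#' covariance matrix (with the determinant sign correction that excludes
#' reflections), and the root-mean-square deviation of the superposed sets
#' is returned.
#'
#' @param coordsA,coordsB n x 3 numeric matrices of matched coordinates
#'   (Angstroms), n >= 3.
#' @return RMSD in Angstroms.
#' @export
kabsch_rmsd <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (!all(dim(A) == dim(B))) stop("coordinate sets must match in size")
  if (nrow(A) < 3L || ncol(A) != 3L) stop("need >= 3 matched 3-D points")
  A0 <- scale(A, scale = FALSE); B0 <- scale(B, scale = FALSE)
  if (qr(A0)$rank < 2L || qr(B0)$rank < 2L)
    warning("degenerate (collinear) coordinates; superposition ill-defined")
  s <- svd(crossprod(A0, B0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((B0 - A0 %*% t(R))^2)))
}

#' Structural alignment score (SAS) matrix
#'
#' The structural distance between two domains is
#' `SAS = 100 * RMS / n_matched`: superposition RMSD normalised by the
#' number of matched positions, so that longer alignments at equal RMSD
#' score as closer.
#'
#' @param rms_matrix symmetric matrix of superposition RMSDs (Angstroms).
#' @param n_matched_matrix matrix of matched-position counts (>= 1),
#'   same shape.
#' @return Symmetric SAS distance matrix with zero diagonal.
#' @export
sas_matrix <- function(rms_matrix, n_matched_matrix) {
  rms <- as.matrix(rms_matrix); nm <- as.matrix(n_matched_matrix)
  if (!all(dim(rms) == dim(nm))) stop("matrix shapes differ")
  if (any(nm < 1)) stop("n_matched must be >= 1")
  if (any(rms < 0)) stop("rms must be >= 0")
  s <- 100 * rms / nm
  diag(s) <- 0
  as_dist_matrix(s, tol = 1e-6)
}

#' Drop uninformative annotation terms
#'
#' A term present in every domain, or in at most one domain, carries no
#' grouping information and is ignored.  Order of surviving terms is
#' preserved.
#'
#' @param m binary term x domain matrix (see [annotation_matrix]).
#' @return The filtered matrix.
#' @export
filter_uninformative_terms <- function(m) {
  m <- as_annotation_matrix(m)
  rs <- rowSums(m)
  m[rs > 1L & rs < ncol(m), , drop = FALSE]
}

#' Mean-character-difference distance from binary annotations
#'
#' `d(i, j)` = number of terms in which domains i and j differ, divided by
#' the number of terms; in `[0, 1]`.
#'
#' @param m binary term x domain matrix, already filtered
#'   (see [filter_uninformative_terms]); >= 3 domains, >= 1 term.
#' @return Symmetric distance matrix over the domains.
#' @export
binary_distance_matrix <- function(m) {
  m <- as_annotation_matrix(m)
  if (ncol(m) < 3L) stop("need at least 3 domains")
  if (nrow(m) < 1L) stop("no informative terms")
  d <- as.matrix(stats::dist(t(m), method = "manhattan")) / nrow(m)
  as_dist_matrix(d)
}

#' Per-edge support from annotation terms
#'
#' The confidence of an internal tree edge under functional data is the
#' number of informative terms whose presence set picks out one side of the
#' edge's bipartition.  In the default `"exact"` mode the presence set
#' (restricted to the tree's leaves) must equal one side; in `"subset"` mode
#' it must be a subset of one side with at least two members (a term
#' consistent with, though not diagnostic of, the clade).
#'
#' @param tree a `phylo` tree whose leaves are annotated domains.
#' @param m binary term x domain matrix; domains must cover the leaves.
#'   Uninformative terms are filtered out first.
#' @param mode `"exact"` (default) or `"subset"`.
#' @return Data frame of internal edges: `key`, `support`.
#' @export
term_support <- function(tree, m, mode = c("exact", "subset")) {
  mode <- match.arg(mode)
  m <- as_annotation_matrix(m)
  tips <- tree$tip.label
  if (!all(tips %in% colnames(m)))
    stop("tree leaves missing from annotation matrix: ",
         paste(setdiff(tips, colnames(m)), collapse = ", "))
  m <- filter_uninformative_terms(m[, tips, drop = FALSE])
  bp <- tree_bipartitions(tree)
  bp <- bp[!bp$is_pendant, , drop = FALSE]
  presence <- lapply(seq_len(nrow(m)), function(i) colnames(m)[m[i, ] == 1L])
  support <- vapply(seq_len(nrow(bp)), function(i) {
    a <- bp$side_a[[i]]; b <- bp$side_b[[i]]
    if (mode == "exact") {
      ka <- split_key(a); kb <- split_key(b)
      sum(vapply(presence, function(p) {
        k <- split_key(p); k == ka || k == kb
      }, TRUE))
    } else {
      sum(vapply(presence, function(p) {
        length(p) >= 2L && (all(p %in% a) || all(p %in% b))
      }, TRUE))
    }
  }, 0L)
  data.frame(key = bp$key, support = support, stringsAsFactors = FALSE)
}
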