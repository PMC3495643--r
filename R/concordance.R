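# Edge-level concordance of a tree with the family classification.
#
# Each tree edge splits the domains of a superfamily in two.  The split is
# compared with the family grouping:
#   AGREE    - one side is exactly one complete family;
#   NEUTRAL  - one side holds members of a single family, but not all of
#              them (an uninformative edge inside a family);
#   DISAGREE - some family is split across both sides in the company of
#              another family;
#   CONSISTENT_MULTI - both sides are unions of two or more complete
#              families (no rule above fires; consistent with the
#              classification at a coarser level).
# Precedence is AGREE > NEUTRAL > DISAGREE: an incomplete single-family side
# reads as uninformative, not as a conflict.

VERDICTS <- c("AGREE", "NEUTRAL", "DISAGREE", "CONSISTENT_MULTI")

#' Classify one bipartition against family labels
#'
#' @param side_a,side_b character vectors of domain ids forming the two
#'   sides of the bipartition (disjoint, jointly all leaves).
#' @param labels a [scop_labels] object, or a named character vector mapping
#'   domain to family (see [family_map]).
#' @return One of `"AGREE"`, `"NEUTRAL"`, `"DISAGREE"`,
#'   `"CONSISTENT_MULTI"`.
#' @export
classify_edge <- function(side_a, side_b, labels) {
  fam <- if (is.character(labels) && !is.null(names(labels))) labels
         else family_map(labels)
  fa <- fam[side_a]; fb <- fam[side_b]
  if (anyNA(fa) || anyNA(fb))
    stop("unlabelled leaf: ",
         paste(c(side_a[is.na(fa)], side_b[is.na(fb)]), collapse = ", "))
  classify_fams(fa, fb)
}

# internal fast path on family-id vectors
classify_fams <- function(fa, fb) {
  ua <- unique(fa); ub <- unique(fb)
  # AGREE: a side that is one family, complete (family absent on other side)
  if (length(ua) == 1L && !(ua %in% ub)) return("AGREE")
  if (length(ub) == 1L && !(ub %in% ua)) return("AGREE")
  # NEUTRAL: a side that is one family, incomplete
  if (length(ua) == 1L || length(ub) == 1L) return("NEUTRAL")
  # DISAGREE: some family occurs on both sides (alongside another family)
  if (any(ua %in% ub)) return("DISAGREE")
  "CONSISTENT_MULTI"
}

#' Classify every edge of a tree against the family labels
#'
#' Runs the edge classifier over all bipartitions of a tree built for one
#' superfamily and attaches each edge's confidence.
#'
#' @param tree a `phylo` tree whose leaves are the labelled domains of one
#'   superfamily.
#' @param labels a [scop_labels] object covering the leaves.
#' @param confidence where edge confidences come from: `"node_label"`
#'   (bootstrap-style supports stored as internal node labels, the default),
#'   `"edge_length"` (structural trees ranked by branch length), or
#'   `"term_support"` (functional trees; requires `annotations`).
#' @param annotations binary term x domain matrix, needed when
#'   `confidence = "term_support"`.
#' @param default_confidence value used where no confidence is available
#'   (e.g. a ground-truth tree); default `NA`.
#' @return Data frame of edge verdicts: `key`, `verdict`, `confidence`,
#'   `is_pendant`, plus list-columns `side_a`, `side_b`.
#' @export
classify_tree <- function(tree, labels,
                          confidence = c("node_label", "edge_length",
                                         "term_support"),
                          annotations = NULL,
                          default_confidence = NA_real_) {
  confidence <- match.arg(confidence)
  fam <- family_map(labels)
  missing <- setdiff(tree$tip.label, names(fam))
  if (length(missing))
    stop("tree leaves absent from labels: ", paste(missing, collapse = ", "))
  bp <- tree_bipartitions(tree)
  verdict <- vapply(seq_len(nrow(bp)), function(i)
    classify_fams(fam[bp$side_a[[i]]], fam[bp$side_b[[i]]]), "")
  conf <- switch(confidence,
    node_label  = bp$confidence,
    edge_length = bp$length,
    term_support = {
      ts <- term_support(tree, annotations)
      ts$support[match(bp$key, ts$key)]
    })
  conf[is.na(conf)] <- default_confidence
  out <- data.frame(key = bp$key, verdict = verdict, confidence = conf,
                    is_pendant = bp$is_pendant, stringsAsFactors = FALSE)
  out$side_a <- bp$side_a
  out$side_b <- bp$side_b
  out
}

#' Edge classification with the dustbin-family relaxation
#'
#' Some superfamilies hold a catch-all "dustbin" family of leftover members
#' with nothing in common; scoring should not penalise the classification
#' for its scatter.  For each candidate family, the tree's bipartitions are
#' re-evaluated on the leaf set excluding that family's members (edges whose
#' restricted side becomes empty are dropped), and the candidate - or no
#' exclusion at all - minimising the number of DISAGREE edges is chosen.
#' Ties go to no exclusion, then to the smallest family id.  The relaxed
#' disagreement count is never larger than the plain one.
#'
#' @inheritParams classify_tree
#' @param ... passed on to [classify_tree] (confidence source etc.).
#' @return List with `dustbin` (chosen family id or `NA`), `n_disagree`
#'   (relaxed count), `n_disagree_plain`, and `verdicts` (edge verdicts
#'   under the chosen exclusion, same shape as [classify_tree] output).
#' @export
dustbin_classify <- function(tree, labels, ...) {
  labels <- as_scop_labels(labels)
  plain <- classify_tree(tree, labels, ...)
  n_dis <- function(v) sum(v$verdict == "DISAGREE")
  best <- list(dustbin = NA_character_, verdicts = plain,
               n = n_dis(plain))
  fam <- family_map(labels)
  candidates <- sort(unique(fam[tree$tip.label]))
  for (d in candidates) {
    keep <- tree$tip.label[fam[tree$tip.label] != d]
    if (length(keep) < 2L) next
    restricted <- plain
    restricted$side_a <- lapply(plain$side_a, intersect, keep)
    restricted$side_b <- lapply(plain$side_b, intersect, keep)
    drop <- lengths(restricted$side_a) == 0L |
            lengths(restricted$side_b) == 0L
    restricted <- restricted[!drop, , drop = FALSE]
    if (!nrow(restricted)) next
    restricted$verdict <- vapply(seq_len(nrow(restricted)), function(i)
      classify_fams(fam[restricted$side_a[[i]]],
                    fam[restricted$side_b[[i]]]), "")
    restricted$is_pendant <- lengths(restricted$side_a) == 1L |
                             lengths(restricted$side_b) == 1L
    n <- n_dis(restricted)
    if (n < best$n) best <- list(dustbin = d, verdicts = restricted, n = n)
  }
  list(dustbin = best$dustbin, n_disagree = best$n,
       n_disagree_plain = n_dis(plain), verdicts = best$verdicts)
}

#' Does a superfamily contain an agreement / a disagreement above a
#' confidence threshold?
#'
#' @param verdicts edge verdict data frame from [classify_tree].
#' @param threshold confidence threshold (on the verdicts' confidence
#'   scale).
#' @param include_pendant count pendant edges? Default `FALSE`: a pendant
#'   edge carries no grouping evidence for multi-member families.
#' @return Logical vector `c(has_agreement, has_disagreement)`.
#' @export
superfamily_verdict <- function(verdicts, threshold,
                                include_pendant = FALSE) {
  v <- verdicts
  if (!include_pendant) v <- v[!v$is_pendant, , drop = FALSE]
  conf <- v$confidence
  above <- !is.na(conf) & conf >= threshold
  c(has_agreement = any(v$verdict == "AGREE" & above),
    has_disagreement = any(v$verdict == "DISAGREE" & above))
}

#' ROC-style sweep of agreement/disagreement counts over confidence
#' thresholds
#'
#' For each threshold, counts the superfamilies containing at least one
#' AGREE edge (resp. at least one DISAGREE edge) at confidence at or above
#' the threshold.  Both counts are non-decreasing as the threshold
#' decreases.  `CONSISTENT_MULTI` edges count as neutral.
#'
#' @param verdicts_by_superfamily named list of edge verdict data frames
#'   (one per superfamily, all on one confidence scale).
#' @param thresholds numeric vector of thresholds to sweep.
#' @param include_pendant see [superfamily_verdict].
#' @return Data frame with one row per threshold (sorted decreasing):
#'   `threshold`, `n_agreement`, `n_disagreement`.
#' @export
roc_curve <- function(verdicts_by_superfamily, thresholds,
                      include_pendant = FALSE) {
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  rows <- lapply(thresholds, function(th) {
    sv <- vapply(verdicts_by_superfamily, superfamily_verdict,
                 logical(2), threshold = th,
                 include_pendant = include_pendant)
    data.frame(threshold = th,
               n_agreement = sum(sv["has_agreement", ]),
               n_disagreement = sum(sv["has_disagreement", ]))
  })
  do.call(rbind, rows)
}
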