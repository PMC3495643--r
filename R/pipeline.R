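# End-to-end plumbing: build a tree of a given flavour for one superfamily
# and audit a whole study against its classification.

#' Build one superfamily's tree in a given flavour
#'
#' * `sequence`: bootstrap-resamples the alignment, builds neighbour-joining
#'   replicates and returns the strict-majority consensus, with bootstrap
#'   percentages as edge confidences.
#' * `structure`: neighbour joining on the structural distance matrix; edge
#'   confidences are taken from branch lengths when classifying.
#' * `function`: filters uninformative terms, builds the mean character
#'   difference matrix and runs neighbour joining; edge confidences are
#'   term-support counts.
#'
#' @param flavour `"sequence"`, `"structure"` or `"function"`.
#' @param alignment character matrix (sequence flavour).
#' @param distances symmetric matrix (structure flavour).
#' @param annotations binary term x domain matrix (function flavour).
#' @param n_replicates bootstrap replicates (sequence flavour).
#' @param seed seed for bootstrap resampling.
#' @return A `phylo` tree.
#' @export
build_superfamily_tree <- function(flavour = c("sequence", "structure",
                                               "function"),
                                   alignment = NULL, distances = NULL,
                                   annotations = NULL,
                                   n_replicates = 300L, seed = 1L) {
  flavour <- match.arg(flavour)
  switch(flavour,
    sequence = {
      if (is.null(alignment)) stop("sequence flavour needs an alignment")
      majority_consensus(bootstrap_trees(alignment, n_replicates, seed))
    },
    structure = {
      if (is.null(distances)) stop("structure flavour needs distances")
      nj_tree(distances)
    },
    `function` = {
      if (is.null(annotations)) stop("function flavour needs annotations")
      nj_tree(binary_distance_matrix(filter_uninformative_terms(annotations)))
    })
}

#' Audit a study: per-superfamily edge verdicts for one tree flavour
#'
#' For every retained superfamily (see [filter_superfamilies]) builds the
#' requested tree flavour and classifies its edges against the labels.
#'
#' @param study a list as returned by [simulate_study] (fields `labels`,
#'   `alignments`, `distances`, `annotations` as needed by the flavour).
#' @param flavour tree flavour, see [build_superfamily_tree].
#' @param labels optional label override (e.g. perturbed labels from
#'   [inject_misclassification]); defaults to `study$labels`.
#' @param n_replicates,seed bootstrap parameters (sequence flavour).
#' @param dustbin apply the dustbin relaxation? Default `FALSE`.
#' @return Named list of edge-verdict data frames, one per retained
#'   superfamily.
#' @export
audit_study <- function(study, flavour = "sequence", labels = NULL,
                        n_replicates = 300L, seed = 1L, dustbin = FALSE) {
  if (is.null(labels)) labels <- study$labels
  labels <- as_scop_labels(labels)
  sfs <- filter_superfamilies(labels)
  set.seed(seed)
  boot_seeds <- sample.int(.Machine$integer.max, length(sfs))
  out <- list()
  for (i in seq_along(sfs)) {
    sf <- sfs[i]
    lab_sf <- superfamily_labels(labels, sf)
    conf <- switch(flavour, sequence = "node_label",
                   structure = "edge_length", `function` = "term_support")
    ann_sf <- NULL
    if (flavour == "function") {
      ann <- study$annotations$matrix
      ann_sf <- ann[, lab_sf$domain, drop = FALSE]
      ann_sf <- filter_uninformative_terms(ann_sf)
      if (nrow(ann_sf) < 1L || ncol(ann_sf) < 3L) next
    }
    tree <- build_superfamily_tree(
      flavour,
      alignment = study$alignments[[sf]],
      distances = study$distances[[sf]],
      annotations = ann_sf,
      n_replicates = n_replicates, seed = boot_seeds[i])
    out[[sf]] <- if (dustbin)
      dustbin_classify(tree, lab_sf, confidence = conf,
                       annotations = ann_sf)$verdicts
    else classify_tree(tree, lab_sf, confidence = conf,
                       annotations = ann_sf)
  }
  out
}
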