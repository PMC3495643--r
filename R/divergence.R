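# Maximum divergence within a group by sequential removal.
#
# Starting from all members of a family (or superfamily), the pair with the
# highest percent identity is found and one of its members removed,
# repeatedly, until only two sequences remain: the two most distant members
# the group can produce.  Their identity is the group's maximum divergence.

#' Greedy maximum divergence of a group
#'
#' Iteratively removes the highest-identity pair's more "redundant" member
#' (the one with the larger mean identity to the remaining others; ties by
#' lexicographic id, keeping the smaller) until two members remain.
#' `mode = "both"` removes both members of the pair at each step (unless
#' that would leave fewer than two).  Pairs flagged as having no alignment
#' count as identity 0.
#'
#' @param identity symmetric percent-identity matrix over the group (see
#'   [identity_matrix]); may carry a logical `no_alignment` attribute
#'   matrix.
#' @param mode `"single"` (default) or `"both"`.
#' @return List: `pair` (the two surviving ids), `identity` (their percent
#'   identity), `no_alignment` (flag for that pair).
#' @export
greedy_max_divergence <- function(identity, mode = c("single", "both")) {
  mode <- match.arg(mode)
  m <- as.matrix(identity)
  ids <- rownames(m)
  if (is.null(ids) || length(ids) < 2L) stop("group of size < 2")
  flag <- attr(identity, "no_alignment")
  if (is.null(flag)) flag <- matrix(FALSE, nrow(m), ncol(m),
                                    dimnames = dimnames(m))
  m[flag] <- 0
  alive <- sort(ids)
  while (length(alive) > 2L) {
    sub <- m[alive, alive]
    diag(sub) <- -Inf
    best <- max(sub)
    hits <- which(sub == best, arr.ind = TRUE)
    # ties: lexicographically smallest (id1, id2) pair
    pairs <- t(apply(hits, 1L, function(ix) sort(alive[ix])))
    pairs <- unique(pairs)
    ord <- order(pairs[, 1L], pairs[, 2L])
    pair <- pairs[ord[1L], ]
    others <- setdiff(alive, pair)
    if (mode == "both" && length(alive) - 2L >= 2L) {
      alive <- others
      next
    }
    # remove the member closer (higher mean identity) to the rest
    mean_id <- vapply(pair, function(p)
      mean(m[p, others]), 0)
    drop <- if (mean_id[1L] > mean_id[2L]) pair[1L]
            else if (mean_id[2L] > mean_id[1L]) pair[2L]
            else max(pair)  # tie: keep the lexicographically smaller id
    alive <- setdiff(alive, drop)
  }
  list(pair = alive,
       identity = m[alive[1L], alive[2L]],
       no_alignment = flag[alive[1L], alive[2L]])
}

#' Maximum pairwise distance within a group
#'
#' @param d symmetric distance matrix.
#' @param group character vector of ids (>= 2) present in `d`.
#' @return The largest within-group pairwise distance.
#' @export
max_pairwise_distance <- function(d, group) {
  d <- as.matrix(d)
  if (!all(group %in% rownames(d)))
    stop("group members missing from matrix: ",
         paste(setdiff(group, rownames(d)), collapse = ", "))
  if (length(group) < 2L) stop("group of size < 2")
  sub <- d[group, group]
  max(sub[upper.tri(sub)])
}

#' Distribution of maximum divergence across families or superfamilies
#'
#' Runs [greedy_max_divergence] for every group with at least two members
#' at the requested level and bins the resulting percent identities.
#' Groups whose surviving pair had no alignment fall in the 0 bin.
#'
#' @param labels a [scop_labels] object.
#' @param identity_by_superfamily named list of percent-identity matrices,
#'   one per superfamily, rows/cols named by domain.
#' @param level `"family"` or `"superfamily"`.
#' @param breaks bin boundaries on the identity scale
#'   (default `seq(0, 100, 10)`).
#' @param mode passed to [greedy_max_divergence].
#' @return List: `results` (data frame `group`, `id1`, `id2`, `identity`,
#'   `no_alignment`), `counts` (named bin counts), `mean_identity`, and
#'   `frac_ge20` (fraction of groups whose surviving pair keeps >= 20%
#'   identity).
#' @export
divergence_distribution <- function(labels, identity_by_superfamily,
                                    level = c("family", "superfamily"),
                                    breaks = seq(0, 100, 10),
                                    mode = "single") {
  level <- match.arg(level)
  labels <- as_scop_labels(labels)
  groups <- if (level == "family") split(labels, labels$family)
            else split(labels, labels$superfamily)
  rows <- lapply(names(groups), function(g) {
    members <- groups[[g]]$domain
    if (length(members) < 2L) return(NULL)  # singleton groups are skipped
    sf <- groups[[g]]$superfamily[1L]
    m <- identity_by_superfamily[[sf]]
    if (is.null(m)) stop("no identity matrix for superfamily ", sf)
    flag <- attr(m, "no_alignment")
    sub <- m[members, members]
    if (!is.null(flag)) attr(sub, "no_alignment") <- flag[members, members]
    r <- greedy_max_divergence(sub, mode = mode)
    data.frame(group = g, id1 = r$pair[1L], id2 = r$pair[2L],
               identity = r$identity, no_alignment = r$no_alignment,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  if (is.null(results))
    return(list(results = NULL, counts = NULL,
                mean_identity = NA_real_, frac_ge20 = NA_real_))
  binned <- results$identity
  binned[results$no_alignment] <- 0
  counts <- table(cut(binned, breaks = breaks, include.lowest = TRUE,
                      right = TRUE))
  list(results = results, counts = counts,
       mean_identity = mean(results$identity),
       frac_ge20 = mean(results$identity >= 20))
}
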