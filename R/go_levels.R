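# Placement taxonomy for annotation terms.
#
# Where in the superfamily/family hierarchy does the set of domains carrying
# a term sit?  Eleven mutually exclusive categories describe the placement,
# from a subset of one family up to spanning several superfamilies, with a
# coarse three-way summary (one family / subset of a family / multiple
# superfamilies) on top.

GO_CATEGORIES <- c("SubFamily", "FamilyEquivalent", "MultiFamily",
                   "PartialFamily", "ScatteredFamilies",
                   "ScatteredInSuperfamily", "AlmostSuperfamily",
                   "SuperfamilyEquivalent", "MultiSuperfamilies",
                   "PartialSuperfamilies", "ScatteredSuperfamilies")

#' Classify a term's presence set into the placement taxonomy
#'
#' For each superfamily touched by the presence set, families are tallied as
#' complete (all members present), partial, or empty.  With a single touched
#' superfamily the categories are checked in order - SubFamily (one partial
#' family, nothing else), FamilyEquivalent (exactly one complete family,
#' nothing partial), MultiFamily (two or more complete families, at least
#' one family untouched), PartialFamily (complete families plus exactly one
#' partial and at least one empty), ScatteredFamilies (two or more partial
#' and at least one empty), ScatteredInSuperfamily (every family partial),
#' AlmostSuperfamily (every family touched, some complete, some partial),
#' SuperfamilyEquivalent (every family complete) - and the first match wins.
#' With several touched superfamilies: MultiSuperfamilies (every touched
#' superfamily fully covered), PartialSuperfamilies (at least one fully
#' covered, exactly one other incompletely covered), else
#' ScatteredSuperfamilies.
#'
#' @param presence character vector of domain ids carrying the term
#'   (non-empty).
#' @param labels a [scop_labels] object covering those domains (and their
#'   whole superfamilies).
#' @return List: `category`, and `tallies`, a data frame per touched
#'   superfamily with counts of `complete`, `partial`, `empty` families.
#' @export
classify_term_placement <- function(presence, labels) {
  presence <- unique(as.character(presence))
  if (!length(presence)) stop("empty presence set")
  labels <- as_scop_labels(labels)
  unknown <- setdiff(presence, labels$domain)
  if (length(unknown))
    stop("unlabelled domains: ", paste(unknown, collapse = ", "))
  sub <- labels[labels$domain %in% presence, , drop = FALSE]
  touched_sf <- unique(sub$superfamily)
  tallies <- do.call(rbind, lapply(touched_sf, function(sf) {
    sf_lab <- labels[labels$superfamily == sf, , drop = FALSE]
    fam_total <- table(sf_lab$family)
    fam_hit <- table(factor(sub$family[sub$superfamily == sf],
                            levels = names(fam_total)))
    data.frame(superfamily = sf,
               complete = sum(fam_hit == fam_total & fam_total > 0),
               partial = sum(fam_hit > 0 & fam_hit < fam_total),
               empty = sum(fam_hit == 0),
               stringsAsFactors = FALSE)
  }))
  category <- if (length(touched_sf) == 1L) {
    with(tallies, {
      f <- complete + partial + empty
      if (complete == 0L && partial == 1L)       "SubFamily"
      else if (complete == 1L && partial == 0L)  "FamilyEquivalent"
      else if (complete >= 2L && partial == 0L && empty >= 1L) "MultiFamily"
      else if (complete >= 1L && partial == 1L && empty >= 1L) "PartialFamily"
      else if (partial >= 2L && empty >= 1L)     "ScatteredFamilies"
      else if (complete == 0L && partial == f)   "ScatteredInSuperfamily"
      else if (empty == 0L && complete >= 1L && partial >= 1L)
                                                 "AlmostSuperfamily"
      else if (complete == f)                    "SuperfamilyEquivalent"
      else stop("unclassifiable tally (single superfamily)")  # unreachable
    })
  } else {
    covered <- tallies$partial == 0L & tallies$empty == 0L
    if (all(covered))                            "MultiSuperfamilies"
    else if (any(covered) && sum(!covered) == 1L) "PartialSuperfamilies"
    else                                         "ScatteredSuperfamilies"
  }
  list(category = category, tallies = tallies)
}

#' Classify every term of an annotation matrix
#'
#' @param m binary term x domain matrix (see [annotation_matrix]); terms
#'   with empty presence sets (e.g. after total dropout) are reported with
#'   category `NA`.
#' @param labels a [scop_labels] object.
#' @return Data frame: `term`, `category`, `n_domains`.
#' @export
classify_placements <- function(m, labels) {
  m <- as_annotation_matrix(m)
  rows <- lapply(rownames(m), function(term) {
    present <- colnames(m)[m[term, ] == 1L]
    cat <- if (length(present)) classify_term_placement(present,
                                                        labels)$category
           else NA_character_
    data.frame(term = term, category = cat, n_domains = length(present),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarise term placements
#'
#' Tallies the eleven placement categories and folds them into the coarse
#' three-way view: terms fitting exactly one family, terms confined to a
#' subset of one family, terms spanning multiple superfamilies, and the
#' intermediate remainder.
#'
#' @param placements data frame with a `category` column (e.g. from
#'   [classify_placements]); `NA` categories are dropped.
#' @return List: `counts` (named 11-way counts), `summary` (named counts
#'   for `one_family`, `sub_family`, `multi_superfamily`, `intermediate`),
#'   and `fractions` (the same, as proportions summing to 1).
#' @export
summarize_placements <- function(placements) {
  cats <- placements$category
  cats <- cats[!is.na(cats)]
  counts <- table(factor(cats, levels = GO_CATEGORIES))
  multi <- c("MultiSuperfamilies", "PartialSuperfamilies",
             "ScatteredSuperfamilies")
  summary <- c(one_family = sum(counts["FamilyEquivalent"]),
               sub_family = sum(counts["SubFamily"]),
               multi_superfamily = sum(counts[multi]),
               intermediate = sum(counts) - sum(counts["FamilyEquivalent"]) -
                 sum(counts["SubFamily"]) - sum(counts[multi]))
  fractions <- if (sum(summary) > 0) summary / sum(summary)
               else summary * NA_real_
  list(counts = counts, summary = summary, fractions = fractions)
}
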