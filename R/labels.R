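#' Two-level domain classification labels
#'
#' Container for the classification being audited: every protein domain
#' belongs to exactly one family and every family to exactly one superfamily
#' (the SCOP-style superfamily/family hierarchy, restricted to the two levels
#' the audit needs).
#'
#' @param domain character vector of unique domain identifiers.
#' @param family character vector, same length, family id of each domain.
#' @param superfamily character vector, same length, superfamily id of each
#'   domain's family.
#'
#' @return A `scop_labels` object: a data frame with columns `domain`,
#'   `family`, `superfamily`.
#'
#' @examples
#' scop_labels(c("d1", "d2", "d3", "d4"),
#'             c("F1", "F1", "F2", "F2"),
#'             c("SF1", "SF1", "SF1", "SF1"))
#' @export
scop_labels <- function(domain, family, superfamily) {
  domain <- as.character(domain)
  family <- as.character(family)
  superfamily <- as.character(superfamily)
  if (length(family) != length(domain) || length(superfamily) != length(domain))
    stop("domain, family and superfamily must have equal length")
  if (anyDuplicated(domain))
    stop("duplicate domain identifiers: ",
         paste(unique(domain[duplicated(domain)]), collapse = ", "))
  # a family may not straddle superfamilies
  fam_sf <- tapply(superfamily, family, function(x) length(unique(x)))
  if (any(fam_sf > 1))
    stop("family in more than one superfamily: ",
         paste(names(fam_sf)[fam_sf > 1], collapse = ", "))
  out <- data.frame(domain = domain, family = family,
                    superfamily = superfamily, stringsAsFactors = FALSE)
  class(out) <- c("scop_labels", "data.frame")
  out
}

#' @export
print.scop_labels <- function(x, ...) {
  cat(sprintf("<scop_labels> %d domains, %d families, %d superfamilies\n",
              nrow(x), length(unique(x$family)),
              length(unique(x$superfamily))))
  NextMethod()
}

as_scop_labels <- function(x) {
  if (inherits(x, "scop_labels")) return(x)
  scop_labels(x$domain, x$family, x$superfamily)
}

#' Map each domain to its family
#'
#' @param labels a [scop_labels] object.
#' @return Named character vector, `names` are domains, values family ids.
#' @export
family_map <- function(labels) {
  labels <- as_scop_labels(labels)
  stats::setNames(labels$family, labels$domain)
}

#' Restrict labels to one superfamily
#'
#' @param labels a [scop_labels] object.
#' @param superfamily a single superfamily id.
#' @return The subset of `labels` for that superfamily.
#' @export
superfamily_labels <- function(labels, superfamily) {
  labels <- as_scop_labels(labels)
  out <- labels[labels$superfamily == superfamily, , drop = FALSE]
  if (nrow(out) == 0L) stop("unknown superfamily: ", superfamily)
  out
}

#' Remove superfamilies whose family grouping cannot be contested
#'
#' A superfamily is retained only if the family-level grouping inside it can
#' carry phylogenetic signal: it must contain at least two families, at least
#' one family with two or more members, and more than three domains in total.
#' Superfamilies with a single family, with only singleton families, or with
#' three or fewer domains are dropped.
#'
#' @param labels a [scop_labels] object.
#' @return Character vector of retained superfamily ids.
#' @export
filter_superfamilies <- function(labels) {
  labels <- as_scop_labels(labels)
  keep <- vapply(split(labels, labels$superfamily), function(sf) {
    fam_sizes <- table(sf$family)
    length(fam_sizes) >= 2L && any(fam_sizes >= 2L) && nrow(sf) >= 4L
  }, logical(1))
  sort(names(keep)[keep])
}
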