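#' Binary term-by-domain annotation matrix
#'
#' Builds the presence/absence matrix of annotation terms (GO terms, EC
#' numbers, or any flat vocabulary) against domains.  Terms are rows,
#' domains columns, entries 0/1.
#'
#' @param term character vector of term ids (one per annotation record).
#' @param domain character vector of annotated domain ids, same length.
#' @param all_domains optional character vector of the full domain universe;
#'   domains with no annotation appear as all-zero columns.
#' @return Integer 0/1 matrix with term rownames and domain colnames.
#' @export
annotation_matrix <- function(term, domain, all_domains = NULL) {
  term <- as.character(term); domain <- as.character(domain)
  if (length(term) != length(domain)) stop("term and domain lengths differ")
  terms <- unique(term)
  doms <- unique(c(domain, as.character(all_domains)))
  m <- matrix(0L, length(terms), length(doms),
              dimnames = list(terms, doms))
  m[cbind(match(term, terms), match(domain, doms))] <- 1L
  m
}

as_annotation_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("annotation matrix entries must be 0/1")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("annotation matrix needs term rownames and domain colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate term ids")
  if (anyDuplicated(colnames(m))) stop("duplicate domain ids")
  storage.mode(m) <- "integer"
  m
}
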