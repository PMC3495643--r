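# Readers/writers for the standard plain-text formats the pipeline shares:
# Newick trees (edge confidences as internal node labels), aligned FASTA,
# PHYLIP square distance matrices, and TSV label/annotation tables.

#' Read / write Newick trees
#'
#' Thin wrappers over ape's Newick parser.  Edge confidences are stored as
#' internal node labels and branch lengths after colons.  Quoted labels are
#' accepted on read; on write, ape's convention replaces spaces in labels
#' with underscores.
#'
#' @param path file path.
#' @param tree a `phylo` object.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  unquote <- function(x) sub("^'(.*)'$", "\\1", x)
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in ", path)
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write an aligned FASTA file
#'
#' @param path file path.
#' @param alignment character matrix of residues, rows named by sequence.
#' @return `read_fasta_alignment` returns a character matrix (residues
#'   uppercased); `write_fasta_alignment` returns `path` invisibly.
#' @export
read_fasta_alignment <- function(path) {
  seqs <- ape::read.FASTA(path, type = "AA")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids in ", path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences in ", path, " have unequal lengths (not an alignment)")
  m <- toupper(as.character(as.matrix(seqs)))
  rownames(m) <- names(seqs)
  m
}

#' @rdname read_fasta_alignment
#' @export
write_fasta_alignment <- function(alignment, path) {
  a <- as_alignment(alignment)
  ape::write.FASTA(ape::as.AAbin(a), file = path)
  invisible(path)
}

#' Read / write a PHYLIP square distance matrix
#'
#' Format: first line the number of taxa, then one line per taxon with its
#' id followed by the full row of distances.  Asymmetries beyond `tol` are
#' rejected on read.
#'
#' @param path file path.
#' @param m square symmetric matrix with ids as dimnames.
#' @param tol symmetry tolerance.
#' @return `read_phylip_matrix` returns a validated matrix;
#'   `write_phylip_matrix` returns `path` invisibly.
#' @export
read_phylip_matrix <- function(path, tol = 1e-6) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop(path, ":1: expected taxon count")
  if (length(lines) < n + 1L)
    stop(path, ": expected ", n, " rows, found ", length(lines) - 1L)
  ids <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(parts) != n + 1L)
      stop(path, ":", i + 1L, ": expected id + ", n, " values, found ",
           length(parts) - 1L)
    ids[i] <- parts[1L]
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(vals)) stop(path, ":", i + 1L, ": non-numeric distance")
    m[i, ] <- vals
  }
  if (anyDuplicated(ids)) stop(path, ": duplicate ids")
  dimnames(m) <- list(ids, ids)
  as_dist_matrix(m, tol = tol)
}

#' @rdname read_phylip_matrix
#' @export
write_phylip_matrix <- function(m, path) {
  m <- as.matrix(m)
  ids <- rownames(m)
  lines <- c(format(nrow(m)),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(ids[i], format(m[i, ], trim = TRUE)),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a domain label table
#'
#' Tab-separated with header `domain_id`, `family_id`, `superfamily_id`.
#'
#' @param path file path.
#' @param labels a [scop_labels] object.
#' @return `read_labels_tsv` returns a [scop_labels];
#'   `write_labels_tsv` returns `path` invisibly.
#' @export
read_labels_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("domain_id", "family_id", "superfamily_id")
  if (!all(need %in% names(tab)))
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  scop_labels(tab$domain_id, tab$family_id, tab$superfamily_id)
}

#' @rdname read_labels_tsv
#' @export
write_labels_tsv <- function(labels, path) {
  labels <- as_scop_labels(labels)
  utils::write.table(
    data.frame(domain_id = labels$domain, family_id = labels$family,
               superfamily_id = labels$superfamily),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an annotation table
#'
#' Tab-separated with header `term_id`, `domain_id`; one row per
#' (term, domain) presence.
#'
#' @param path file path.
#' @param m binary term x domain matrix.
#' @param all_domains optional full domain universe for the matrix columns.
#' @return `read_annotations_tsv` returns a binary term x domain matrix;
#'   `write_annotations_tsv` returns `path` invisibly.
#' @export
read_annotations_tsv <- function(path, all_domains = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("term_id", "domain_id")
  if (!all(need %in% names(tab)))
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  annotation_matrix(tab$term_id, tab$domain_id, all_domains = all_domains)
}

#' @rdname read_annotations_tsv
#' @export
write_annotations_tsv <- function(m, path) {
  m <- as_annotation_matrix(m)
  hit <- which(m == 1L, arr.ind = TRUE)
  utils::write.table(
    data.frame(term_id = rownames(m)[hit[, 1L]],
               domain_id = colnames(m)[hit[, 2L]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
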