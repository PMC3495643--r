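# Synthetic SCOP-like data with known ground truth.
#
# Hierarchies (superfamilies > families > domains), ultrametric trees in
# which families are clades, alignments evolved along those trees under an
# equal-rates 20-state model, noisy "structural" distance matrices and
# level-targeted annotations -- everything downstream of real SCOP/ASTRAL/
# GOA inputs, generated with a single seed.

# sample() treats a length-1 numeric vector as 1:n; this does not
resample <- function(x, ...) x[sample.int(length(x), ...)]

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Configuration of the synthetic data generator
#'
#' @param n_superfamilies number of superfamilies.
#' @param families_per_superfamily integer range `c(lo, hi)` of families per
#'   superfamily.
#' @param domains_per_family integer range `c(lo, hi)` of domains per
#'   family.
#' @param within_family_height expected substitutions/site from a family's
#'   ancestor to its leaves.
#' @param between_family_height expected substitutions/site from the
#'   superfamily root to the leaves; must be >= `within_family_height`.
#' @param alignment_length number of alignment columns.
#' @param n_terms number of annotation terms to simulate.
#' @param term_level_probabilities probabilities of targeting a term at the
#'   subfamily / family / multi-family / superfamily / multi-superfamily
#'   level (5-vector summing to 1).
#' @param annotation_dropout probability that a true presence is lost.
#' @param annotation_spurious probability that a false presence is added
#'   per (term, domain) cell.  Note this scales with the domain universe:
#'   the expected number of spurious presences per term is roughly
#'   `annotation_spurious * n_domains`, so the default is small -- false
#'   assignments are rare in curated annotation sets, incompleteness is the
#'   dominant noise.
#' @param distance_noise_sd relative (multiplicative Gaussian) noise on the
#'   synthetic structural distances.
#' @param seed integer master seed; all randomness flows from it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_superfamilies = 50L,
                             families_per_superfamily = c(2L, 5L),
                             domains_per_family = c(2L, 6L),
                             within_family_height = 0.2,
                             between_family_height = 0.8,
                             alignment_length = 500L,
                             n_terms = 200L,
                             term_level_probabilities = rep(0.2, 5),
                             annotation_dropout = 0.1,
                             annotation_spurious = 1e-4,
                             distance_noise_sd = 0.1,
                             seed = 1L) {
  cfg <- list(n_superfamilies = as.integer(n_superfamilies),
              families_per_superfamily = as.integer(families_per_superfamily),
              domains_per_family = as.integer(domains_per_family),
              within_family_height = within_family_height,
              between_family_height = between_family_height,
              alignment_length = as.integer(alignment_length),
              n_terms = as.integer(n_terms),
              term_level_probabilities = term_level_probabilities,
              annotation_dropout = annotation_dropout,
              annotation_spurious = annotation_spurious,
              distance_noise_sd = distance_noise_sd,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_superfamilies >= 1L,
              length(families_per_superfamily) == 2L,
              length(domains_per_family) == 2L,
              families_per_superfamily[1L] <= families_per_superfamily[2L],
              domains_per_family[1L] <= domains_per_family[2L],
              within_family_height >= 0,
              between_family_height >= within_family_height,
              alignment_length >= 1L,
              n_terms >= 0L,
              length(term_level_probabilities) == 5L,
              all(term_level_probabilities >= 0),
              all(term_level_probabilities <= 1),
              abs(sum(term_level_probabilities) - 1) < 1e-9,
              annotation_dropout >= 0, annotation_dropout <= 1,
              annotation_spurious >= 0, annotation_spurious <= 1,
              distance_noise_sd >= 0)
  })
  # ranges must admit a retainable superfamily: >=2 families, a family with
  # >=2 members, >=4 domains in total
  if (cfg$families_per_superfamily[2L] < 2L)
    stop("families_per_superfamily must allow >= 2 families")
  if (cfg$domains_per_family[2L] < 2L)
    stop("domains_per_family must allow a family of >= 2 members")
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a SCOP-like two-level hierarchy
#'
#' Samples family and domain counts within the configured ranges, adjusted
#' (within the ranges) so that every superfamily survives
#' [filter_superfamilies]: at least two families, at least one family with
#' two or more members, at least four domains.
#'
#' @param config a [generator_config].
#' @return A [scop_labels] object. Deterministic for a fixed seed.
#' @export
generate_hierarchy <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  f_rng <- pmax(config$families_per_superfamily, c(2L, 2L))
  d_rng <- config$domains_per_family
  rows <- lapply(seq_len(config$n_superfamilies), function(i) {
    sf <- sprintf("SF%03d", i)
    nf <- resample(f_rng[1L]:f_rng[2L], 1L)
    sizes <- resample(d_rng[1L]:d_rng[2L], nf, replace = TRUE)
    if (max(sizes) < 2L) sizes[1L] <- 2L
    while (sum(sizes) < 4L) {
      grow <- which(sizes < d_rng[2L])
      if (!length(grow)) stop("domain range cannot reach 4 domains")
      sizes[grow[1L]] <- sizes[grow[1L]] + 1L
    }
    fam <- sprintf("%s_F%02d", sf, seq_len(nf))
    data.frame(domain = unlist(lapply(seq_len(nf), function(k)
                 sprintf("%s_D%02d", fam[k], seq_len(sizes[k])))),
               family = rep(fam, sizes),
               superfamily = sf, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  scop_labels(tab$domain, tab$family, tab$superfamily)
}

# internal: random ultrametric subtree over given leaves, scaled to height h
scaled_coalescent <- function(leaves, h) {
  n <- length(leaves)
  if (n == 1L) return(NULL)
  tr <- ape::rcoal(n, tip.label = leaves)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- if (depth > 0) tr$edge.length * h / depth
                    else tr$edge.length
  if (h == 0) tr$edge.length[] <- 0
  tr
}

#' Generate the true tree of one superfamily
#'
#' Families are monophyletic by construction: per-family random coalescent
#' subtrees of height `within_h` are attached to the tips of a random
#' between-family backbone, itself of height `between_h - within_h`, so all
#' leaves sit at depth `between_h` and every family forms a clade.
#'
#' @param labels_sf a [scop_labels] subset for one superfamily with >= 2
#'   families.
#' @param within_h,between_h tree heights in expected substitutions/site,
#'   `between_h >= within_h`.
#' @param seed integer seed.
#' @return A rooted ultrametric `phylo` tree over the superfamily's
#'   domains.
#' @export
generate_superfamily_tree <- function(labels_sf, within_h, between_h,
                                      seed = 1L) {
  labels_sf <- as_scop_labels(labels_sf)
  if (length(unique(labels_sf$superfamily)) != 1L)
    stop("labels must cover exactly one superfamily")
  fams <- split(labels_sf$domain, labels_sf$family)
  if (length(fams) < 2L) stop("need >= 2 families")
  if (between_h < within_h) stop("between_h must be >= within_h")
  set.seed(seed)
  slots <- sprintf("FAMSLOT%03dX", seq_along(fams))
  backbone <- scaled_coalescent(slots, between_h - within_h)
  bb_txt <- ape::write.tree(backbone)
  for (k in seq_along(fams)) {
    subtree <- scaled_coalescent(fams[[k]], within_h)
    rep_txt <- if (is.null(subtree)) fams[[k]][1L]
               else sub(";$", "", ape::write.tree(subtree))
    bb_txt <- sub(slots[k], rep_txt, bb_txt, fixed = TRUE)
  }
  ape::read.tree(text = bb_txt)
}

#' Evolve a gap-free amino-acid alignment along a tree
#'
#' Sites evolve independently under the 20-state equal-rates model (the
#' amino-acid analogue of Jukes-Cantor): all exchange rates equal, uniform
#' stationary frequencies, branch lengths in expected substitutions/site.
#' The expected proportion of differing sites between two leaves at tree
#' distance `d` is `(19/20) * (1 - exp(-20 d / 19))`.
#'
#' @param tree a `phylo` tree with branch lengths in substitutions/site.
#' @param length number of columns (>= 1).
#' @param seed integer seed.
#' @return Character matrix of residues, rows named by leaf.
#' @export
simulate_alignment <- function(tree, length, seed = 1L) {
  if (length < 1L) stop("alignment length must be >= 1")
  set.seed(seed)
  sim <- phangorn::simSeq(tree, l = length, type = "AA",
                          Q = rep(1, 190), bf = rep(1 / 20, 20))
  m <- toupper(as.character(sim))
  rownames(m) <- names(sim)
  m
}

#' Noisy structural distance matrix from a true tree
#'
#' Emulates automatically generated structural distances: the patristic
#' (path-length) distance on the true tree, perturbed by independent
#' multiplicative Gaussian noise per pair and truncated at zero.
#'
#' @param tree the true `phylo` tree.
#' @param noise_sd relative noise scale.
#' @param seed integer seed.
#' @return Symmetric distance matrix over the leaves.
#' @export
noisy_distance_matrix <- function(tree, noise_sd = 0.1, seed = 1L) {
  d <- ape::cophenetic.phylo(tree)
  d <- d[sort(rownames(d)), sort(rownames(d))]
  set.seed(seed)
  n <- nrow(d)
  eps <- matrix(0, n, n)
  eps[upper.tri(eps)] <- stats::rnorm(n * (n - 1L) / 2L, 0, noise_sd)
  eps <- eps + t(eps)
  out <- pmax(d * (1 + eps), 0)
  diag(out) <- 0
  dimnames(out) <- dimnames(d)
  as_dist_matrix(out)
}

#' Simulate level-targeted annotations
#'
#' Each term targets a noise-free presence set at one of five levels chosen
#' by `term_level_probabilities`: a strict subset of one family, one whole
#' family, a union of >= 2 (but not all) whole families of one superfamily,
#' one whole superfamily, or >= 2 whole superfamilies.  Dropout then removes
#' each presence independently with probability `annotation_dropout`, and
#' spurious presences are added with probability `annotation_spurious` per
#' absent cell.  The ground-truth level of every term is recorded.
#'
#' @param labels a [scop_labels] object.
#' @param config a [generator_config]; the annotation fields and `seed` are
#'   used.
#' @return List: `matrix` (binary term x domain, with noise), `truth`
#'   (data frame `term`, `level`), `clean` (the noise-free matrix).
#' @export
simulate_annotations <- function(labels, config) {
  stopifnot(inherits(config, "generator_config"))
  labels <- as_scop_labels(labels)
  set.seed(config$seed + 1L)
  levels5 <- c("subfamily", "family", "multi_family", "superfamily",
               "multi_superfamily")
  fam_sizes <- table(labels$family)
  fams_per_sf <- table(labels$superfamily[!duplicated(labels$family)])
  can <- c(subfamily = any(fam_sizes >= 2L),
           family = TRUE,
           multi_family = any(fams_per_sf >= 3L),
           superfamily = TRUE,
           multi_superfamily = length(fams_per_sf) >= 2L)
  p <- config$term_level_probabilities
  if (any(p > 0 & !can))
    stop("unrealisable term levels for this hierarchy: ",
         paste(levels5[p > 0 & !can], collapse = ", "))
  doms_of_fam <- split(labels$domain, labels$family)
  doms_of_sf <- split(labels$domain, labels$superfamily)
  fams_of_sf <- lapply(split(labels$family, labels$superfamily), unique)
  n_terms <- config$n_terms
  terms <- sprintf("T%04d", seq_len(n_terms))
  lev <- sample(levels5, n_terms, replace = TRUE, prob = p)
  target <- lapply(lev, function(l) {
    switch(l,
      subfamily = {
        f <- sample(names(fam_sizes)[fam_sizes >= 2L], 1L)
        d <- doms_of_fam[[f]]
        sample(d, sample.int(length(d) - 1L, 1L))
      },
      family = doms_of_fam[[sample(names(doms_of_fam), 1L)]],
      multi_family = {
        sf <- sample(names(fams_per_sf)[fams_per_sf >= 3L], 1L)
        fs <- fams_of_sf[[sf]]
        k <- resample(2:(length(fs) - 1L), 1L)
        unlist(doms_of_fam[sample(fs, k)], use.names = FALSE)
      },
      superfamily = doms_of_sf[[sample(names(doms_of_sf), 1L)]],
      multi_superfamily = {
        k <- resample(2:min(3L, length(doms_of_sf)), 1L)
        unlist(doms_of_sf[sample(names(doms_of_sf), k)], use.names = FALSE)
      })
  })
  clean <- matrix(0L, n_terms, nrow(labels),
                  dimnames = list(terms, labels$domain))
  for (i in seq_len(n_terms)) clean[i, target[[i]]] <- 1L
  noisy <- clean
  if (config$annotation_dropout > 0) {
    drop <- matrix(stats::runif(length(noisy)) < config$annotation_dropout,
                   nrow(noisy))
    noisy[clean == 1L & drop] <- 0L
  }
  if (config$annotation_spurious > 0) {
    add <- matrix(stats::runif(length(noisy)) < config$annotation_spurious,
                  nrow(noisy))
    noisy[clean == 0L & add] <- 1L
  }
  list(matrix = noisy,
       truth = data.frame(term = terms, level = lev,
                          stringsAsFactors = FALSE),
       clean = clean)
}

#' Inject known misclassifications
#'
#' Moves `n_moves` distinct domains to a different family within their own
#' superfamily (only superfamilies with >= 2 families are eligible),
#' returning the perturbed labels and a log of the moves.  The input labels
#' are not modified.
#'
#' @param labels a [scop_labels] object.
#' @param n_moves number of domains to move.
#' @param seed integer seed.
#' @return List: `labels` (perturbed), `log` (data frame `moved_domain`,
#'   `from_family`, `to_family`).
#' @export
inject_misclassification <- function(labels, n_moves, seed = 1L) {
  labels <- as_scop_labels(labels)
  log <- data.frame(moved_domain = character(0), from_family = character(0),
                    to_family = character(0), stringsAsFactors = FALSE)
  if (n_moves == 0L) return(list(labels = labels, log = log))
  fams_of_sf <- lapply(split(labels$family, labels$superfamily), unique)
  movable <- labels$domain[lengths(fams_of_sf)[labels$superfamily] >= 2L]
  if (n_moves > length(movable))
    stop("n_moves exceeds the ", length(movable), " movable domains")
  set.seed(seed)
  moved <- sample(movable, n_moves)
  out <- labels
  for (d in moved) {
    i <- match(d, out$domain)
    from <- out$family[i]
    others <- setdiff(fams_of_sf[[out$superfamily[i]]], from)
    to <- if (length(others) == 1L) others else sample(others, 1L)
    out$family[i] <- to
    log <- rbind(log, data.frame(moved_domain = d, from_family = from,
                                 to_family = to, stringsAsFactors = FALSE))
  }
  list(labels = out, log = log)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running the whole generator: hierarchy, one true
#' tree and alignment per superfamily, noisy structural distances, and
#' annotations.  Per-superfamily seeds are drawn from the master seed.
#'
#' @param config a [generator_config].
#' @return List: `config`, `labels`, `trees`, `alignments`, `distances`
#'   (all named by superfamily), `annotations` (see
#'   [simulate_annotations]).
#' @export
simulate_study <- function(config = generator_config()) {
  labels <- generate_hierarchy(config)
  sfs <- sort(unique(labels$superfamily))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 3L * length(sfs))
  trees <- list(); alignments <- list(); distances <- list()
  for (i in seq_along(sfs)) {
    sf <- sfs[i]
    lab_sf <- superfamily_labels(labels, sf)
    trees[[sf]] <- generate_superfamily_tree(
      lab_sf, config$within_family_height, config$between_family_height,
      seed = seeds[3L * i - 2L])
    alignments[[sf]] <- simulate_alignment(
      trees[[sf]], config$alignment_length, seed = seeds[3L * i - 1L])
    distances[[sf]] <- noisy_distance_matrix(
      trees[[sf]], config$distance_noise_sd, seed = seeds[3L * i])
  }
  list(config = config, labels = labels, trees = trees,
       alignments = alignments, distances = distances,
       annotations = simulate_annotations(labels, config))
}
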