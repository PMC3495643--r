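test_that("minimal hierarchy and determinism", {
  cfg <- generator_config(n_superfamilies = 1,
                          families_per_superfamily = c(2, 2),
                          domains_per_family = c(2, 2), seed = 3)
  lab <- generate_hierarchy(cfg)
  expect_equal(length(unique(lab$superfamily)), 1L)
  expect_equal(length(unique(lab$family)), 2L)
  expect_equal(nrow(lab), 4L)
  expect_identical(lab, generate_hierarchy(cfg))
})

test_that("every generated superfamily survives the retention filter", {
  cfg <- generator_config(n_superfamilies = 50,
                          families_per_superfamily = c(2, 6),
                          domains_per_family = c(1, 8), seed = 7)
  lab <- generate_hierarchy(cfg)
  expect_length(filter_superfamilies(lab), 50L)
})

test_that("impossible ranges are rejected", {
  expect_error(generator_config(families_per_superfamily = c(1, 1)),
               ">= 2 families")
  expect_error(generator_config(domains_per_family = c(1, 1)),
               ">= 2 members")
  expect_error(generator_config(term_level_probabilities = rep(0.25, 5)))
  expect_error(generator_config(within_family_height = 0.5,
                                between_family_height = 0.1))
})

test_that("families are clades of the generated tree", {
  lab <- quartet_labels()
  tree <- generate_superfamily_tree(lab, 0.1, 0.5, seed = 4)
  keys <- tree_bipartitions(tree)$key
  expect_true(famaudit:::split_key(c("a", "b")) %in% keys)
  # single-family input rejected
  lab1 <- scop_labels(c("a", "b"), c("F", "F"), c("S", "S"))
  expect_error(generate_superfamily_tree(lab1, 0.1, 0.5), ">= 2 families")
  # leaves sit at the between-family height; family subtrees at within
  depths <- ape::node.depth.edgelength(tree)
  expect_equal(unname(depths[1:4]), rep(0.5, 4), tolerance = 1e-9)
})

test_that("zero within-family height collapses families to a point", {
  lab <- scop_labels(paste0("d", 1:6), rep(c("F", "G"), each = 3),
                     rep("S", 6))
  tree <- generate_superfamily_tree(lab, 0, 0.5, seed = 5)
  d <- ape::cophenetic.phylo(tree)
  expect_equal(d["d1", "d2"], 0, tolerance = 1e-12)
  expect_equal(d["d1", "d3"], 0, tolerance = 1e-12)
  expect_gt(d["d1", "d4"], 0.5)
})

test_that("true trees with perfect confidence never disagree (round trip)", {
  n_dis <- 0L
  for (i in 1:100) {
    cfg <- generator_config(n_superfamilies = 1,
                            families_per_superfamily = c(2, 4),
                            domains_per_family = c(1, 4), seed = 900 + i)
    lab <- generate_hierarchy(cfg)
    tree <- generate_superfamily_tree(lab, 0.1, 0.5, seed = i)
    v <- classify_tree(tree, lab, default_confidence = 100)
    n_dis <- n_dis + sum(v$verdict == "DISAGREE")
  }
  expect_equal(n_dis, 0L)
})

test_that("alignment simulation is deterministic and model-faithful", {
  lab <- quartet_labels()
  tree <- generate_superfamily_tree(lab, 0.1, 0.5, seed = 6)
  a1 <- simulate_alignment(tree, 100, seed = 8)
  expect_identical(a1, simulate_alignment(tree, 100, seed = 8))
  expect_equal(dim(a1), c(4L, 100L))
  expect_true(all(a1 %in% famaudit:::AA_ALPHABET))
  expect_error(simulate_alignment(tree, 0), ">= 1")
  # zero-length branches: all sequences identical
  t0 <- tree; t0$edge.length[] <- 0
  a0 <- simulate_alignment(t0, 50, seed = 9)
  expect_true(all(a0 == rep(a0[1, ], each = 4)))
})

test_that("observed p-distance matches the closed-form expectation", {
  # 20-state equal-rates model: p(d) = (19/20) (1 - exp(-20 d / 19))
  for (d in c(0.2, 0.8)) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
    L <- 10000
    a <- simulate_alignment(tr, L, seed = round(100 * d))
    p_obs <- mean(a["a", ] != a["b", ])
    p_exp <- (19 / 20) * (1 - exp(-20 * d / 19))
    se <- sqrt(p_exp * (1 - p_exp) / L)
    expect_lt(abs(p_obs - p_exp), 3 * se)
  }
})

test_that("noisy structural distances stay valid and near the truth", {
  lab <- quartet_labels()
  tree <- generate_superfamily_tree(lab, 0.1, 0.5, seed = 10)
  d0 <- noisy_distance_matrix(tree, noise_sd = 0, seed = 1)
  dt <- ape::cophenetic.phylo(tree)
  expect_equal(d0[rownames(dt), colnames(dt)], dt, tolerance = 1e-12)
  d1 <- noisy_distance_matrix(tree, noise_sd = 0.2, seed = 2)
  expect_true(all(d1 >= 0))
  expect_identical(d1, noisy_distance_matrix(tree, noise_sd = 0.2, seed = 2))
})

test_that("annotation targets honour their level; noise behaves", {
  cfg <- generator_config(n_superfamilies = 4, n_terms = 150,
                          annotation_dropout = 0, annotation_spurious = 0,
                          seed = 11)
  lab <- generate_hierarchy(cfg)
  ann <- simulate_annotations(lab, cfg)
  pl <- classify_placements(ann$matrix, lab)
  got <- merge(pl, ann$truth)
  expected <- c(subfamily = "SubFamily", family = "FamilyEquivalent",
                multi_family = "MultiFamily",
                superfamily = "SuperfamilyEquivalent",
                multi_superfamily = "MultiSuperfamilies")
  expect_identical(got$category, unname(expected[got$level]))
  # total dropout empties every row
  cfg2 <- generator_config(n_superfamilies = 4, n_terms = 20,
                           annotation_dropout = 1, annotation_spurious = 0,
                           seed = 12)
  ann2 <- simulate_annotations(lab, cfg2)
  expect_true(all(rowSums(ann2$matrix) == 0))
  # noise-free level fractions recover the target mix (binomial 99% bounds)
  cfg3 <- generator_config(n_superfamilies = 6, n_terms = 1000,
                           annotation_dropout = 0, annotation_spurious = 0,
                           seed = 13)
  lab3 <- generate_hierarchy(cfg3)
  ann3 <- simulate_annotations(lab3, cfg3)
  pl3 <- classify_placements(ann3$matrix, lab3)
  frac <- table(factor(unname(expected[ann3$truth$level]),
                       levels = expected)) / 1000
  for (lv in names(expected)) {
    got_frac <- mean(pl3$category == expected[[lv]])
    expect_lt(abs(got_frac - 0.2), 3.09 * sqrt(0.2 * 0.8 / 1000) + 1e-9)
  }
})

test_that("misclassification injection is exact, logged and reversible", {
  cfg <- generator_config(n_superfamilies = 5, seed = 14)
  lab <- generate_hierarchy(cfg)
  # n_moves = 0 is the identity
  id <- inject_misclassification(lab, 0, seed = 1)
  expect_identical(id$labels, lab)
  expect_equal(nrow(id$log), 0L)
  mv <- inject_misclassification(lab, 3, seed = 2)
  changed <- lab$family != mv$labels$family
  expect_equal(sum(changed), 3L)
  expect_setequal(mv$labels$domain[changed], mv$log$moved_domain)
  expect_true(all(mv$log$from_family != mv$log$to_family))
  # moves stay within the superfamily
  sf_of <- stats::setNames(lab$superfamily, lab$domain)
  fam_sf <- stats::setNames(lab$superfamily, lab$family)
  expect_identical(unname(fam_sf[mv$log$to_family]),
                   unname(sf_of[mv$log$moved_domain]))
  # determinism; original untouched
  mv2 <- inject_misclassification(lab, 3, seed = 2)
  expect_identical(mv$log, mv2$log)
  expect_error(inject_misclassification(lab, 10000), "exceeds")
})

test_that("an injected move disagrees on the true tree (detectable regime)", {
  # detectability needs >= 3 families or a source family of >= 3 members;
  # in a 2-family superfamily with a 2-member source family the only
  # informative edge reads NEUTRAL under the verdict precedence
  for (i in 1:20) {
    cfg <- generator_config(n_superfamilies = 1,
                            families_per_superfamily = c(3, 4),
                            domains_per_family = c(2, 4), seed = 1100 + i)
    lab <- generate_hierarchy(cfg)
    tree <- generate_superfamily_tree(lab, 0.1, 0.5, seed = i)
    mv <- inject_misclassification(lab, 1, seed = i)
    v <- classify_tree(tree, mv$labels, default_confidence = 100)
    expect_gte(sum(v$verdict == "DISAGREE"), 1L)
  }
})

test_that("the whole study is reproducible from one seed", {
  cfg <- generator_config(n_superfamilies = 2, alignment_length = 60,
                          families_per_superfamily = c(3, 5),
                          n_terms = 30, seed = 15)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$labels, s2$labels)
  expect_identical(lapply(s1$trees, ape::write.tree),
                   lapply(s2$trees, ape::write.tree))
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$annotations$matrix, s2$annotations$matrix)
})
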