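test_that("edge classification follows the agree/disagree/neutral rules", {
  lab <- quartet_labels()
  expect_identical(classify_edge(c("a", "b"), c("c", "d"), lab), "AGREE")
  expect_identical(classify_edge(c("a", "c"), c("b", "d"), lab), "DISAGREE")
  lab2 <- scop_labels(c("a", "b", "c", "d", "e"),
                      c("F", "F", "F", "G", "G"), rep("S", 5))
  expect_identical(classify_edge(c("a", "b"), c("c", "d", "e"), lab2),
                   "NEUTRAL")
  lab4 <- scop_labels(letters[1:8], rep(c("F", "G", "H", "I"), each = 2),
                      rep("S", 8))
  expect_identical(
    classify_edge(c("a", "b", "c", "d"), c("e", "f", "g", "h"), lab4),
    "CONSISTENT_MULTI")
  expect_error(classify_edge(c("a", "z"), c("b"), lab), "unlabelled")
})

test_that("edge classifier equals the naive set-algebra oracle", {
  # exhaustive over all bipartitions and <=3-family labelings, n = 4..6;
  # random labelings for n = 7, 8
  for (n in 4:8) {
    leaves <- paste0("L", seq_len(n))
    sides <- lapply(0:(2^(n - 1) - 2), function(mask) {
      bits <- as.logical(bitwAnd(mask, 2^(0:(n - 2)))) # leaf 1 fixed side A
      c(leaves[1], leaves[-1][bits])
    })
    labelings <- if (n <= 6) {
      do.call(expand.grid, rep(list(1:3), n))
    } else {
      set.seed(n)
      as.data.frame(matrix(sample(1:3, 200 * n, replace = TRUE), 200))
    }
    impl <- character(0); oracle <- character(0)
    for (r in seq_len(nrow(labelings))) {
      fam <- stats::setNames(paste0("F", unlist(labelings[r, ])), leaves)
      for (side_a in sides) {
        side_b <- setdiff(leaves, side_a)
        impl <- c(impl, classify_edge(side_a, side_b, fam))
        oracle <- c(oracle, naive_classify_edge(side_a, side_b, fam))
      }
    }
    expect_identical(impl, oracle)
  }
})

test_that("the true synthetic tree never disagrees with correct labels", {
  for (i in 1:10) {
    cfg <- generator_config(n_superfamilies = 1, seed = 500 + i)
    lab <- generate_hierarchy(cfg)
    tree <- generate_superfamily_tree(lab, 0.1, 0.6, seed = i)
    v <- classify_tree(tree, lab, default_confidence = 100)
    expect_equal(sum(v$verdict == "DISAGREE"), 0L)
  }
})

test_that("an injected misclassification creates a disagreement", {
  lab <- scop_labels(c("a", "b", "c", "d", "e"),
                     c("F", "F", "F", "G", "G"), rep("S", 5))
  tree <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,(d:1,e:1):1);")
  # move a into G: family F = {b,c}, G = {a,d,e}.  The {a,b} edge now has F
  # on both sides alongside G, which no neutral reading can absorb.
  moved <- scop_labels(c("a", "b", "c", "d", "e"),
                       c("G", "F", "F", "G", "G"), rep("S", 5))
  v0 <- classify_tree(tree, lab, default_confidence = 100)
  v1 <- classify_tree(tree, moved, default_confidence = 100)
  expect_equal(sum(v0$verdict == "DISAGREE"), 0L)
  expect_gte(sum(v1$verdict == "DISAGREE"), 1L)
  key <- famaudit:::split_key(c("a", "b"))
  expect_identical(v1$verdict[v1$key == key], "DISAGREE")
})

test_that("classify_tree verdicts equal the oracle on random labelings", {
  for (i in 1:25) {
    set.seed(600 + i)
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    fam <- stats::setNames(paste0("F", sample(1:3, n, replace = TRUE)),
                           tr$tip.label)
    lab <- scop_labels(tr$tip.label, fam, rep("S", n))
    v <- classify_tree(tr, lab, default_confidence = 1)
    for (k in seq_len(nrow(v)))
      expect_identical(v$verdict[k],
                       naive_classify_edge(v$side_a[[k]], v$side_b[[k]],
                                           fam))
  }
})

test_that("dustbin relaxation removes the scatter of one family", {
  # families F={a,b}, D={x,y}; tree ((a,x),(b,y)) interleaves D through F
  lab <- scop_labels(c("a", "b", "x", "y"),
                     c("F", "F", "D", "D"), rep("S", 4))
  tree <- ape::read.tree(text = "((a:1,x:1):1,(b:1,y:1):1);")
  plain <- classify_tree(tree, lab, default_confidence = 100)
  expect_gte(sum(plain$verdict == "DISAGREE"), 1L)
  db <- dustbin_classify(tree, lab, default_confidence = 100)
  expect_equal(db$n_disagree, 0L)
  expect_true(db$dustbin %in% c("D", "F"))  # either exclusion clears it
  # nothing to relax: dustbin is none, verdicts unchanged
  tree2 <- ape::read.tree(text = "((a:1,b:1):1,(x:1,y:1):1);")
  db2 <- dustbin_classify(tree2, lab, default_confidence = 100)
  expect_true(is.na(db2$dustbin))
  expect_identical(db2$verdicts$verdict,
                   classify_tree(tree2, lab,
                                 default_confidence = 100)$verdict)
})

test_that("dustbin count is the minimum over candidate exclusions", {
  for (i in 1:40) {
    set.seed(700 + i)
    n <- sample(6:9, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    fams <- paste0("F", sample(1:3, n, replace = TRUE))
    lab <- scop_labels(tr$tip.label, fams, rep("S", n))
    db <- dustbin_classify(tr, lab, default_confidence = 1)
    # brute force over candidates: drop each family, reclassify by hand
    fam <- family_map(lab)
    counts <- c(none = sum(classify_tree(tr, lab,
                             default_confidence = 1)$verdict == "DISAGREE"))
    for (d in unique(fams)) {
      keep <- tr$tip.label[fam[tr$tip.label] != d]
      if (length(keep) < 2) next
      bp <- tree_bipartitions(tr)
      cnt <- 0
      for (k in seq_len(nrow(bp))) {
        sa <- intersect(bp$side_a[[k]], keep)
        sb <- intersect(bp$side_b[[k]], keep)
        if (!length(sa) || !length(sb)) next
        if (naive_classify_edge(sa, sb, fam) == "DISAGREE") cnt <- cnt + 1
      }
      counts[d] <- cnt
    }
    expect_equal(db$n_disagree, min(counts))
    expect_lte(db$n_disagree, db$n_disagree_plain)
  }
})

test_that("superfamily verdict applies the confidence threshold", {
  v <- data.frame(key = c("k1", "k2"),
                  verdict = c("AGREE", "DISAGREE"),
                  confidence = c(90, 40), is_pendant = c(FALSE, FALSE))
  expect_equal(unname(superfamily_verdict(v, 80)), c(TRUE, FALSE))
  expect_equal(unname(superfamily_verdict(v, 30)), c(TRUE, TRUE))
  expect_equal(unname(superfamily_verdict(v, 101)), c(FALSE, FALSE))
  # pendant edges excluded by default
  vp <- data.frame(key = "k", verdict = "AGREE", confidence = 100,
                   is_pendant = TRUE)
  expect_equal(unname(superfamily_verdict(vp, 0)), c(FALSE, FALSE))
  expect_equal(unname(superfamily_verdict(vp, 0, include_pendant = TRUE)),
               c(TRUE, FALSE))
})

test_that("ROC sweep is monotone and order-invariant", {
  v1 <- data.frame(key = "k", verdict = "AGREE", confidence = 100,
                   is_pendant = FALSE)
  roc <- roc_curve(list(S1 = v1), thresholds = c(50, 80, 100, 101))
  expect_equal(roc$n_agreement, c(0, 1, 1, 1))
  expect_equal(roc$n_disagreement, rep(0, 4))
  set.seed(800)
  vlist <- lapply(1:8, function(i)
    data.frame(key = paste0("k", 1:3),
               verdict = sample(c("AGREE", "DISAGREE", "NEUTRAL"), 3,
                                replace = TRUE),
               confidence = sample(0:100, 3), is_pendant = FALSE))
  th <- c(0, 25, 50, 75, 100)
  up <- roc_curve(vlist, th)
  down <- roc_curve(vlist, rev(th))
  expect_identical(up, down)
  expect_true(all(diff(up$n_agreement) >= 0))      # thresholds decrease
  expect_true(all(diff(up$n_disagreement) >= 0))
  # at the loosest threshold counts equal direct existence checks
  loosest <- up[nrow(up), ]
  expect_equal(loosest$n_agreement,
               sum(vapply(vlist, function(v)
                 any(v$verdict == "AGREE"), TRUE)))
  expect_equal(loosest$n_disagreement,
               sum(vapply(vlist, function(v)
                 any(v$verdict == "DISAGREE"), TRUE)))
})
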