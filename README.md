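# famaudit

Hierarchical protein-domain classifications (SCOP and its kin) nest
families inside superfamilies. The superfamily level has a clean
evolutionary definition; the family level is curated and does not. famaudit
turns "what is a family?" into a testable question: **does each family form
a distinct phylogenetic group within its superfamily?** It is aimed at
people who maintain or consume domain classifications and want to audit
family-level groupings against evidence, and at method developers who need
a fully synthetic, ground-truthed test bed for tree-versus-taxonomy
concordance.

## What it computes

For every auditable superfamily (≥2 families, ≥1 family with ≥2 members,
\>3 domains), famaudit builds up to three trees:

* **sequence** — neighbour joining on Poisson-corrected p-distances,
  condensed from bootstrap replicates into a strict-majority consensus
  whose edges carry support `100 · occurrences / replicates`;
* **structure** — neighbour joining on a structural distance matrix (SAS
  scores, `100 · RMSD / n_matched`);
* **function** — neighbour joining on the mean character difference of a
  binary term × domain presence/absence matrix, after dropping terms
  present in ≤1 or all domains; edges are ranked by the number of terms
  diagnostic of the clade.

Every tree edge (bipartition *A*|*B* of the superfamily's domains) is then
classified against the family labels, testing in order:

1. **AGREE** — a side is exactly one complete family;
2. **NEUTRAL** — a side is a proper, pure subset of one family;
3. **DISAGREE** — some family has members on both sides alongside another
   family;
4. **CONSISTENT_MULTI** — both sides are unions of complete families.

On top of the per-edge verdicts sit: a *dustbin relaxation* (re-score with
the one family whose exclusion minimises disagreements removed), ROC-style
sweeps of agreement/disagreement counts over confidence thresholds, a
sequential-removal statistic for the maximum divergence within families
and superfamilies, and an eleven-category taxonomy placing each annotation
term's presence set in the hierarchy (from "subset of one family" to
"scattered across superfamilies"). A seeded generator produces SCOP-like
hierarchies, trees, alignments, distance matrices and annotations with
known ground truth, so the whole pipeline runs and is tested without any
external data.

## Worked example

```r
library(famaudit)

cfg   <- generator_config(n_superfamilies = 5, seed = 42)
study <- simulate_study(cfg)

labels <- superfamily_labels(study$labels, "SF001")
labels
#> <scop_labels> 8 domains, 2 families, 1 superfamilies

tree <- build_superfamily_tree("sequence",
                               alignment = study$alignments[["SF001"]],
                               n_replicates = 300, seed = 1)
verdicts <- classify_tree(tree, labels)
subset(verdicts, !is_pendant)[, c("verdict", "confidence")]
#>   verdict confidence
#> 1 NEUTRAL   97.66667
#> 2 NEUTRAL  100.00000
#> 5   AGREE  100.00000
#> 8 NEUTRAL  100.00000
#> 9 NEUTRAL   69.66667

superfamily_verdict(verdicts, threshold = 80)
#>    has_agreement has_disagreement
#>             TRUE            FALSE
```

The consensus tree isolates family `SF001_F02` as a clade with bootstrap
support 100 (the AGREE edge); the remaining internal edges sit inside
`SF001_F01` and are neutral. At threshold 80 the superfamily counts as
containing an agreement and no disagreement — its family grouping is
evolutionarily consistent with the sequence data.

```r
div <- greedy_max_divergence(identity_matrix(study$alignments[["SF001"]]))
sprintf("most distant pair: %s / %s at %.1f%% identity",
        div$pair[1], div$pair[2], div$identity)
#> "most distant pair: SF001_F01_D06 / SF001_F02_D02 at 21.2% identity"

summarize_placements(
  classify_placements(study$annotations$matrix, study$labels))$fractions
#>        one_family        sub_family multi_superfamily      intermediate
#>         0.1105528         0.2964824         0.1909548         0.4020101
```

The divergence statistic repeatedly removes the most redundant member of
the highest-identity pair until the two most distant domains remain; the
placement summary folds the eleven-category term taxonomy into the coarse
one-family / sub-family / multi-superfamily / intermediate split.

A command-line driver wrapping these functions (subcommands `simulate`,
`build-tree`, `classify`, `roc`, `divergence`, `go-levels`) is installed
at `system.file("cli/famaudit.R", package = "famaudit")`.

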