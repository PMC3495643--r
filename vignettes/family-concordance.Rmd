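---
title: "Auditing family groupings with independent phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing family groupings with independent phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famaudit)
```

## The question

Hierarchical domain classifications such as SCOP place every protein domain
in a family nested inside a superfamily. The superfamily level has a crisp
evolutionary definition; the family level is curated from a mixture of
sequence, structure and function signals and lacks one. famaudit asks a
falsifiable version of the question "what is a family?": *does each family
behave as a distinct phylogenetic group within its superfamily?* It builds,
for every superfamily, trees derived independently from three data sources
— a multiple sequence alignment, a matrix of structural distances, and
binary functional annotations — and scores every tree edge against the
family grouping.

## Edge classification

Removing one edge of an unrooted tree splits the superfamily's domains into
two sides (a bipartition). Each split is compared with the family labels:

* **AGREE** — one side is exactly one complete family: the edge isolates a
  family as a clade.
* **NEUTRAL** — one side holds some, but not all, members of a single
  family: an edge inside a family, uninformative about the grouping.
* **DISAGREE** — some family has members on both sides, in the company of
  another family: the tree interleaves families.
* **CONSISTENT_MULTI** — both sides are unions of two or more complete
  families. No family is split; the edge is consistent with the
  classification at a coarser granularity. It is counted as neutral in
  summaries but reported separately.

The rules are checked in the order AGREE, NEUTRAL, DISAGREE. The ordering
matters: read literally, a pure-but-incomplete side also satisfies the
disagree wording (its family has members on both sides, and other families
are present somewhere). Giving NEUTRAL precedence is the only reading under
which the canonical neutral example — families $F=\{a,b,c\}$, $G=\{d,e\}$,
split $\{a,b\}\,|\,\{c,d,e\}$ — is actually neutral, so that ordering is
adopted throughout.

A consequence worth knowing: a single mislabelled domain in a
**two-family** superfamily whose source family has only two members is
undetectable, because the one informative edge then reads NEUTRAL (the
complement is a pure incomplete family) and a pendant AGREE remains. With
three or more families, or a source family of three or more members, a
mislabelling always creates at least one DISAGREE edge somewhere in the
true topology. Detection rates on synthetic data should be interpreted
with this blind spot in mind.

Pendant edges (one side a single leaf) are classified but excluded from
superfamily-level summaries by default: a singleton side can only ever
read AGREE (for singleton families) or NEUTRAL, so it carries no grouping
evidence for multi-member families.

## Which superfamilies are auditable

A superfamily enters the audit only if the family grouping inside it could
in principle be contested: at least two families, at least one family with
two or more members, and more than three domains. `filter_superfamilies()`
applies exactly this rule.

## The three tree flavours

**Sequence.** Columns of the superfamily alignment are resampled with
replacement; each replicate yields a distance matrix and a
neighbour-joining tree, and the replicates are condensed into a
strict-majority consensus (a split is kept only when present in more than
half of the replicates). Each internal edge carries its support,
$100 \times \text{occurrences}/\text{replicates}$. The default is 300
replicates. The strict (>50%) rule is deliberately simpler than the
majority-rule-extended variant of some consensus programs; only
high-support edges (60 and above) matter downstream, and those are
identical under both rules. The per-replicate distance is the
Poisson-corrected p-distance $-\ln(1-p)$, a standard correction for
multiple substitutions, with plain p-distance available by flag; columns
gapped in either member of a pair are ignored (pairwise deletion), and
saturated pairs are clipped at a configurable ceiling (default 10
substitutions/site) with a warning.

**Structure.** A structural distance matrix — in real use, SAS scores,
$100 \times \mathrm{RMSD} / n_\text{matched}$, which normalise
superposition RMSD by alignment length — is fed directly to neighbour
joining. No bootstrap is possible for a single distance matrix, so edge
confidence is taken from the NJ branch length: long internal branches are
well-separated groups. A per-superfamily total-distance ranking is an
alternative mode; neither is claimed canonical, since ranking "by total
structural distance" admits both readings. `kabsch_rmsd()` provides the
superposition primitive (SVD with the determinant correction that
excludes reflections) for computing RMSDs from matched coordinates.

**Function.** Terms present in every domain or in at most one domain of a
superfamily are uninformative and dropped. The remaining binary
presence/absence matrix gives a mean-character-difference distance
(differing terms / total terms, in $[0,1]$; the scale-invariant choice
among the two plausible binary distances), and an NJ tree. Edge confidence
is the number of informative terms whose presence set equals one side of
the edge — terms diagnostic of that clade. A laxer subset-containment mode
is available behind a flag, since "terms which support an edge" is
ambiguous; exact equality is the default because it makes supports sum to
at most the number of informative terms.

## Dustbin relaxation

Superfamilies often retain a catch-all first family holding members that
share nothing in particular — a "dustbin". Scoring should not penalise the
classification for the scatter of one such family. For each candidate
family (and for no exclusion at all), the tree's bipartitions are
re-evaluated with the candidate's members removed — edges whose restricted
side becomes empty are dropped — and the option minimising the DISAGREE
count wins; ties prefer no exclusion, then the smallest family id. Because
"no exclusion" is always a candidate, the relaxed count can never exceed
the plain one. The classification does not say which family is the
dustbin, so minimisation over single-family exclusions is the most
permissive reading of "do not penalise".

## Threshold sweeps

`roc_curve()` counts, for each confidence threshold, the superfamilies
containing at least one AGREE edge and those containing at least one
DISAGREE edge at or above the threshold. Each superfamily is counted once
per threshold against both axes; both counts are non-decreasing as the
threshold falls. Thresholds are swept on whichever confidence scale the
flavour uses (bootstrap percent, branch length, or term count), so curves
from different flavours are comparable only by shape, not by x-position.

## Divergence statistics

The maximum divergence inside a group (family or superfamily) is found by
sequential removal: repeatedly locate the pair with the highest percent
identity and remove one of its members until two remain; the survivors are
the group's two most distant members. Which member of the top pair to drop
is under-determined; famaudit removes the one with the larger mean
identity to the remaining others, which preserves outliers (a
"remove-both" mode is available behind a flag). Pairs with no comparable
columns are flagged "no alignment" and treated as identity 0, collapsing
into the leftmost histogram bin. Groups of one are skipped.

## Term placement taxonomy

Each annotation term's presence set is placed into one of eleven mutually
exclusive categories by tallying, per touched superfamily, the families
that are complete, partial, or empty, then testing the categories in a
fixed order (first match wins): SubFamily, FamilyEquivalent, MultiFamily,
PartialFamily, ScatteredFamilies, ScatteredInSuperfamily,
AlmostSuperfamily, SuperfamilyEquivalent within one superfamily;
MultiSuperfamilies, PartialSuperfamilies, ScatteredSuperfamilies across
several. The prose definitions of these categories under-determine some
boundaries — e.g. a set that completes some families with exactly one
partial family and no empty one, which the fixed order sends to
AlmostSuperfamily, or a fully covered single-family superfamily, which
reads FamilyEquivalent rather than SuperfamilyEquivalent. The ordered
decision procedure is an interpretation, chosen for totality and
exclusivity: exhaustive enumeration over a 12-domain toy hierarchy (all
4095 presence sets) confirms every set lands in exactly one category. The
three-way summary folds these into: exactly one family (FamilyEquivalent),
a subset of one family (SubFamily), spanning superfamilies (the three
multi-superfamily categories), and an intermediate remainder.

## The synthetic generator

All tests run on generated data with known ground truth. The generator
emulates, per superfamily: a two-level classification; an ultrametric true
tree in which every family is a clade (per-family random coalescent
subtrees of height $h_w$ grafted onto a random between-family backbone so
all leaves sit at depth $h_b \ge h_w$); a gap-free amino-acid alignment
evolved along that tree under the 20-state equal-rates model (uniform
exchange rates and frequencies — the amino-acid analogue of Jukes–Cantor,
with closed-form expected p-distance
$p(d) = \tfrac{19}{20}(1 - e^{-20d/19})$ used to validate the simulator);
a noisy structural distance matrix (true path distances with independent
multiplicative Gaussian noise, truncated at zero); and annotation terms
targeted at one of five levels — subset of a family, one family, several
whole families, one superfamily, several superfamilies — with dropout and
spurious noise applied per cell.

Reference conditions, used by the acceptance checks and the
`scripts/acceptance.R` report: 50 superfamilies, 2–5 families of 2–6
domains, $h_w = 0.2$ and $h_b = 0.8$ substitutions/site (a four-fold
separation, under which within-family identity averages roughly 65% and
between-family identity roughly 20% — comfortably inside the zone where
sequence phylogenetics is informative), 500 alignment columns, 300
bootstrap replicates, annotation dropout 0.1 and spurious rate $10^{-4}$
per cell. The spurious default is small on purpose: being a per-cell
probability it scales with the size of the domain universe (~700 domains
at reference conditions), and false assignments are rare in curated
annotation sets — incompleteness, modelled by dropout, is the dominant
noise.

What the generator does **not** emulate: real SCOP size and depth
distributions (real superfamilies are highly skewed; ours are uniform in a
narrow range), alignment error (alignments are true by construction —
real low-identity superfamilies can produce unreliable alignments and
hence spurious disagreements), rate heterogeneity across sites and
lineages, annotation biases correlated with family size, or any 3-D
structure beyond what the superposition primitive needs. Passing tests
therefore certify the machinery — that the audit recovers known ground
truth and that every statistic equals its independent oracle — not the
empirical conclusions one would draw from real SCOP/GOA snapshots.

## Numerical choices

* Negative NJ branch-length estimates are clamped to zero.
* NJ tie-breaking follows the underlying implementation (ape); it is
  deterministic, which is what reproducibility requires.
* Consensus supports are stored as exact rationals times 100, serialised
  at 17 significant digits so Newick round-trips are bit-exact.
* Distance matrices are validated on construction: symmetry within 1e-8
  (asymmetries within tolerance are averaged away), zero diagonal,
  non-negativity.
* Saturated corrected distances clip at `ceiling` (default 10); pairs with
  no comparable columns get the ceiling with a warning.
* Greedy-removal ties (equal identity pairs, equal mean identity) break
  lexicographically, keeping the smaller id.
* All randomness descends from a single integer seed per entry point;
  per-superfamily seeds are drawn once from the master seed.

## Limitations

* The NEUTRAL-over-DISAGREE precedence makes single-move mislabellings in
  minimal (2-family, 2-member) superfamilies invisible, as discussed
  above.
* Structural edge confidence from branch lengths is on an arbitrary scale;
  thresholds for it cannot be compared with bootstrap percentages.
* The term-placement taxonomy treats terms as flat labels; no ontology
  hierarchy is consulted, so a parent and child term count as two
  independent terms.
* Real-data ingestion (FASTA + label TSV + PHYLIP matrices + annotation
  TSV) is supported but the package ships no real data; conclusions about
  real classifications require the user's own snapshots.
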