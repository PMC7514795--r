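---
title: "Concept decision trees: placing incomplete taxa on a seed phylogeny"
author: "cdtphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept decision trees: placing incomplete taxa on a seed phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdtphylo)
```

## The model

`cdtphylo` treats phylogenetic placement of incomplete, discretely coded
taxa as a cascade of binary classification problems. A rooted seed tree
over the relatively complete species is taken as given and *trusted*: the
method never rearranges it, it only decides where each held-back species
enters. Every internal node of the seed tree becomes a decision point: the
species below its first child form class 0 ("left", A subtree), those
below its second child class 1 ("right", B subtree), and the whole
character matrix is the condition attribute set C of a rough-set decision
table.

**Templates.** A concept-sample template is an attribute subset B together
with, per attribute, the set of states observed on the left and on the
right among the seed species under that node. A template is kept only if,
for every attribute, the two observed value sets are disjoint and
non-empty; otherwise it could not discriminate the node's sides.
Templates are found by a genetic algorithm over chromosomes of length N
(one site per attribute, codes `0..N`; equal non-zero codes form one
template; 0 = unselected), with fitness

$$F \;=\; \sum_{n=1}^{L} \frac{|C| - r_n}{|C|}$$

where a template of size $r_n$ contributes only when it preserves the
positive region, $POS_B(D) = POS_C(D)$. Many small positive-region-
preserving templates therefore beat few large ones: redundancy is exactly
what makes the method robust to missing entries at match time.

**Matching.** A species' row Q matches a template on the left iff its
state lies in the left value set for *every* template attribute (right
analogously); a missing value on any template attribute leaves both
tallies untouched. At each decision point all K templates vote; the
species descends towards the side with the larger tally and stops at a
leaf (attached as its sibling) or at a tie (attached as an extra child —
"species stacking"). Stacked polytomies are resolved agglomeratively by
merging the pair of children with the smallest single-linkage Wagner
distance (sum of absolute state differences over jointly observed
attributes, ties broken lexicographically).

## Assumptions

* The seed tree is correct; errors in it propagate to every placement.
* Character states are small non-negative integers; the Wagner distance
  treats them as ordered, the parsimony tree length as unordered.
* Decisions are binary: polytomies in the seed tree are resolved into a
  caterpillar (with a warning) before templates are built.
* Missing entries carry no information: a species missing a value on a
  template attribute is never forced to a side by that template, value
  sets never contain missing observations, and a seed species missing a
  value on any attribute of B forms its own singleton equivalence block
  (it is never asserted equal to anything).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` (splitSpecies) | 0.9 | completeness fraction above which a species joins sub1; there is no canonical value, 0.9 keeps sub1 genuinely "relatively complete" |
| `popSize` | 50 | GA population per decision point |
| `pc` | 0.8 | single-point crossover probability |
| `pm` | 0.1 | basic-bit mutation probability (one site redrawn) |
| `maxGen` | 100 | GA generations |
| `seed` | — | one integer seeding the whole build/graft/bootstrap |
| `replicates` (bootstrapAccuracy) | 1000 | character-bootstrap replicates; desk-scale runs use far fewer |

The GA operates per node on small decision tables, so its cost is driven
by `popSize × maxGen × N`. The compiled kernel (fitness and repair in
C++) makes the defaults affordable for matrices of a few dozen to ~150
attributes.

## Numerical choices

* Entropies are in bits (base 2); the base only rescales comparisons.
* Mutual-information equalities use a tolerance of 1e-9.
* The repair operator grows a deficient template by the attribute with
  the largest significance gain `SGF(a,R,D)`, preferring unselected
  attributes on ties, then the lowest index. Members of already-complete
  templates are not stolen; when only they remain as candidates the donor
  template is absorbed whole — the union's partition refines the donor's,
  so the union is complete immediately and no finished template is ever
  damaged. Among eligible donors the largest is absorbed, which sacrifices
  the least fitness and spares small (often singleton) templates.
* Roulette selection falls back to uniform sampling when every fitness is
  zero; elitism re-inserts the previous generation's best over the current
  worst, with random choice among tied bests.
* All randomness flows through R's RNG; a single seed reproduces the
  build, the grafting order outcome and the bootstrap stream exactly.

## The synthetic-data generator

`simulateTree()` draws rooted binary topologies uniformly (sequential
addition to a uniformly chosen edge, including the root edge);
`simulateCharacters()` evolves each character root-to-tip with a per-edge
jump probability (`changeRate`) to a uniformly chosen different state —
an Mk-like process without rate heterogeneity; `makeFixture()` designates
a random 60% of taxa as sub1, prunes the true tree to them as the seed
tree, and masks the sub2 rows. Defaults (40 taxa × 60 characters, 3
states, rate 0.15) emulate the scale of published morphological matrices
(tens of taxa and characters, a few states).

What the generator does **not** emulate: correlated characters, ordered
multistate evolution, clade-specific rates, and non-random missingness —
real morphological matrices have all four. Passing the recovery tests
therefore shows the machinery is faithful, not that real-data accuracy
will match.

## What the experiments show — and a known limitation

With *fully separating* characters (clade-indicator fixtures) grafting
recovers placements essentially perfectly, and the property suite holds:
seed topology is never altered, templates replay every seed species to
its true side, tree length never decreases when leaves are added, and
everything is reproducible from one seed.

Under the recovery conditions used in the acceptance suite (20 taxa, 40
characters, 3 states, change rate 0.15 per edge, 60/40 split, 20 seeds)
the mean path accuracy at 0% masking plateaus near 0.6–0.7, and near 0.79
even when every node is equipped with *all* cleanly separating single
attributes — the maximal template sets the disjoint-value-set rule
permits. The cause is structural: at 0.15 changes per edge on a 38-edge
tree each character changes ~5–6 times, so shallow nodes rarely have any
attribute whose left/right observed value sets are disjoint, and species
whose tallies tie there stack high in the tree. Species attaching on the
*stem* of a clade are a second intrinsic hard case: they lack the derived
states of both sides, so most of a clade's characters vote against them.
The masking curve behaves as expected: mean accuracy does not increase as
the missing proportion rises from 0% to 70% (within bootstrap confidence
intervals). Test and experiment problem sizes (tables of ≤8 species for
oracle comparisons, 20-taxon fixtures, 4 bootstrap replicates per masking
level) were chosen to keep the full suite at desk scale.

## Design choices where the design was open

* **sub1/sub2 threshold** is a parameter (default 0.9): "relatively
  complete" has no canonical cutoff.
* **Selection pool**: each generation selects from parents and offspring
  combined, then applies elitism.
* **Chromosome length** is fixed at N; the `(N+1)^N` count of distinct
  template assignments only holds for fixed-length codes.
* **Tie at a decision point (m = n > 0)**: the species attaches at the
  current node rather than guessing a side; the Wagner repair pathway
  then resolves the stack. Guessing would trade an auditable polytomy for
  silent error.
* **Clade identity across trees** (for path accuracy): a node is
  identified by the sorted set of seed (sub1) leaves below it, which makes
  path sequences comparable between trees that differ in grafted taxa.
  This is the largest interpretive choice in the evaluation module and is
  recorded in the placement metadata.
* **Tree length** is Fitch unordered parsimony with missing entries as
  wildcards, computed through phangorn's parsimony engine and verified
  against exhaustive assignment enumeration in the tests.
* **Bootstrap** resamples characters (columns) with replacement — the
  standard phylogenetic bootstrap — rebuilding the decision tree per
  replicate.
* **Grafted species never update templates**: decision points derive from
  sub1 only, so placements are order-independent at the template level
  (the tree, and hence stacking, still depends on grafting order).

## Limitations

* Binary decisions only; extensive seed-tree polytomies dilute the
  caterpillar resolution's meaning.
* No branch lengths and no support values on grafted edges.
* Placement quality is bounded by the existence of cleanly separating
  characters at shallow nodes (see above); datasets with heavy homoplasy
  near the root will see stacking there.
* Polymorphic codings (`{01}`) are rejected at parse time.
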