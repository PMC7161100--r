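---
title: "Guide-tree merging of leaf-disjoint phylogenies: model, algorithm, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide-tree merging of leaf-disjoint phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtmerge)
```

## The problem

Estimating a species tree on thousands of taxa is expensive, and the most
accurate methods often do not scale. A standard divide-and-conquer remedy
is to (i) compute a fast *starting tree* on all taxa, (ii) decompose the
taxon set into disjoint subsets using that tree, (iii) re-estimate a
high-quality tree on each subset with the preferred (slower) method, and
(iv) merge the subset trees back into one tree on the full taxon set.
Step (iv) is the disjoint tree merger (DTM) problem: the subset trees are
*leaf-disjoint*, so they carry no information at all about how they fit
together, and some auxiliary signal is required.

`gtmerge` implements a merger that uses a *guide tree* — a possibly
inaccurate tree on the full taxon set, in practice the starting tree
itself — as that auxiliary signal.

## The optimization criterion

All trees here are unrooted and leaf-labeled; `L(t)` is the leafset of
`t`. Every edge `e` of a tree induces a bipartition (split) of its
leafset, and `C(t)` denotes the set of nontrivial splits of `t` (both
sides with at least two taxa; trivial splits are shared by all trees on
a leafset and carry no information). The *false-negative (FN) distance*
from `A` to `B` is `|C(B) \ C(A)|`: the number of splits of `B` missing
from `A`. It is asymmetric; the familiar Robinson–Foulds distance is the
symmetric sum `FN(A,B) + FN(B,A)`. FN rather than RF is the right
objective because constraint trees and merged trees may be
multifurcating, and an unresolved region should not be penalized twice.

A *compatibility supertree* for constraint trees `T_1, ..., T_k` on
disjoint leafsets is a tree `T` on the union of their leafsets whose
homeomorphic restriction to each `L(T_i)` is exactly `T_i`. An
*unblended* merger is a compatibility supertree formed solely by adding
connecting edges between the constraint trees — internal nodes of
different constraint trees are never interleaved. The problem solved
here is: among all unblended mergers of the `T_i`, find one minimizing
the FN distance to the guide tree. (The blended variant of this problem
is NP-hard; the unblended variant admits the polynomial-time solution
implemented in this package. Unblendedness genuinely costs something:
see the worked example below, where no unblended merger can recover a
single guide split.)

## The algorithm

Classify each guide edge by how many constraint sets have leaves on both
of its sides:

* **0 sets — a bridge edge**: it separates whole constraint sets;
* **1 set — the edge lies within that set**;
* **2 or more sets — the edge violates convexity**: the constraint sets
  cannot be assigned to connected regions of the guide around it.

Say a split `A|B` *violates* a constraint tree `t` when its restriction
`A ∩ L(t) | B ∩ L(t)` is nontrivial and is not a split of `t`.

The merge then proceeds in two phases.

1. **Collapse.** Remove from the guide every edge that violates some
   constraint tree, then every edge that violates convexity. A collapsed
   split can never appear in *any* unblended merger: a split taken from
   inside one constraint component restricts trivially to every other
   constraint set, and an added bridge restricts trivially to all of
   them — so a split spanning two sets nontrivially, or restricting
   outside `C(T_i)`, is unachievable. Every surviving edge is a bridge
   or lies within a single set, and its restriction to that set is a
   split of the constraint tree.

2. **Rejoin.** Recursively: if the current component's leafset is one
   constraint set, return that constraint tree. Otherwise find a
   *border* — a bridge edge, or a polytomy where edges of two different
   constraint sets meet, which is first refined by pulling all edges of
   one set onto a fresh node, manufacturing a bridge. Delete the bridge,
   recurse on both sides, and reconnect the two partial supertrees by
   subdividing, on each side, an edge that induces the same bipartition
   as a neighbor edge of the deleted bridge. An inductive argument shows
   each partial supertree contains every split of its component, so the
   required attachment edge always exists (the package treats its
   absence as an internal invariant failure, and the test suite verifies
   it never occurs); the same induction shows every surviving guide
   split reaches the output. Together with phase 1 this gives exact
   optimality: the output misses precisely the collapsed splits, and no
   unblended merger can do better.

Attachment edges are located by subtree hashing — each taxon gets a
fixed pseudo-random weight, each edge is keyed by the weight-sum of the
leaves below it, and candidates matched by sum are verified exactly —
which keeps the whole merge at `O(N^2)` work. The package counts this
hashing work (`gtm_op_count()`), and the acceptance checks confirm the
empirical growth is no worse than quadratic (the measured log–log slope
on random instances from 250 to 2000 taxa is about 1.3–1.6).

```{r example}
guide <- parse_newick("(1,(2,(3,(4,(5,(6,(7,8)))))));")  # caterpillar
t1 <- parse_newick("(1,(5,(6,7)));")
t2 <- parse_newick("(2,(3,(4,8)));")
m <- gtm(guide, list(t1, t2))
m
```

Both constraint trees are induced subtrees of the caterpillar guide, so
the guide itself is a compatibility supertree — but a *blended* one.
Every internal guide edge is spanned by both constraint sets, the
collapse phase removes all five, and the best unblended merger has FN
distance 5: connecting two subset trees with one edge cannot reproduce
interleaved structure. The brute-force oracle
(`best_unblended()`) confirms the value by scanning all 25 attachment
pairs.

## Tunable parameters

* `max_size` (`B`) in `centroid_decomposition()`: the subset size bound,
  default 120 taxa — the customary subset size in divide-and-conquer
  species-tree pipelines, balancing subset-tree accuracy against
  subset-method cost. Any `B >= 1` is valid; `B = n` returns a single
  subset and the merge degenerates to returning the lone constraint
  tree.
* `random_ties` in `gtm()`: `NULL` (default) applies a deterministic
  tie-break policy; an integer seed draws all tie-breaks uniformly at
  random instead. Optimality is guaranteed for *any* tie-break, so the
  choice affects only which optimal merger is returned.
* `cap` in the oracle: a guard (default `1e6` candidate mergers) against
  combinatorial blowup; the oracle is meant for small instances only.

## Tie-breaking and determinism

Wherever the algorithm may choose "any" border node, separated set, or
neighbor edge, the deterministic policy picks: among bridge edges, the
one whose far side (the side not holding the overall smallest taxon)
has the smallest minimum taxon, then the smaller side; among junction
refinements, the first junction in traversal order and the constraint
set with the smallest member taxon; among neighbor edges, the one whose
far side holds the smallest taxon. These choices are arbitrary but
documented, and they make `write_newick(gtm(...)$supertree)`
byte-reproducible; the serializer itself orders children at every node
by smallest descendant taxon, so a topology has exactly one canonical
Newick rendering.

## Degenerate inputs and numerical choices

* Constraint trees with one or two leaves have no internal structure:
  single-node components attach directly at their vertex, two-leaf
  components at their only edge; the violation test is vacuous for them.
* Multifurcating guides are accepted as-is; multifurcating constraint
  trees are accepted and simply cause more guide edges to collapse (a
  star constraint collapses every guide edge with a nontrivial
  restriction to it). The `binary` qualifier in the formal problem
  statement is not essential to the algorithm and is not enforced.
* Branch lengths are carried through parsing, restriction and untouched
  edges, but the merge is purely topological: edges created by
  subdivision or joining carry no length, and collapsing sums nothing.
* Hash signatures use taxon weights drawn once from a fixed internal
  seed (uniform on [1, 2]); candidate matches within 1e-8 of the target
  sum are verified by exact set comparison, so hash collisions can cost
  time but never correctness.
* Rooted Newick input is accepted and unrooted by suppressing the
  degree-2 root, since essentially all tree files on disk are written
  rooted.

## What the synthetic generator does and does not emulate

`make_instance()` mirrors the *shape* of pipeline inputs: a true binary
tree (uniformly random topology), a centroid decomposition into subsets
of at most `B` taxa, constraint trees that are the true tree's induced
subtrees, and a guide tree derived from the true tree by a controlled
number of random NNI moves. NNI perturbation was chosen over SPR because
its effect on RF distance is bounded (at most 2 per move), giving guide
error that is controlled by construction.

Real pipeline inputs differ in two important ways: estimated constraint
trees contain errors (here they are exactly correct), and guide-tree
error from few-gene estimation under incomplete lineage sorting is
structured, not uniform NNI noise. Passing tests therefore demonstrate
the *algorithmic* guarantees — optimality, the compatibility contract,
scaling — not field accuracy on real data. Coalescent simulation, gene
tree estimation and sequence evolution are deliberately out of scope.

## Problem sizes used by the tests

The optimality gate compares the merge against brute force on 200
random instances (140 with k = 2 and constraint trees of at most 6
leaves, 60 with k = 3 and at most 4 leaves — both convexity-respecting
and arbitrary random partitions of the taxa); identity recovery runs up
to 128 taxa; the scaling check runs the full pipeline shape at 250–2000
taxa with B = 120. These sizes keep the brute-force oracle exact while
exercising every code path (bridges, junction refinement, vertex
attachment, multifurcations).

## Known limitations

* No blended merging: when the guide interleaves constraint trees, the
  optimal unblended FN can be far from 0 (the caterpillar example loses
  everything). This is inherent to the method, not an implementation
  limit.
* Exactly one guide tree is used; there is no support for merging with
  distance matrices or multiple guides.
* No branch lengths are estimated for the added edges.
* The recursion depth equals the number of bridge deletions, so
  extremely fragmented inputs (thousands of single-taxon constraint
  sets) approach R's recursion limits; the intended regime (subsets of
  tens to hundreds of taxa) is far from them.
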