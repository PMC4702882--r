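---
title: "Methods: hierarchically consistent orthologous groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchically consistent orthologous groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ognest)
```

# The problem

Orthologs are genes in different species that descend from a single gene in
their last common ancestor through speciation; paralogs descend through
duplication. Graph-based orthology inference clusters proteins into
orthologous groups (OGs) per taxonomic level — the clade whose common
ancestor defines group membership — which makes the resolution of the
groups level-dependent: one mammal-wide OG may correspond to two separate
rodent-specific OGs if a duplication predates the rodent radiation. ognest
implements the full cycle: per-level graph clustering, reconciliation of
the levels into a nested hierarchy, gene-tree-based pairwise orthology, and
annotation summarization/propagation, together with a simulator that
provides ground truth.

# Per-level clustering

The input is a filtered, symmetrized similarity graph. Three modelling
assumptions drive the clustering and deserve being explicit:

* **In-paralog rule.** Proteins $a,b$ of one species are collapsed when
  $s(a,b) \ge \max(\mathrm{bestout}(a), \mathrm{bestout}(b))$, with
  $\mathrm{bestout}(x)$ the best score of $x$ against any other species
  (0 if none). The rationale is the standard one: a within-species pair
  that is mutually closer than anything across species postdates the last
  speciation, hence is an in-paralog pair. The comparison is `>=`, so exact
  ties (which the simulator produces deliberately, see below) collapse.
* **Unit-level reciprocal best hits.** The score between two units is the
  maximum member-pair score; a unit pair is kept when each is the other's
  best in the partner species. *All* tied best partners are kept — dropping
  ties would make the result depend on input order.
* **Triangles.** Groups are seeded by BBH triangles spanning three distinct
  species, merged when sharing an edge. Because a unit may sit in two
  triangles that share only a vertex, and OGs must stay disjoint, clusters
  are implemented as connected components over triangle-participating
  edges — a superset of "merge triangles sharing an edge" forced by
  disjointness. A BBH edge in no triangle still links units of two
  species: if both are unclustered it forms a two-unit OG (without this,
  two-species levels could never produce any OG), if exactly one is
  clustered the other joins that group (processed in decreasing weight
  order, then lexicographically), and an edge between two different groups
  changes nothing.

Seed clusters, when supplied, are conserved afterwards: all computed groups
intersecting a seed are unioned with it, the origin is recorded, and a seed
forcing two seeds into one group merges them with a warning.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `threshold` in `filter_hits()` | 50 | bits | conventional storage cut-off for all-vs-all searches; read strictly (`> 50`): a hit at exactly 50 bits is dropped. The boundary is configurable because either convention exists in the wild. |
| symmetrization rule | max | — | of the two directed scores; max is monotone and preserves best-hit relations (min or mean could demote a genuine best hit). |

# Hierarchical consistency

Levels are scanned in leaf-to-root order (`leafward_order()`: each level
before its parent, ties lexicographic — the scan order is otherwise
arbitrary and only needs to be deterministic). For a child OG whose members
fall into $k \ge 2$ parent OGs, the member partitions are sorted largest
first (ties: more species first, then smallest member id) and examined as
consecutive pairs, winner against next:

* empty species overlap → the two **parent** OGs are merged. We merge the
  full parent OGs, not only the partitions; the alternative (re-clustering
  only the partition members at the parent) would leave the parent level
  internally inconsistent with its own graph clustering.
* non-empty overlap → the smaller partition's proteins are split out of
  the shared OG at the child level and at every level below where they
  still co-occur with the larger partition's proteins, forming their own
  OG at each affected level.

A single leaf-to-root pass does not guarantee the nesting invariant:
separations edit levels that were already scanned. `enforce_consistency()`
therefore repeats the full scan until a global fixed point, with a
termination guard of twice the total protein count (each resolution either
reduces the number of (child OG, parent OG) incidences or merges two parent
groups, so the fixed point exists; the guard converts a hypothetical
violation of that argument into a hard error instead of an endless loop).
The invariant — every OG wholly inside one parent OG, members unclustered
at the parent exempted — is re-checked after enforcement and asserted
across 100 simulated datasets in the test suite, along with idempotence and
protein conservation. Apparent inconsistencies caused by gene fusions are
*not* modelled; the invariant is enforced unconditionally.

# Pairwise orthology from gene trees

Trees are consumed, not inferred: alignment and tree reconstruction happen
upstream, ognest takes rooted Newick with `species.protein` leaf names.
An internal node is a **duplication** iff at least two of its child
subtrees share a species (multifurcations are treated as simultaneous
splits; any overlap counts, no fractional threshold — a threshold of zero
is the conservative choice when branch support is unknown, and is what the
exhaustive oracle test pins down). Leaf pairs partition into orthologs
(speciation LCA, different species), in-paralogs (same species) and
cross-species paralogs (duplication LCA, excluded from ortholog output).
Relations are typed by co-ortholog counts: $n_a$ = orthologs of $a$ in
$b$'s species and vice versa; $1/1$ → one2one, exactly one 1 → one2many,
else many2many. Unrooted input is rejected; midpoint rooting is available
behind `force_root = TRUE` since no rooting method is canonical.

# Annotation summarization and propagation

The consensus description is deliberately simple and auditable: lowercase
word n-grams (punctuation stripped, hyphens kept), a fixed stop-list
("protein", "putative", "hypothetical", "uncharacterized", "predicted",
"conserved"), pure numbers and accession-like tokens (a short letter prefix
followed by three or more digits) removed; the winner maximizes coverage,
then n-gram length, then character length, then lexicographic order; with
more than one description a winner must cover at least two of them. The
procedure is deterministic and idempotent.

Term frequencies divide by **annotated** members per namespace, not all
members — "relative frequency among genes we know anything about" is the
quantity a profile browser wants; the denominator is recorded alongside.
COG functional categories are carried through and inherited but never
predicted (training a category classifier is out of scope). After
reconciliation, OGs without a description inherit description and
categories from the nearest annotated ancestor OG (by member containment)
and are flagged `inherited = TRUE`, so applications can exclude them.

Viral-style post-processing: OGs are merged when they share an identical
majority (> 50% of members with data) Pfam clan architecture. Architecture
comparison is order-sensitive — clan-level granularity already forgives
domain substitutions, and ignoring order would merge genuinely different
architectures. Polyprotein cleavage takes 1-based inclusive chain
coordinates, discards any chain strictly containing another (smallest
units retained) and deduplicates identical products.

# The simulator

`simulate_taxonomy()` draws a Kingman-coalescent topology (two uniformly
chosen lineages coalesce per step) with coalescence heights $1, 2, \dots$ —
an ultrametric tree with integer node heights. This is a deliberate
numerical choice, not a biological claim: patristic distances are sums of
integers, so equal distances are *exactly* equal in floating point, and the
score ties that the clustering rules depend on (see below) are exact.
Levels are a random subset of internal nodes, root always included; species
sets are subtree leaves, so the hierarchy is nested by construction.

`simulate_family()` evolves one ancestral gene along the species tree: per
branch, each lineage duplicates with probability $1 - e^{-\lambda}$ and
each resulting lineage is lost with probability $1 - e^{-\mu}$ (one
duplication opportunity per lineage per branch; nested same-branch
duplications are not modelled). Duplication nodes are placed at the *top*
of the branch, i.e. at the parent node's height. This placement makes every
species outside the duplicated clade exactly equidistant to both copies, so
with zero noise its best hits tie across the copy lineages and the tied BBH
edges are precisely what reconnects ancient paralog lineages into the
single ancestral group that the ground truth defines. Ground truth at a
level groups extant genes by their ancestral copy at the level's root node;
these partitions are nested across levels by construction. Families with
fewer than two surviving genes carry no pairwise signal and are resampled
(bounded at 100 attempts).

`scores_from_family()` emits both directions of every pair as
$S_0 - \mathrm{decay} \cdot d + N(0, \sigma)$ floored at zero, with $d$ the
patristic distance. The defaults — 10 species, 4 levels, 3 families,
$\lambda = 0.1$, $\mu = 0.05$, $S_0 = 500$ bits, decay 10 bits per unit
distance, $\sigma = 5$ bits — keep all within-family scores far above the
50-bit threshold (minimum $500 - 10 \cdot 18 = 320$) while score *ranks*
can flip under noise, which is the failure mode the clustering actually
has to survive.

What the simulator does **not** emulate: sequence evolution (scores are a
linear-decay proxy; compositional biases, rate heterogeneity and alignment
artefacts are absent), horizontal transfer, gene fusion, assembly/proteome
quality problems, and within-branch duplication bursts. Passing tests
therefore demonstrate algorithmic correctness against the model's ground
truth, not performance on real proteomes.

# Verification strategy and problem sizes

The test suite cross-checks every non-trivial rule against an independent
oracle: in-paralog detection against brute-force predicate evaluation on
200 random graphs (≤ 20 proteins, ≤ 4 species); species-overlap labeling
against a naive recursion, exhaustively over all rooted binary tree shapes
with ≤ 7 leaves labeled from ≤ 3 species (about 29 000 trees); annotation
inheritance counts against a brute-force ancestor search; recovery metrics
against closed-form pair counting. Pipeline-level properties are asserted
over simulated datasets: the nesting invariant and idempotence of
enforcement (100 seeds), exact ground-truth recovery with $\mu = 0$,
$\sigma = 0$ (20 datasets), exact pairwise orthology on true trees and an
F ≥ 0.9 floor after perturbing 10% of internal edges by random
nearest-neighbour interchanges (200 families). These sizes keep the whole
suite around half a minute while still exercising hundreds of distinct
topologies per property.

# Known limitations

* The "split again on cross-lineage reciprocal best hits" refinement
  sometimes described for graph clustering is not implemented as a separate
  pass; all cross-level corrections are delegated to the consistency stage.
* Gene fusions violate the nesting invariant in real data; ognest enforces
  the invariant unconditionally.
* Unclustered singletons are tracked per level but not emitted as
  single-member OGs in the members files.
* The consensus-description heuristic is a transparent proxy; it will
  happily agree on an uninformative shared phrase if that is all the
  members share.
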