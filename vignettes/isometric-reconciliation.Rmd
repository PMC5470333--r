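---
title: "Isometric gene tree reconciliation: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isometric gene tree reconciliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A gene family evolves inside a species phylogeny by speciations,
duplications and losses. Given a gene tree `G_I` and a species tree `S_I`
*with branch lengths*, isometric reconciliation asks for a mapping `Φ` of
gene-tree nodes to points of the species tree that respects those lengths
exactly: whenever `u` is the parent of `v` in the rooted gene tree,
`Φ(u) = anc(Φ(v), d(u, v))`, the point exactly `d(u, v)` above the image
of `v`. The mapping interprets each gene node as a speciation or a
duplication at an exact time; points above the species root live on an
implicit infinite edge, so duplications predating the first speciation are
representable.

`isorec` implements this model in four settings:

* **both trees rooted** (`reconcile_rooted`): each internal gene node is
  placed from one descendant leaf, the implied new species nodes are
  materialized, and the candidate mapping is verified edge by edge. The
  reconciliation, when it exists, is unique, so the arbitrary leaf choice
  cannot matter — the `leaf_choice` argument exists only to let tests
  demonstrate that.
* **unrooted gene tree, rooted species tree**
  (`reconcile_unrooted_gene`, `reconcile_per_edge`): internal gene nodes
  are placed by *triangulation* from two already-placed relatives (the
  candidate images are level ancestors of the two known images; the
  descendant of the two candidates is the answer, and incomparable
  candidates prove irreconcilability). Each gene edge is then examined for
  the root: with `λ = lca(Φ(u), Φ(v))` and
  `ε = (d(u,v) − d(Φ(u),λ) − d(Φ(v),λ))/2`, the edge hosts the root iff
  `ε > 0` or `λ` differs from both images, the root sitting at offset
  `d(Φ(u),λ) + ε` from `u` and mapping to `anc(λ, ε)`. At most one edge
  may host the root; a final isometry check accepts or rejects.
* **both trees unrooted** (`reconcile_both_unrooted`): every internal
  species node, and every point inside every species edge, is a candidate
  root. The package runs the per-edge algorithm *parametrically* in the
  root offset ρ and reports the full solution set (see below).
* **rooted trees with an unknown gene-tree rate** (`reconcile_scaled`):
  all gene branch lengths are multiplied by an unknown factor α > 0.

## Exact arithmetic

Every branch length, depth, interval endpoint and breakpoint is an exact
rational (reduced integer pairs, overflow-checked). This is not a luxury:
the algorithms decide *equalities* — whether `ε` is exactly zero, whether
an image lands exactly on a node, where two linear forms in ρ cross — and
these questions are ill-posed in floating point. Decimal Newick literals
are converted exactly (`"0.1"` becomes 1/10, not the nearest double), and
non-decimal rationals are serialized as `"n/d"` fractions, which the
parser reads back. Rootedness is an input flag, never inferred from the
text; an unrooted tree written with a top-level bifurcation is read as a
phantom anchor and its two edges are merged.

## Query structures

The species tree is preprocessed into an index with (i) an Euler-tour +
sparse-table lowest-common-ancestor structure with O(1) queries, and
(ii) a weighted level-ancestor built on the heavy-path decomposition: an
edge to a child is heavy iff the child's subtree holds at least half of
the parent's, so any leaf-to-root path crosses O(log n) light edges, and
`anc(u, d)` is answered by walking heavy paths and binary-searching the
ascending node-weight array of the answering path — with exact rational
comparisons throughout. All queries accept implicit points `pt(u, h)`
(a height above a node, including heights above the root).

## The parametric algorithm for two unrooted trees

When the species root is an unknown point at distance ρ from `x_a` inside
edge `(x_a, x_b)`, every quantity in the per-edge algorithm is either
independent of ρ ("fixed") or a linear form `d + c·ρ` ("parametric",
always attached above the root). The package starts with the whole open
edge `(0, L)` as a candidate interval and refines:

1. **Step A** maps each endpoint of each gene edge from its fixed leaf
   pair. A level-ancestor query from a leaf has three regimes — fixed in a
   side subtree, parametric above the root, or crossing the root at a
   specific ρ, where the interval is split. The triangulation comparison
   between two parametric candidates is decided by solving
   `d₁ + c₁ρ = d₂ + c₂ρ`, splitting at an interior crossing.
2. **Steps B and C** compute `λ`, `ε` (whose slope always lies in
   {0, ±1/2, ±1, ±3/2, ±2}; the test suite asserts this on every run) and
   the edge-length checks, again splitting where a sign or equality flips.
3. Each gene edge is processed independently over the whole interval; the
   per-edge partitions are then overlaid on their pooled endpoints, and the
   root-selection and final verification stages refine further where they
   must. This one-pass overlay produces the same final partition as
   re-simulating pooled intervals to a fixed point, without the iteration —
   every per-edge decision is constant on any subinterval of the piece it
   was made on, so overlaying loses nothing.

Each final piece carries either a rejection or a *parametric history*:
the rooted gene tree (root possibly at a parametric offset inside one gene
edge) and a mapping whose images are fixed points or forms `pt(r, d+cρ)`.
`evaluate_at(ph, ρ)` substitutes any interior ρ and returns a concrete,
verified history. Interval boundaries and internal species nodes are never
taken as limits: each is checked by an exact fixed-root run. Adjacent
accepted intervals and boundary points are merged into maximal root sets
when the boundary's fixed-root history equals the one-sided limits of the
neighbouring parametric histories (computed by substituting the boundary ρ
and contracting the zero-length edges that appear); this is how half-open
answers such as "any ρ in [1, 4)" are reported. Whether such sets should
be merged at all is not dictated by the model; the limit-comparison rule
is this package's choice.

Degenerate inputs are handled uniformly: a single-leaf gene tree accepts
every rooting; a two-leaf gene tree has no internal node, so its root must
be found inside its only edge (the package handles this case explicitly).

## Scaling

If exactly one input tree is ultrametric (all leaves equidistant from the
root — judged over *mapped* species leaves only, which is equivalent to
deleting subtrees that carry no gene), no α can work. If neither is, any
leaf pair at unequal gene depths pins the only possible α via
`α·δ_G = δ_S`; the package takes the lexicographically first such pair,
requires `δ_S > 0` and verifies by a full reconciliation. If both are
ultrametric, reconciliation succeeds exactly for
`α ≥ α* = max_v h_S(x_v)/h_G(v)` over internal gene nodes `v`, where
`x_v` is the lca of the images of `v`'s leaf descendants and `h` denotes
height above the leaves. The claim itself gives only sufficiency of
`α ≥ α*`; its necessity argument (the image of `v` must be an ancestor of
`x_v`) justifies returning *irreconcilable* below the threshold, and the
test suite exercises 20 values straddling `α*`. In the degenerate case
`α* = 0` (every `x_v` a leaf, e.g. all genes in one species) any positive
α works; the certificate reports `α* = 0` and the returned history is
computed at α = 1.

## Histories: simple, inferable, and the simulator

A *simple* history has one event per species node: sample (leaf),
speciation, duplication (one child; every preimage has two children) or
loss (one child; every preimage a gene leaf). An *inferable* history is
what reconciliation can actually recover: positive lengths, only
observable gene nodes, and one-child species nodes only where a gene node
maps. `inferable_version()` maps the former to the latter (pruning lost
subtrees, bypassing unary nodes, contracting zero edges);
`expand_to_simple()` goes back, chaining simultaneous events with
zero-length edges, inserting explicit nodes on bypassing gene edges and
adding loss leaves for missing lineages — loss leaves are pendant at half
the remaining edge length, a deterministic choice where the construction
only requires "shorter than the edge". `admits_positive_simple()` checks
the classifier-based criterion for whether an inferable history is the
inferable version of some strictly-positive simple history.

The simulator (`simulate_simple_history`) generates the species tree by a
random birth process with dyadic-rational split times (grid 1/64, so all
downstream arithmetic keeps small denominators), an optional jitter mode
for non-ultrametric leaf depths, and a stem branch of length 1/2 above the
first speciation on which pre-speciation events can fall. Gene lineages
evolve top-down: every lineage splits at every speciation it reaches, and
experiences duplication and loss as Poisson events (default 0.3 events per
unit length each) at distinct grid times, each event inserting a dedicated
one-child species node. Default sizes in the test suite are 2–8 species
and at least 2–3 surviving genes (resampling under a retry budget), with
larger runs capped at 12–14 genes — sizes chosen so that thousands of
property checks stay interactive while still exercising multifurcations,
pre-speciation duplications and heavy loss.

What the simulator does *not* emulate: branch-length noise (all lengths
are exact by construction — the tolerance-based variant of the problem is
out of scope), rate heterogeneity across branches, horizontal transfer,
and gene lineages bypassing a speciation (bypasses are classified and
expanded correctly when present in a history, but the generative process
never creates them). Passing tests therefore certify the algorithms under
the exact-length model, not robustness to estimated branch lengths.

## Verification strategy

The suite is anchored on independent oracles rather than on the
implementation's own paths: naive edge-by-edge walks for level ancestors
and distances; brute-force fixed-root runs on a probe grid (all discovered
breakpoints plus interval midpoints) against the parametric solution set;
cross-checks between the stage-based and per-edge algorithms; and
ground-truth round trips in which a simulated history is reduced to its
reconciliation input and must be reproduced node-for-node, including
recovered roots and added duplication nodes. The instrumented parametric
runs additionally assert the structural bounds on interval splitting
(at most 5 endpoints per node mapping, 10 endpoints and 11 subintervals
per gene edge within one candidate interval).

## Known limitations

* Rational arithmetic overflows beyond numerators/denominators of 2^52 and
  stops with an error rather than losing exactness silently; extremely
  long decimal expansions in inputs would hit this.
* The rooted-gene/unrooted-species variant and tolerance-based
  reconciliation of noisy lengths are not implemented (open problems in
  this model).
* The explicit parametric representation of the species tree with all
  parametric nodes ordered is not constructed; parametric histories keep
  the species tree implicit, and `evaluate_at()` materializes it for any
  concrete root offset. This matches the algorithm's own default and
  avoids the extra quadratic interval splitting the explicit form needs.
* `solution_accepts` answers membership queries for node roots, discovered
  boundaries and open intervals; offsets are exact rationals, so callers
  probing with floating-point values must convert first.
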