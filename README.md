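# isorec

Isometric gene tree/species tree reconciliation with exact branch
lengths, in R.

## The problem

A gene family evolves inside a species phylogeny through speciations,
duplications and losses. Classical reconciliation uses topologies only;
*isometric* reconciliation additionally demands that the branch lengths of
the gene tree `G` and the species tree `S` be respected exactly: a mapping
`Φ` of gene nodes to points of the species tree is isometric when, for
every gene edge with parent `u` and child `v`,

    Φ(u) = anc(Φ(v), d(u, v)),

the point at distance exactly `d(u, v)` above the image of `v` (the level
ancestor; points above the species root live on an implicit infinite
edge). Gene nodes placed at species nodes are speciations; gene nodes
placed inside species edges are duplications, and the reconciled species
tree gains a one-child node at each such point.

`isorec` is intended for researchers studying gene family evolution with
trusted branch lengths (e.g. dated trees or infinite-sites-style
reconstructions). It provides:

* `reconcile_rooted()` — both trees rooted; the reconciliation is unique
  when it exists.
* `reconcile_unrooted_gene()` / `reconcile_per_edge()` — unrooted gene
  tree against a rooted species tree; the algorithm roots the gene tree,
  using triangulation from pairs of mapped nodes and an exact rule for
  placing the root inside a gene edge (two equivalent formulations).
* `reconcile_both_unrooted()` — both trees unrooted; returns the *set of
  all* reconciliations as exact root-position intervals on species edges
  (solved parametrically in the root offset, with breakpoints where
  decisions change), plus fixed-root answers at species nodes and interval
  boundaries.
* `reconcile_scaled()` — both trees rooted but gene branch lengths scaled
  by an unknown factor α: recovers the unique admissible α
  (non-ultrametric case) or the exact threshold α\* above which every α
  works (ultrametric case).
* a simple/inferable history formalism (`classify_species_node`,
  `inferable_version`, `expand_to_simple`, `is_inferable`,
  `admits_positive_simple`) and a seeded simulator
  (`simulate_simple_history`, `derive_input`) producing inputs with known
  ground truth.

All arithmetic is exact: branch lengths are rationals parsed exactly from
decimal Newick literals, so the equality tests at the heart of the
algorithms are well posed.

## Worked example

Reconciling an unrooted gene tree with a rooted species tree:

```r
library(isorec)
S  <- parse_newick("((B:2,C:2)x:1,A:3)r;", rooted = TRUE)
G  <- parse_newick("(b1:2,c1:2,a1:4)y;", rooted = FALSE)
mu <- parse_leaf_map(data.frame(gene = c("b1","c1","a1"),
                                species = c("B","C","A")), G, S)
res <- reconcile_unrooted_gene(input_history(G, S, mu))
print(res)
#> isometric reconciliation: reconciled
#>   G: (a1:3,(b1:2,c1:2)y:1)Q;
#>   S: (A:3,(B:2,C:2)x:1)r;
```

The gene tree has been rooted at a new node `Q`, placed 3 units above
`a1` and 1 unit above `y` — the only position where all distances fit.
The mapping interprets `y` as the speciation `x` and `Q` as the root
speciation `r`:

```r
h <- res$history
data.frame(gene = h$G$labels, maps_to = h$S$labels[h$phi])
#>   gene maps_to
#> 1   b1       B
#> 2   c1       C
#> 3   a1       A
#> 4    y       x
#> 5    Q       r
```

With both trees unrooted the answer is a set of root positions. Here two
gene copies in species `a` force a duplication; the species tree (a
single edge of length 6) can be rooted anywhere, but the reconciliation
changes shape at offset 1, where the duplication point crosses the root:

```r
S2  <- parse_newick("(a:3,b:3);", rooted = FALSE)
G2  <- parse_newick("(a1:0.5,a2:1.5);", rooted = FALSE)
mu2 <- parse_leaf_map(data.frame(gene = c("a1","a2"), species = c("a","a")),
                      G2, S2)
print(reconcile_both_unrooted(input_history(G2, S2, mu2)))
#> solution set for doubly-unrooted isometric reconciliation
#>   edge (a,b) length 6:
#>     (0,1): parametric reconciliation
#>     (1,6): parametric reconciliation
#>     rho = 1: reconciled
#>     accepted set (0,6)
```

The two open intervals carry parametric reconciliations (mappings linear
in the root offset ρ; instantiate one with `evaluate_at()`), the
breakpoint ρ = 1 is checked by an exact fixed-root run, and because all
three agree in the limit they are reported merged as one accepted set.

A command-line interface with `reconcile`, `simulate` and `check`
subcommands is installed at `inst/cli/isorec.R`
(`Rscript $(Rscript -e 'cat(system.file("cli","isorec.R",package="isorec"))') simulate --species 5 --seed 42 --out-prefix sim_`).

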