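# netfold

Folding and unfolding between rooted phylogenetic networks and
multi-labelled trees (MUL-trees), in R.

Reticulate evolution — hybridisation, allopolyploidy, lateral transfer —
is represented by rooted phylogenetic networks: leaf-labelled DAGs in
which a *reticulation* vertex (in-degree ≥ 2, out-degree 1) marks a
lineage with several parents. The same history can be carried by a
MUL-tree, a rooted tree whose leaves repeat labels (a gene tree of a
polyploid complex relabelled by species is the classic example). The two
pictures are connected by a pair of operations:

* **unfolding** $U(N)$ — the MUL-tree whose vertices are the directed
  root paths of $N$ (the pseudo tree of all paths is $U^*(N)$; the map
  sending each path to its last vertex is a *folding map*, the
  phylogenetic analogue of a graph fibration);
* **folding** $F(T)$ — merging the repeated subtrees of a MUL-tree into
  reticulations, via a guide tree $T^\dagger$ (one subdivision vertex per
  merged arc) and the quotient of $T^\dagger$ by equality of pseudo-subtree
  canonical forms.

`U(F(T)) \cong T` always; a network with `F(U(N)) \cong N` is **stable**.
The package implements, with verified certificates throughout:

* unfolding with the canonical folding map, and folding with a full trace
  (shrinking tree sequence, guide tree, vertex partition, quotient);
* stability via three routes — direct, the compressed + irreducible /
  identical-child-sets characterisation for semi-resolved networks, and
  the guide-tree criterion $U^*(N) \cong [U(N)]^\dagger$;
* X-morphisms and folding maps as explicit data, the five-property test
  for a vertex partition to be the fibres of a folding map, quotients,
  and unique lifting of morphisms through folding maps;
* tree display (brute force over reticulation arc choices), **weak
  display** (display inside the unfolding) by a polynomial dynamic
  program with locally separated reconciliation witnesses, and the
  HangLeaves reduction that turns any binary display instance into an
  equivalent one on a binary, compressed, tree-sibling (hence stable)
  network;
* exact isomorphism for MUL-trees (canonical codes) and networks (colour
  refinement + individualisation, with witness bijections);
* readers/writers for extended Newick, Newick with repeated labels and a
  lossless JSON edge list, all with canonical (isomorphism-invariant)
  output;
* seeded random generators for binary trees, MUL-trees and constrained
  networks, which supply every input used by the tests.

## A worked example

```r
library(netfold)

n1 <- fixture_n1()          # one reticulation r with parents u and v
write_enewick(n1)
#> "(((c)#H1,a),(#H1,b));"

u <- unfold(n1)             # MUL-tree of root paths: leaf c appears twice
write_mul_newick(u)
#> "((a,c),(b,c));"

isTRUE(network_isomorphic(fold(u)$result, n1))
#> TRUE                     # folding the unfolding recovers N1: stable

is_stable(n1)
#> <stability_report>
#>   stable (direct)        TRUE
#>   compressed             TRUE
#>   semi-resolved          TRUE
#>   irreducible            TRUE
#>   stable (child sets)    TRUE
#>   stable (guide tree)    TRUE

t1 <- read_mul_newick("((a,c),b);")
isTRUE(displays(n1, t1))                                   # TRUE
isTRUE(weakly_displays(n1, read_mul_newick("((a,b),c);"))) # FALSE

reconciliation(n1, t1)$r    # witness map into the tree vertices of N1
#>    t1    t2    t3    t4    t5
#> "rho"   "u"   "a"   "c"   "b"
```

The report reads: `N1` is stable, and all three theoretical routes agree.
The reconciliation maps the guest tree's root to the network root, its
cherry `(a,c)` to the tree vertex `u`, and each leaf to its label's leaf;
the path for the cherry-to-`c` arc runs through the reticulation.

A thin command-line front end is installed as `exec/netfold`
(subcommands `unfold`, `fold`, `stable`, `display`, `weak-display`,
`reconcile`, `reduce`, `generate`, `isomorphic`, `validate`; decision
subcommands answer through the exit code).

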