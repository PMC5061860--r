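---
title: "Folding MUL-trees and unfolding phylogenetic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folding MUL-trees and unfolding phylogenetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netfold)
```

## The objects

A **rooted phylogenetic network** on a label set $X$ is a rooted directed
acyclic graph with a single root of out-degree at least two in which every
other vertex is either a *tree vertex* (in-degree 1, out-degree 0 or
$\ge 2$) or a *reticulation* (in-degree $\ge 2$, out-degree 1), no vertex
has in- and out-degree one, and the leaves are labelled bijectively by $X$.
Reticulations model events — hybridisation, allopolyploidy, lateral
transfer — in which a lineage has more than one parent. When parallel arcs
are permitted we speak of an *X-network*; `netfold` carries parallel arcs
as first-class objects (arc *keys*) because folding can create them, while
the `phylo_network` validator rejects them.

A **MUL-tree** (multi-labelled tree) is a rooted tree whose leaves carry
labels from $X$ with repetition allowed; this is what one obtains, for
example, when a gene tree for a polyploid complex is relabelled by species.
A *pseudo* MUL-tree additionally allows degree-two (subdivision) vertices.

The package revolves around two constructions that connect these worlds:

* **Unfolding** `unfold_star()` / `unfold()`: the vertices of $U^*(N)$ are
  the directed paths of $N$ starting at the root, with an arc whenever one
  path extends another by a single arc. Suppressing the degree-two vertices
  (paths ending in a reticulation) gives the MUL-tree $U(N)$. The map
  $f^*$ sending each path to its final vertex is the canonical *folding
  map* onto $N$; in this sense $U^*(N)$ behaves like a universal cover of
  the network.
* **Folding** `fold()`: repeated subtrees of a MUL-tree $T$ are merged into
  reticulations. The pipeline finds *maximal inextendible* subtree classes
  (repeated subtrees not contained in larger repeated subtrees), shrinks
  the tree class by class while recording each step, replays the steps on a
  *guide tree* $T^\dagger$ — $T$ with one subdivision vertex inserted on
  every arc whose head carries a copy of a processed class — and finally
  takes the quotient of $T^\dagger$ by equality of pseudo-subtree canonical
  forms. Arc multiplicities in the quotient are the number of children a
  block representative has in the target block, so the result can contain
  parallel arcs; `fold()` asserts on every call that unfolding its result
  reproduces the input.

A network is **stable** when folding its unfolding returns the network
itself. `is_stable()` reports three routes to that answer: the direct
comparison, the characterisation by *compressed* (every reticulation's
child is a tree vertex) together with either *irreducibility* (no two tree
vertices whose root paths carry isomorphic unfolded subtrees) or the
absence of two tree vertices with identical child sets (the two are
equivalent for semi-resolved networks, i.e. when every internal tree
vertex has out-degree two), and the guide-tree criterion
$U^*(N)\cong [U(N)]^\dagger$, which holds unconditionally.

## Canonical forms

All isomorphism questions for trees are answered through sorted-multiset
codes built bottom-up: a leaf labelled $x$ becomes `L(x)`, a degree-two
vertex becomes `D(code of child)`, and any other vertex wraps the sorted
multiset of its children's codes in `I(...)`. Equal codes characterise
isomorphic (pseudo) MUL-trees exactly, subdivision patterns included; the
codes also give writers a canonical child order, so isomorphic objects
serialise to identical text. Networks are canonicalised by colour
refinement seeded with leaf labels and degrees, followed by
individualisation on ambiguous colour classes; leaf labels almost always
make refinement discrete at the sizes this package addresses, and the
procedure is exact, not heuristic. `network_isomorphic()` returns a
witness bijection when the answer is yes.

## The shrinking sequence: scars

The folding pipeline needs one genuinely delicate decision. The shrinking
sequence deletes all but one copy of a repeated subtree and, in the naive
formulation, tidies up by suppressing the degree-two vertex this leaves
behind. That tidying *forgets* structure: deleting a subtree below a
vertex can make the remainder accidentally isomorphic to a genuine smaller
repeated subtree elsewhere, and from then on the pipeline's behaviour —
and the final network — depends on the order in which classes were
processed. A concrete binary example found by the random generator made a
compressed, irreducible network fold "unstably" under one processing
order and stably under another.

`netfold` therefore tracks the sequence as pseudo MUL-trees with **scar
marks**: a vertex that loses a child keeps any resulting degree-two shape
and gains a scar count, and isomorphism within the sequence is
scar-annotated. A damaged vertex can never be mistaken for an undamaged
copy of a smaller subtree (for multifurcating vertices, where a removal
leaves no degree-two trace, the scar count alone carries the mark). Under
this bookkeeping the guide tree and the folded network are invariant under
the processing order — the package checks this across randomised
order-policies in its test suite — and all theorem-level equivalences
(the round trip, the sibling criterion for binary inputs, the stability
characterisations and the guide-tree criterion) hold on every randomised
check. The user-facing `tau` component of a fold trace still reports the
conventional suppressed MUL-tree view of each step.

One consequence is worth stating explicitly. With this semantics, sampled
non-binary tree-child networks are always stable (the test suite asserts
this on a fixed seed grid): the tree-child property forces every
reticulation's child to be a tree vertex and leaves every tree vertex a
private descending chain of in-degree-one vertices to a leaf, which rules
out identifiable pairs. Accounts that track the shrinking sequence with
suppression and no marks can classify such networks as unstable, but only
at the price of making the outcome order-dependent.

## Displaying and weakly displaying trees

A network *displays* a tree if some subgraph is a subdivision of the tree;
`displays()` answers this for binary instances by enumerating, per
reticulation, which incoming arc survives — exponential in the number of
reticulations, which is why the instance size is capped and why the
polynomial questions below matter. A tree is *weakly displayed* by a
network when the unfolding $U(N)$ displays it. `weakly_displays()` decides
this in $O(|V(T)|\cdot|V(N)|\cdot k)$ table updates by filling an
indicator $\tau(v,u)$ ("some tree vertex at or below $u$ roots a copy of
$T(v)$") over topological orders: a leaf row is set where its label lies
at or below $u$; an interior row is set when a child of $u$ is already
set, or when two *distinct* children of $u$ carry the two child subtrees.
The first disjunct is applied at every non-leaf vertex including the root,
which keeps the table monotone along ancestors. Backpointers prefer the
single-child disjunct and break ties by vertex id, so extracted witnesses
are reproducible for a given input object.

Positive answers are certified: `reconciliation()` follows the
backpointers into a *locally separated reconciliation* — a map from tree
vertices to tree vertices of the network plus one directed network path
per tree arc, such that the two paths leaving any vertex are non-empty
with distinct initial arcs — and `verify_reconciliation()` checks the
certificate independently. `reconciliation_morphism()` converts a
reconciliation into a subdivision of the tree together with an X-morphism
into the network, which `lift_morphism()` can lift through the canonical
folding map into $U^*(N)$; the composition is verified arc-by-arc in the
tests, with lift uniqueness confirmed by exhaustive search on small
instances.

The `stable_instance()` reduction shows why weak display is the tractable
notion: it converts any binary display instance $(N,T)$ into an equivalent
instance on a binary, compressed, tree-sibling (hence stable) network by
hanging gadget leaves — a new root, a fresh reticulation and two fresh
labels per application — first on a subdivision of every arc entering a
reticulation and then once more beside every original reticulation to give
it a tree sibling. Display status is preserved exactly, so deciding
display remains hard even on stable networks.

## Verification by certificates

Structure-preserving maps are explicit data (`xmorphism`: a vertex map
plus an arc map), never implicit conventions. `verify_x_morphism()`
checks incidence and the leaf condition, `verify_folding_map()` adds
surjectivity and the unique-lifting property, and
`partition_is_fibration()` checks the five conditions under which the
blocks of a vertex partition of a pseudo MUL-tree are the fibres of a
folding map onto a phylogenetic network: the local out-isomorphism
property; degree-two vertices sitting in blocks of size at least two with
a parent in a second block; parent-coherence for all other non-root
vertices; leaf blocks equal to label classes; and no two block-mates
sharing a parent (absence of parallel arcs in the quotient). Conditions
that mention a parent are taken to fail when a block-mate is the root and
has none. The test suite confirms on random partitions — fold-derived,
code-derived and randomly perturbed — that the five-property check is
exactly equivalent to "the quotient validates as a phylogenetic network
and the projection verifies as a folding map".

## Generators and what the tests do (and do not) show

All test inputs come from seeded generators; nothing is downloaded.
`random_binary_tree()` grows trees by uniform arc subdivision (including
an above-root position), giving the familiar $2|X|-1$ vertex count.
`random_network()` adds each reticulation by subdividing a source and a
target arc and connecting them, with acyclicity guaranteed by a
reachability check rather than repair; under the `compressed` constraint
the target arc is never chosen incident to an existing reticulation, which
keeps every reticulation's child a tree vertex by construction, while
`tree_child`, `tree_sibling` and `semi_resolved` are obtained by rejection
sampling. Without the `binary` constraint the generator may also raise the
in-degree of an existing reticulation (probability 0.25 per event) and
contract internal tree arcs into multifurcations (probability 0.25 per
arc); these defaults were chosen once to give the property coverage the
stability tests need — non-compressed, compressed-but-not-tree-sibling and
tree-child networks all occur within a few hundred draws — and are not
tuned otherwise. `random_multree()` duplicates random subtrees of a random
binary tree, so with `dup > 0` repeated labels (and usually inextendible
subtrees) appear.

Default problem sizes follow the scale of the worked objects: label sets
of 3–8, up to five reticulations, MUL-trees with at most a dozen leaves.
Unfolding is exponential in the number of reticulations in the worst
case, so `unfold_star()` materialises the whole path tree but refuses to
grow past an explicit `cap` (default $10^5$ vertices) rather than
truncate silently. These are combinatorial correctness tests on abstract
networks: passing them says nothing about inference from sequence data,
branch lengths, or any statistical question — those are outside the
package's scope, as are unrooted structures and NEXUS-family formats.

## Numerical and degenerate-input choices

* Vertex ids are opaque, stable strings; deterministic tie-breaks (class
  choice, backpointers, serialisation order) use radix string order, which
  is locale-independent.
* A MUL-tree root of out-degree one is accepted by the validator (only
  in-degree-one/out-degree-one vertices are forbidden); the shrinking
  sequence may collapse such a root while folding. A single-label
  MUL-tree such as the cherry `(a,a)` is legal; label sets of size at
  least two are required of networks only.
* `fold()` of a MUL-tree with repeated sibling subtrees yields parallel
  arcs; the result is then an X-network but not a phylogenetic network,
  and for binary inputs `prop1_yields_network()` predicts this without
  folding.
* Extended Newick is read without branch lengths (rejected with a clear
  message); wrapper vertices around a bare hybrid reference are
  suppressed on input. The JSON edge list is the lossless interchange
  format and the only one able to carry pseudo trees and unlabelled
  leaves.

## A worked example

```{r example}
n1 <- fixture_n1()                     # one reticulation, X = {a, b, c}
write_enewick(n1)
u <- unfold(n1)
write_mul_newick(u)                    # the MUL-tree ((a,c),(b,c))
ft <- fold(u)
isTRUE(network_isomorphic(ft$result, n1))
is_stable(n1)
t1 <- read_mul_newick("((a,c),b);")
isTRUE(displays(n1, t1))
reconciliation(n1, t1)$r
```
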