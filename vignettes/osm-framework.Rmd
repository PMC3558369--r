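---
title: "One-step mutation matrices on rooted phylogenies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-step mutation matrices on rooted phylogenies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmkit)
```

## The model

An alignment column (character, site pattern) over `n` taxa and an alphabet
of `r` states is a function from taxa to states. The one-step-mutation (OSM)
framework asks what a *single* substitution somewhere on a rooted binary
phylogenetic tree does to a character, and, from there, how many
substitutions are minimally needed to turn one character into another.

The framework rests on modelling a substitution type as a permutation of the
alphabet, and on requiring the set `Sigma` of admissible types (plus the
identity) to be an Abelian group acting *regularly* on the states:

* **C1** every type is a bijection on the states;
* **C2** for every ordered state pair exactly one element maps the first to
  the second (regularity) -- hence `|Sigma| = r`;
* **C3** closure under composition;
* **C4** commutativity;
* **C5** an identity element, with every other element fixed-point free;
* **C6** inverses;
* **C7** associativity (automatic for permutations).

For DNA there are exactly two such groups: the Klein four-group `Z2 x Z2`
(the substitution matrices of the Kimura 3ST model: transition `s1`,
transversions `s2`, `s3`) and the cyclic group `Z4` generated by a four-cycle
such as `A>G>T>C>A`. Six four-cycles exist on four states, collapsing to
three distinguishable cyclic groups (`enumerate_four_cycle_groups()`);
with the Klein four-group this model-level count includes isomorphic copies,
which we deliberately keep separate (see *Counting constructions* below).

A type `sigma_i` acting on the edge `e` of a rooted tree acts simultaneously
on every taxon descending from `e`. On the character space of `r^n` columns
this is a Kronecker product with `sigma_i` at the descendant positions and
the identity elsewhere (`lift_to_edge()`), and it equals the composition of
the pendant-edge lifts of the descendants -- the algebraic heart of the
method, verified in the test suite on random trees. The set `Sigma_T` of all
`|E(T)| * (r - 1)` lifted operators generates the full group on the
character space; its Cayley graph has the `r^n` characters as vertices and
one edge per generator application.

Weighting each operator by `alpha_{e,i} * p_e` -- the probability that a
single mutation hits edge `e` (relative branch length) and is of type `i` --
and summing gives the OSM matrix

```
M_T = sum_e sum_{i=1}^{r-1} alpha_{e,i} p_e sigma^{e,i},
```

a convex combination of permutation matrices, hence doubly stochastic, with
the uniform distribution as stationary vector of the induced random walk.

## The transformation algorithm

`min_substitutions(tree, group, f, fd)` computes the minimal number of
elements of `Sigma_T` whose composition maps `f` to `fd`:

1. **Position-wise types.** By regularity there is exactly one type per
   position sending `f_j` to `fd_j` (`positionwise_sigma()`).
2. **Push onto a constant.** Apply that operation to the constant character
   `c1...c1` to get `h` (`apply_to_constant()`). Two positions of `h` agree
   exactly when their types agree, so parsimony may act on `h` instead of on
   the tuple of types.
3. **Root-constrained Fitch.** `fitch_rooted(tree, h, c1)` scores `h` with
   the requirement that the root carries `c1`; the score is the answer.

Commutativity makes the choice of `c1` immaterial (tested over all four DNA
states on random instances). The algorithm is linear in `n`, while the two
oracle routes it is validated against -- breadth-first search in the Cayley
graph and the minimal power `k` with `M_T^k[f, fd] > 0` -- are exponential
in `n` and therefore guarded (see *Guards* below).

On the five-taxon tree `((1,2),(3,(4,5)))`, transforming `GTAGA` into
`ACCTC` needs the operation `(s1, s1, s2, s2, s2)` under the Klein
four-group, giving `h = GGCCC` and two substitutions, but
`(s'3, s'1, s'3, s'1, s'3)` and `h = CGCGC` under the cyclic group, giving
three: the minimal count depends on the group, not only on the characters.

```{r example}
tr <- read_osm_tree("((1,2),(3,(4,5)));")
min_substitutions(tr, osm_group_preset("K3ST"), "GTAGA", "ACCTC")
min_substitutions(tr, osm_group_preset("Z4"), "GTAGA", "ACCTC")
```

### The root-constraint correction

The Fitch pass runs bottom-up over the subtree below the degree-1 root and
adds 1 exactly when the requested root state is missing from the final
state set, instead of modifying the recursion. This is exact, not an
approximation: the stem edge belongs to the tree, so the constrained
optimum is `min(cost(root_state), m + 1)`, and the first-pass state set at
the top vertex is precisely the set of states attaining the minimum `m`.
The returned extension is one arbitrary most-parsimonious witness with ties
broken by alphabet order; only the score is contractual.

## Trees, orderings and conventions

* **Degree-1 root.** Rooted binary X-trees here have a root of outdegree 1,
  so the stem edge can carry substitutions. Because common newick writers
  emit bifurcating roots, `read_osm_tree()` by default prepends a stem edge
  (`stem_policy = "add_stem"`, stem length 0, which contributes `p_e = 0`
  unless uniform weighting is chosen); a newick whose root already has a
  single child, like `((1,2));`, is used as is.
* **Taxon order** is the left-to-right leaf order of the newick string; it
  is recorded in `tree$taxa` and used to index the character space with
  taxon 1 most significant, matching the Kronecker convention (left factor
  most significant) used for products of groups and for edge lifts.
* **Edge names** are derived from the child vertex: pendant edges `e_1`,
  internal and stem edges by the sorted descendant set (`e_12`, `e_345`).
* **Alphabet order** is explicit and user-visible; the DNA preset is
  `A, C, G, T` and all printed matrices are asserted under this ordering.
  `Z4` labels its elements `s'1..s'3` from the generator `A>G>T>C>A`; the
  `K2ST` preset provides the alternative generator `A>C>G>T>A` used
  elsewhere in the literature (its `s'2` is then the transition).

## Tunable parameters

| Parameter | Meaning | Default |
|---|---|---|
| `p_e` | probability a single mutation hits edge `e` | branch length / tree length, or uniform |
| `alpha_{e,i}` | probability the mutation on `e` has type `i` | uniform `1/(r-1)` |
| `stem_length` | length given to an added stem edge | 0 |
| `guard` | cap on `r^n` for dense/exhaustive operations | `options(osmkit.guard = 65536)` |
| `tol` | double-stochasticity tolerance in model audits | `1e-9` |

No estimation of `alpha_{e,i}` from data is attempted; the defaults are the
uniform study conditions and are user-overridable. A subtlety worth knowing:
under *uniform* type weights the OSM matrix is symmetric even for the
cyclic group, because each generator and its inverse receive equal weight;
genuine asymmetry appears as soon as a four-cycle outweighs its inverse.
For the Klein four-group every element is an involution, so the matrix is
symmetric for any weighting.

## Guards and numerical choices

Everything that enumerates the character space -- dense operator matrices,
the OSM matrix, Cayley BFS, the igraph oracle -- is capped by a single
guard on `r^n` (default 65536) and errors with advice rather than
materializing. The Fitch path has no cap: it is the scalable route.

`min_power_positive()` refuses weight sets containing zeros: a zero-weight
operator is still a generator for reachability but contributes nothing to
the matrix support, so the two notions would silently disagree.

Birkhoff extraction (`birkhoff_decompose()`) repeatedly removes a
permutation lying in the positive support, chosen to maximize the minimum
covered entry (bottleneck matching via binary search over support
thresholds, bipartite perfect matching from igraph), and subtracts its
minimal covered entry. This terminates within `(r-1)^2 + 1` terms; the
decomposition is not unique and only the reconstruction is contractual.
When the input is an exact convex combination of a regular group's elements
with distinct weights, the supports of distinct elements are disjoint, and
the extraction provably returns exactly those elements -- which is why
`audit_model()` can meaningfully run the condition checks on the extracted
set. Stochasticity checks use a configurable tolerance (`1e-9`) because
model matrices typically come from floating-point estimation.

## Counting constructions

`enumerate_constructions(r)` lists unordered factorizations of `r` into
factors of at least 2, each naming a direct product of cyclic groups: two
constructions for `r = 4` and four for `r = 20` (`Z20`, `Z2 x Z10`,
`Z4 x Z5`, `Z2 x Z2 x Z5`). As abstract groups these collapse further
(`Z20` is isomorphic to `Z4 x Z5`, and `Z2 x Z10` to `Z2 x Z2 x Z5`), but
the constructions act differently on a fixed, ordered alphabet and are the
natural unit for model building, so `reduce_isomorphism_classes()` is
provided for reporting and never applied implicitly. The coset partition of
a subgroup (`coset_partition()`) bins the alphabet into blocks of subgroup
size -- for amino acids, e.g., four blocks of five under the `Z5` subgroup
of `Z2 x Z2 x Z5`; no such algebraic binning matches biochemical binnings
like the hydrophobicity classes, which limits the biological meaning of the
20-state groups.

## Synthetic instances and what the tests show

`make_fixture()` produces the two study instances (the two-taxon tree with
stem edge `e_12`; the five-taxon tree `((1,2),(3,(4,5)))` with the pair
`GTAGA -> ACCTC`) and random instances: rooted binary trees by sequential
leaf attachment, uniform random character pairs, and uniform or seeded
exponential edge weights. The five-taxon topology is fixed here once --
published figures of this instance constrain but do not fully pin the
shape; both caterpillar resolutions give the same printed scores, and this
package standardizes on `((1,2),(3,(4,5)))`.

The equivalence suite (`run_equivalence_suite()`) checks the three routes
to the minimal count against one another -- Fitch-based algorithm, Cayley
distance (igraph), first positive matrix power -- exhaustively on all
character pairs at `n = 2` (256 pairs) and `n = 3` (4096 pairs) for both
DNA groups, and on sampled pairs at `n = 4..5`; these sizes keep the full
test run around half a minute while already covering every tree shape
quirk (cherries, caterpillars, the stem) that the algebra must respect.
Random fixtures are uniform over characters and contain no rate
heterogeneity, gaps, or alignment error, so passing tests certify the
combinatorics and the algebra, not the fit of any model to real sequence
data.

## Limitations

* Only Abelian groups with regular actions are supported as OSM groups;
  non-Abelian sets (such as the symmetric-GTR permutation set) are
  diagnosed, not used.
* Posterior distributions of substitution counts, Hadamard/spectral
  machinery, Lie-algebraic model closure and goodness-of-fit pipelines
  built on top of the minimal count are out of scope.
* Trees must be binary with unique leaf labels; multifurcations and
  unrooted trees are rejected rather than resolved.
* Exhaustive oracles and dense exports are limited by the `r^n` guard; the
  Fitch route is the only one intended for large `n`.
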