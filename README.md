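# osmkit

Group-theoretic tools for **one-step mutation (OSM) matrices** on rooted
phylogenies: for molecular evolution researchers who want to count, place
and audit single substitutions on a tree at the level of whole alignment
columns.

An alignment column over `n` taxa and an `r`-state alphabet is a character
`f : X -> C`. A substitution type is a permutation of `C`; the admissible
types together with the identity must form an Abelian group `Σ` acting
regularly on the states (conditions C1–C6: bijectivity, regularity,
closure, commutativity, identity + fixed-point freeness, inverses). For
DNA these are the Klein four-group `Z2 × Z2` (the K3ST substitution
matrices `s0..s3`) and the cyclic group `Z4` of a four-cycle such as
`A→G→T→C→A`. A type `σ_i` on an edge `e` of a rooted binary tree `T`
(degree-1 root, so the stem edge is a real edge) lifts to the character
space as the Kronecker product acting on all descendants of `e`. The
weighted convex sum over edges and types,

    M_T = Σ_e Σ_{i=1}^{r-1} α_{e,i} · p_e · σ^{e,i},

is the OSM matrix: sparse, doubly stochastic, with a uniform stationary
distribution — the transition kernel of "one substitution somewhere on
`T`".

The package provides:

* **Groups** — construction (cyclic, direct products via Kronecker
  products, presets `K3ST`/`Z4`/`K2ST`, a spec mini-language), condition
  audits with witnesses, regular-action transformers, enumeration of
  four-cycles and of product constructions up to 20 states, coset
  partitions of the alphabet.
* **Trees** — newick in/out with explicit degree-1 root handling,
  child-named edges (`e_1`, `e_12`), normalized edge/type weights.
* **OSM operators** — lazy edge lifts, `Σ_T`, the sparse OSM matrix,
  Cayley-graph shortest paths, matrix-power and stationarity utilities,
  MatrixMarket/TSV export.
* **The transformation algorithm** — the minimal number of tree-governed
  substitutions converting one character into another, computed in linear
  time by a root-constrained Fitch pass, plus an exhaustive Cayley-graph
  oracle for verification.
* **Model audits** — Birkhoff–von Neumann decomposition of doubly
  stochastic transition matrices and condition reports for the extracted
  permutation sets (e.g. the symmetric-GTR set decomposes but fails
  C3/C4/C5; unequal-frequency models do not decompose at all).

## Worked example

Transform `GTAGA` into `ACCTC` on the five-taxon tree `((1,2),(3,(4,5)))`:

```r
library(osmkit)
tr <- read_osm_tree("((1,2),(3,(4,5)));")
g  <- osm_group_preset("K3ST")
res <- min_substitutions(tr, g, "GTAGA", "ACCTC", details = TRUE)
res$operation
#> <osm_positionwise> (s1, s1, s2, s2, s2) on K3ST
paste(res$h, collapse = "")
#> [1] "GGCCC"
res$m
#> [1] 2
```

Position by position, a transition `s1` fixes taxa 1–2 and a transversion
`s2` fixes taxa 3–5; applied to the constant column `AAAAA` this operation
gives `h = GGCCC`, and Fitch with root state `A` pulls the shared types up
onto two internal edges: **two** substitutions suffice (one `s1` above the
cherry `(1,2)`, one `s2` above `(3,(4,5))`). Under the cyclic group
instead, `min_substitutions(tr, osm_group_preset("Z4"), "GTAGA", "ACCTC")`
returns `3` — the minimal count depends on the group.

Auditing the symmetric-GTR permutation set:

```r
check_conditions(sgtr_permutation_set())
#> <osm_conditions> 7 permutations on [ACGT]
#>   C1 (bijective):                 pass
#>   C2 (regular action):            FAIL
#>        witnesses: A->A covered 4x, C->C covered 4x, G->G covered 4x, T->T covered 4x
#>   C3 (closed):                    FAIL
#>        witnesses: sa*sb, sa*sc, sa*sd, sa*se, sa*sf, ...
#>   C4 (commutative):               FAIL
#>        witnesses: sa*sb, sa*sc, sa*sd, sa*se, sb*sc, ...
#>   C5 (identity & fixed-point free): FAIL
#>        witnesses: sa fixes GT; sb fixes CT; sc fixes CG; ...
#>   C6 (inverses):                  pass
#>   C7 (associative):               pass
#>   => NOT an admissible OSM group
```

A thin command-line dispatcher ships at `inst/cli/osmkit.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","osmkit.R",package="osmkit"))')" \
  mindist --newick "((1,2),(3,(4,5)));" --group K3ST \
  --from GTAGA --to ACCTC --oracle
```

See the methods vignette (`vignettes/osm-framework.Rmd`) for the model,
conventions, parameter defaults and design decisions.

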