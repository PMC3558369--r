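# Shared fixtures, built in code.

k3st <- osm_group_preset("K3ST")
z4 <- osm_group_preset("Z4")
DNA <- dna_alphabet()

fig1_tree <- function() read_osm_tree("((1,2));")
fig2_tree <- function() read_osm_tree("((1,2),(3,(4,5)));")

# random permutation over r states
random_perm <- function(r, letters = default_alphabet(r), label = "p") {
  perm(sample(r), letters, label)
}

# random rooted binary tree with the given number of taxa and runif lengths
random_tree <- function(n) {
  as_osm_tree(ape::rtree(n, tip.label = as.character(seq_len(n))))
}

# random doubly stochastic matrix: convex combination of random permutations
random_doubly_stochastic <- function(r, k = r + 2L) {
  w <- rexp(k); w <- w / sum(w)
  Reduce(`+`, lapply(seq_len(k), function(i) {
    w[i] * as.matrix(random_perm(r))
  }))
}

expect_same_perm <- function(a, b) {
  expect_identical(a$map, b$map)
  expect_identical(a$letters, b$letters)
}
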