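#' Reproducible synthetic instances
#'
#' Builds a (tree, weights, character pair, group) instance, either from a
#' named preset or at random. Presets: `"fig1"`, the rooted two-taxon tree
#' with stem edge e_12; `"fig2"`, the five-taxon tree ((1,2),(3,(4,5)))
#' with the character pair GTAGA -> ACCTC. Random instances draw a rooted
#' binary tree by sequential leaf attachment (via [ape::rtree()]), edge
#' weights either uniform or proportional to seeded exponential draws, and
#' a uniform random character pair. Identical seed and spec give identical
#' fixtures.
#'
#' @param preset `"fig1"`, `"fig2"`, or `NULL` for a random instance.
#' @param n number of taxa for random instances.
#' @param group group specification string (see [parse_group_spec()]) or
#'   an `osm_group`.
#' @param seed RNG seed for random instances (calls [set.seed()]).
#' @param weight_scheme `"uniform"` or `"exponential"`.
#' @return A list with `tree`, `weights`, `f`, `fd`, `group`.
#' @examples
#' fx <- make_fixture("fig2")
#' min_substitutions(fx$tree, fx$group, fx$f, fx$fd)
#' @export
make_fixture <- function(preset = NULL, n = 5L, group = "K3ST",
                         seed = NULL,
                         weight_scheme = c("uniform", "exponential")) {
  weight_scheme <- match.arg(weight_scheme)
  g <- if (inherits(group, "osm_group")) group else parse_group_spec(group)
  r <- group_size(g)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("fig1", "fig2"))
    if (preset == "fig1") {
      tree <- read_osm_tree("((1,2));")
      f <- stats::setNames(rep(g$letters[1L], 2L), tree$taxa)
      fd <- stats::setNames(sample(g$letters, 2L, replace = TRUE),
                            tree$taxa)
    } else {
      tree <- read_osm_tree("((1,2),(3,(4,5)));")
      f <- as_char_vec("GTAGA", tree$taxa, dna_alphabet())
      fd <- as_char_vec("ACCTC", tree$taxa, dna_alphabet())
      if (!identical(g$letters, dna_alphabet())) {
        stop("preset \"fig2\" is a DNA instance")
      }
    }
  } else {
    n <- as.integer(n)
    ph <- ape::rtree(n, rooted = TRUE, tip.label = as.character(seq_len(n)),
                     br = NULL)
    tree <- as_osm_tree(ph)
    f <- stats::setNames(sample(g$letters, n, replace = TRUE), tree$taxa)
    fd <- stats::setNames(sample(g$letters, n, replace = TRUE), tree$taxa)
  }
  ne <- nrow(tree$edges)
  weights <- if (weight_scheme == "uniform") {
    normalize_weights(tree, uniform = TRUE, n_types = r - 1L)
  } else {
    normalize_weights(tree, lengths = rexp(ne), n_types = r - 1L)
  }
  list(tree = tree, weights = weights, f = f, fd = fd, group = g)
}

#' Cross-validate the three equivalent substitution counts
#'
#' Operationalizes the equivalence at the heart of the framework: for
#' character pairs on a tree, the Fitch-based count
#' ([min_substitutions()]), the Cayley-graph distance (igraph shortest
#' path over the generator set) and the minimal power of the OSM matrix
#' with a positive entry must agree. With `pairs = "all"` every ordered
#' pair of the r^n characters is checked (distances and first-positive
#' powers are then computed for the whole character space at once);
#' otherwise `pairs` seeded random pairs are drawn.
#'
#' @param tree an `osm_tree`.
#' @param g an `osm_group` (or spec string).
#' @param pairs `"all"` or a number of random pairs.
#' @param seed seed for sampled pairs.
#' @param weights an `osm_weights`; default uniform with uniform types
#'   (strictly positive, as the matrix route requires).
#' @param methods subset of `c("fitch", "cayley", "power")` to run
#'   (default all three).
#' @param guard cap on r^n.
#' @return A list: `n_pairs`, `disagreements` (data frame, one row per
#'   disagreeing pair; empty when all agree), `agree` (logical), and the
#'   per-method score vectors.
#' @examples
#' fx <- make_fixture("fig1")
#' run_equivalence_suite(fx$tree, fx$group, pairs = 20, seed = 1)$agree
#' @export
run_equivalence_suite <- function(tree, g, pairs = "all", seed = NULL,
                                  weights = NULL,
                                  methods = c("fitch", "cayley", "power"),
                                  guard = NULL) {
  stopifnot(inherits(tree, "osm_tree"))
  if (!inherits(g, "osm_group")) g <- parse_group_spec(g)
  methods <- match.arg(methods, several.ok = TRUE)
  r <- group_size(g); n <- tree$n
  N <- r^n
  check_guard(N, guard, "the equivalence suite")
  weights <- weights %||% normalize_weights(tree, uniform = TRUE,
                                            n_types = r - 1L)
  chars <- t(vapply(seq_len(N), function(i) index_char(i, n, g$letters),
                    character(n)))

  if (identical(pairs, "all")) {
    pair_idx <- cbind(rep(seq_len(N), each = N), rep(seq_len(N), times = N))
  } else {
    if (!is.null(seed)) set.seed(seed)
    pair_idx <- cbind(sample(N, pairs, replace = TRUE),
                      sample(N, pairs, replace = TRUE))
  }

  scores <- list()
  if ("fitch" %in% methods) {
    scores$fitch <- vapply(seq_len(nrow(pair_idx)), function(k) {
      min_substitutions(tree, g,
                        stats::setNames(chars[pair_idx[k, 1L], ], tree$taxa),
                        stats::setNames(chars[pair_idx[k, 2L], ], tree$taxa))
    }, 1L)
  }
  if ("cayley" %in% methods) {
    D <- igraph::distances(cayley_igraph(tree, g, guard), mode = "out")
    scores$cayley <- as.integer(D[pair_idx])
  }
  if ("power" %in% methods) {
    m <- build_osm(tree, g, weights, guard)
    K <- first_positive_power(as.matrix(m$matrix), max_k = 2L * n + 2L)
    scores$power <- K[pair_idx]
  }

  tab <- as.data.frame(scores)
  disagree <- if (ncol(tab) > 1L) {
    which(apply(tab, 1L, function(z) length(unique(z)) > 1L))
  } else integer(0L)
  dis <- if (length(disagree)) {
    data.frame(
      f = apply(chars[pair_idx[disagree, 1L], , drop = FALSE], 1L, paste,
                collapse = ""),
      fd = apply(chars[pair_idx[disagree, 2L], , drop = FALSE], 1L, paste,
                 collapse = ""),
      tab[disagree, , drop = FALSE])
  } else {
    cbind(data.frame(f = character(), fd = character()),
          tab[integer(0L), , drop = FALSE])
  }
  c(list(n_pairs = nrow(pair_idx), disagreements = dis,
         agree = length(disagree) == 0L), scores)
}

# first k (0..max_k) with (M^k)[i, j] > 0, for all entries at once
first_positive_power <- function(M, max_k) {
  N <- nrow(M)
  K <- matrix(NA_integer_, N, N)
  diag(K) <- 0L
  cur <- diag(N)
  for (k in seq_len(max_k)) {
    cur <- cur %*% M
    hit <- is.na(K) & cur > 0
    K[hit] <- k
    if (!anyNA(K)) break
  }
  if (anyNA(K)) stop("entries still zero after power ", max_k)
  K
}
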