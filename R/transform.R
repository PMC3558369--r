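#' Position-wise transformer between two characters
#'
#' By regularity there is exactly one group element per position sending
#' `f_j` to `fd_j`; the resulting tuple (sigma_1, ..., sigma_n) applied
#' position-wise maps `f` to `fd`.
#'
#' @param g an `osm_group` acting regularly.
#' @param f,fd characters (string, vector, or named vector; see
#'   [osm_character]).
#' @param taxa taxon labels (default `1..n` or the names of `f`).
#' @return An object of class `osm_positionwise`: list with `labels`,
#'   `elements` (list of `osm_perm`), `taxa`, `group`.
#' @examples
#' positionwise_sigma(osm_group_preset("K3ST"), "GTAGA", "ACCTC")
#' @export
positionwise_sigma <- function(g, f, fd, taxa = NULL) {
  stopifnot(inherits(g, "osm_group"))
  taxa <- taxa %||% names(f) %||%
    as.character(seq_len(if (length(f) == 1L) nchar(f[[1L]]) else length(f)))
  f <- as_char_vec(f, taxa, g$letters)
  fd <- as_char_vec(fd, taxa, g$letters)
  els <- lapply(seq_along(taxa), function(j) transformer(g, f[j], fd[j]))
  structure(list(labels = vapply(els, `[[`, "", "label"), elements = els,
                 taxa = taxa, group = g),
            class = "osm_positionwise")
}

#' @export
print.osm_positionwise <- function(x, ...) {
  cat("<osm_positionwise> (", paste(x$labels, collapse = ", "), ") on ",
      x$group$name, "\n", sep = "")
  invisible(x)
}

#' Apply a position-wise operation to a constant character
#'
#' `h_j = sigma_j(c1)`: the image of the constant character `c1...c1`.
#' Since two states of `h` agree exactly when the corresponding operations
#' agree, parsimony can act on `h` instead of on the operation itself.
#'
#' @param op an `osm_positionwise` operation.
#' @param c1 the constant state (default: first alphabet letter).
#' @return A named character vector (taxon -> state).
#' @examples
#' op <- positionwise_sigma(osm_group_preset("K3ST"), "GTAGA", "ACCTC")
#' apply_to_constant(op, "A")  # GGCCC
#' @export
apply_to_constant <- function(op, c1 = NULL) {
  stopifnot(inherits(op, "osm_positionwise"))
  letters <- op$group$letters
  c1 <- c1 %||% letters[1L]
  letter_index(c1, letters)
  stats::setNames(vapply(op$elements, perm_apply, "", x = c1), op$taxa)
}

#' Fitch small parsimony with a fixed root state
#'
#' Bottom-up Fitch (intersection if nonempty, else union and one more
#' change) over the subtree below the degree-1 root, followed by a +1
#' correction when the required root state is not in the final state set.
#' Because the stem edge belongs to the tree and can carry a substitution,
#' this equals the minimum number of state-changing edges over all
#' extensions `g` with `g(root) = root_state`.
#'
#' @param tree an `osm_tree`.
#' @param h character at the leaves.
#' @param root_state required state at the root.
#' @param letters the alphabet (default DNA, or the unique states of `h`).
#' @return An object of class `osm_fitch`: `score`, per-vertex state
#'   `sets`, and one most-parsimonious `extension` (ties broken by
#'   alphabet order).
#' @examples
#' tr <- read_osm_tree("((1,2),(3,(4,5)));")
#' fitch_rooted(tr, "GGCCC", "A")$score  # 2
#' @export
fitch_rooted <- function(tree, h, root_state, letters = NULL) {
  stopifnot(inherits(tree, "osm_tree"))
  if (is.null(letters)) {
    letters <- if (all(unique(c(unlist(strsplit(paste(h, collapse = ""),
                                                "")), root_state))
                       %in% dna_alphabet())) dna_alphabet() else
      alphabet(sort(unique(c(h, root_state))))
  }
  letters <- alphabet(letters)
  h <- as_char_vec(h, tree$taxa, letters)
  letter_index(root_state, letters)

  nn <- max(tree$edges$parent, tree$edges$child)
  sets <- vector("list", nn)
  score <- 0L
  for (v in tree$postorder) {
    kids <- tree$children[[v]]
    if (length(kids) == 0L) {
      sets[[v]] <- h[[tree$taxa[v]]]
    } else if (v != tree$root) {
      s1 <- sets[[kids[1L]]]; s2 <- sets[[kids[2L]]]
      inter <- intersect(s1, s2)
      if (length(inter)) sets[[v]] <- inter else {
        sets[[v]] <- union(s1, s2)
        score <- score + 1L
      }
    }
  }
  top_set <- sets[[tree$top]]
  if (!(root_state %in% top_set)) score <- score + 1L
  sets[[tree$root]] <- root_state

  # one most-parsimonious refinement, ties broken by alphabet order
  by_alpha <- function(s) s[order(letter_index(s, letters))][1L]
  ext <- character(nn)
  ext[tree$root] <- root_state
  ext[tree$top] <- if (root_state %in% top_set) root_state else
    by_alpha(top_set)
  downorder <- rev(tree$postorder)
  for (v in downorder) {
    for (k in tree$children[[v]]) {
      if (v == tree$root) next
      ext[k] <- if (ext[v] %in% sets[[k]]) ext[v] else by_alpha(sets[[k]])
    }
  }
  changes <- sum(ext[tree$edges$parent] != ext[tree$edges$child])
  structure(list(score = score, sets = sets, extension = ext,
                 changes = changes, root_state = root_state,
                 letters = letters),
            class = "osm_fitch")
}

#' @export
print.osm_fitch <- function(x, ...) {
  cat("<osm_fitch> score ", x$score, " with root state ", x$root_state,
      "\n", sep = "")
  invisible(x)
}

#' Minimal number of substitutions transforming one character into another
#'
#' The core transformation computation: find the position-wise operation
#' sigma with sigma(f) = fd, push it onto the constant character
#' h = sigma(c1...c1), and score h by root-constrained Fitch with root
#' state c1. The result is the minimal number of tree-governed operations
#' (elements of Sigma_T: one substitution type applied on one edge) whose
#' composition maps f to fd. The choice of c1 is immaterial by
#' commutativity. Linear in the number of taxa.
#'
#' @inheritParams positionwise_sigma
#' @param tree an `osm_tree` on the same taxa.
#' @param c1 constant state used internally (default: first alphabet
#'   letter).
#' @param details if `TRUE` return a list with the operation, `h` and the
#'   Fitch result instead of a bare count.
#' @return Integer count (or a detail list).
#' @examples
#' tr <- read_osm_tree("((1,2),(3,(4,5)));")
#' min_substitutions(tr, osm_group_preset("K3ST"), "GTAGA", "ACCTC")  # 2
#' min_substitutions(tr, osm_group_preset("Z4"), "GTAGA", "ACCTC")    # 3
#' @export
min_substitutions <- function(tree, g, f, fd, c1 = NULL, details = FALSE) {
  stopifnot(inherits(tree, "osm_tree"), inherits(g, "osm_group"))
  op <- positionwise_sigma(g, f, fd, taxa = tree$taxa)
  c1 <- c1 %||% g$letters[1L]
  h <- apply_to_constant(op, c1)
  fit <- fitch_rooted(tree, h, root_state = c1, letters = g$letters)
  if (!details) return(fit$score)
  list(m = fit$score, operation = op, h = h, fitch = fit, c1 = c1)
}

#' Brute-force oracle for the minimal substitution count
#'
#' Independent verification of the Fitch-based computation: builds the full
#' Cayley graph of the tree-governed generator set Sigma_T on all r^n
#' characters (as an \pkg{igraph} graph) and returns the graph distance
#' between `f` and `fd`. Exponential in n; guarded.
#'
#' @inheritParams min_substitutions
#' @param depth_cap error if the distance exceeds this cap.
#' @param guard cap on r^n (default `getOption("osmkit.guard", 65536)`).
#' @return Integer minimal composition length.
#' @export
exhaustive_oracle <- function(tree, g, f, fd, depth_cap = Inf,
                              guard = NULL) {
  stopifnot(inherits(tree, "osm_tree"), inherits(g, "osm_group"))
  r <- length(g$letters); n <- tree$n
  N <- r^n
  check_guard(N, guard, "the exhaustive oracle")
  gr <- cayley_igraph(tree, g)
  fi <- char_index(as_char_vec(f, tree$taxa, g$letters), g$letters)
  di <- char_index(as_char_vec(fd, tree$taxa, g$letters), g$letters)
  d <- igraph::distances(gr, v = fi, to = di, mode = "out")[1L, 1L]
  if (!is.finite(d)) stop("target character unreachable")  # cannot happen
  if (d > depth_cap) stop("minimal composition length ", d,
                          " exceeds depth_cap ", depth_cap)
  as.integer(d)
}

# full Cayley graph of Sigma_T on the r^n characters, as an igraph object
cayley_igraph <- function(tree, g, guard = NULL) {
  ops <- build_sigma_T(tree, g, guard = guard)
  r <- length(g$letters); N <- r^tree$n
  check_guard(N, guard, "Cayley graph construction")
  from <- rep(seq_len(N), times = length(ops))
  to <- unlist(lapply(ops, op_index_map), use.names = FALSE)
  igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
}
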