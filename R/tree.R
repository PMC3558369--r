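#' Rooted binary phylogenetic trees with a degree-1 root
#'
#' The OSM framework works on rooted binary X-trees whose root has indegree
#' 0 and outdegree 1, so that the stem edge above the ingroup can itself
#' carry substitutions. Newick text is parsed with \pkg{ape}; because most
#' newick writers emit a bifurcating root, the default `stem_policy
#' = "add_stem"` prepends a stem edge and a degree-1 root when the newick
#' root has two children (a newick root that already has a single child is
#' used as the root directly, as in `"((1,2));"`).
#'
#' Edges are identified by their child vertex: pendant edges by the taxon
#' label (`e_1`), internal and stem edges by the sorted set of descendant
#' taxa (`e_12`, `e_345`). The taxon order used to index characters is the
#' left-to-right leaf order of the newick string.
#'
#' @param text newick string (alternative to `file`).
#' @param file path to a newick file.
#' @param stem_policy `"add_stem"` (default) or `"as_is"` (error if the
#'   newick root is not degree 1).
#' @param stem_length branch length given to an added stem edge (default 0).
#' @return An object of class `osm_tree` with fields `taxa`, `edges` (a
#'   data frame with `parent`, `child`, `name`, `length`), `root`, `top`
#'   (the root's single child), `desc` (edge name -> descendant taxa) and
#'   traversal indices.
#' @examples
#' tr <- read_osm_tree("((1,2),(3,(4,5)));")
#' tr$edges$name
#' @export
read_osm_tree <- function(text = NULL, file = NULL,
                          stem_policy = c("add_stem", "as_is"),
                          stem_length = 0) {
  stem_policy <- match.arg(stem_policy)
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`")
  }
  ph <- if (!is.null(text)) ape::read.tree(text = text) else
    ape::read.tree(file)
  if (is.null(ph)) stop("could not parse newick input")
  as_osm_tree(ph, stem_policy = stem_policy, stem_length = stem_length)
}

#' Convert an ape "phylo" tree
#' @param ph an [ape::read.tree()]-style `phylo` object.
#' @inheritParams read_osm_tree
#' @return An `osm_tree`.
#' @export
as_osm_tree <- function(ph, stem_policy = c("add_stem", "as_is"),
                        stem_length = 0) {
  stem_policy <- match.arg(stem_policy)
  stopifnot(inherits(ph, "phylo"))
  ntip <- length(ph$tip.label)
  if (anyDuplicated(ph$tip.label)) {
    stop("duplicate leaf names: ",
         paste(unique(ph$tip.label[duplicated(ph$tip.label)]), collapse = ", "))
  }
  edge <- ph$edge
  len <- ph$edge.length %||% rep(NA_real_, nrow(edge))
  nnode <- max(edge)
  root <- setdiff(unique(edge[, 1L]), edge[, 2L])
  outdeg <- tabulate(edge[, 1L], nbins = nnode)
  internal <- setdiff(unique(edge[, 1L]), root)
  if (any(outdeg[internal] != 2L)) {
    stop("tree is not binary: internal vertex with outdegree ",
         paste(unique(outdeg[internal][outdeg[internal] != 2L]),
               collapse = ","))
  }
  if (outdeg[root] == 2L) {
    if (stem_policy == "as_is") {
      stop("newick root has two children; use stem_policy = \"add_stem\"")
    }
    new_root <- nnode + 1L
    edge <- rbind(c(new_root, root), edge)
    len <- c(stem_length, len)
    root <- new_root
    nnode <- new_root
  } else if (outdeg[root] != 1L) {
    stop("root must have outdegree 1 or 2, found ", outdeg[root])
  }
  parent <- edge[, 1L]; child <- edge[, 2L]
  children <- split(child, factor(parent, levels = seq_len(nnode)))

  # postorder over vertices (children before parents), iterative
  post <- integer(0L); stack <- root; emit <- integer(0L)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    emit <- c(emit, v)
    kids <- children[[v]]
    if (length(kids)) stack <- c(stack, kids)
  }
  post <- rev(emit)

  taxa <- ph$tip.label
  desc_v <- vector("list", nnode)
  for (v in post) {
    kids <- children[[v]]
    desc_v[[v]] <- if (length(kids) == 0L) taxa[v] else
      unlist(desc_v[kids], use.names = FALSE)
  }
  edge_name <- vapply(child, function(v) {
    labs <- sort(desc_v[[v]])
    sep <- if (all(nchar(labs) == 1L)) "" else ","
    paste0("e_", paste(labs, collapse = sep))
  }, "")
  edges <- data.frame(parent = parent, child = child, name = edge_name,
                      length = len, stringsAsFactors = FALSE)
  desc <- stats::setNames(lapply(child, function(v) desc_v[[v]]), edge_name)
  structure(list(
    taxa = taxa, n = ntip, edges = edges, root = root,
    top = children[[root]][1L], children = children, postorder = post,
    desc = desc
  ), class = "osm_tree")
}

#' @export
print.osm_tree <- function(x, ...) {
  cat("<osm_tree> ", x$n, " taxa (", paste(x$taxa, collapse = ", "),
      "), ", nrow(x$edges), " edges, degree-1 root\n", sep = "")
  cat("  newick:", write_osm_newick(x), "\n")
  invisible(x)
}

#' Write a tree as newick
#'
#' The degree-1 root is written as an extra pair of parentheses around the
#' subtree below the stem, so `read_osm_tree(write_osm_newick(t))` round
#' trips the topology.
#'
#' @param tree an `osm_tree`.
#' @param file optional path; when `NULL` the newick string is returned.
#' @return The newick string (invisibly when writing to a file).
#' @export
write_osm_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "osm_tree"))
  has_len <- !all(is.na(tree$edges$length))
  len_of <- stats::setNames(tree$edges$length, tree$edges$child)
  leaf <- function(v) length(tree$children[[v]]) == 0L
  emit <- function(v) {
    lab <- if (leaf(v)) tree$taxa[v] else {
      paste0("(", paste(vapply(tree$children[[v]], emit, ""),
                        collapse = ","), ")")
    }
    l <- len_of[[as.character(v)]]
    if (has_len && !is.null(l) && !is.na(l)) paste0(lab, ":", format(l)) else
      lab
  }
  nwk <- paste0("(", emit(tree$top), ");")
  if (is.null(file)) return(nwk)
  writeLines(nwk, file)
  invisible(nwk)
}

#' Descendant taxa of an edge
#'
#' All taxa whose path to the root passes the edge. The stem edge has every
#' taxon as descendant; a pendant edge only its own.
#'
#' @param tree an `osm_tree`.
#' @param edge edge name (e.g. `"e_12"`).
#' @return Character vector of taxon labels.
#' @examples
#' descendants(read_osm_tree("((1,2));"), "e_12")
#' @export
descendants <- function(tree, edge) {
  stopifnot(inherits(tree, "osm_tree"))
  d <- tree$desc[[edge]]
  if (is.null(d)) {
    stop("unknown edge '", edge, "'; edges are: ",
         paste(tree$edges$name, collapse = ", "))
  }
  d
}

#' Normalized edge and substitution-type weights
#'
#' Computes the relative branch lengths p_e (branch length divided by the
#' total tree length, so that they sum to 1 and can be read as the
#' probability that a single mutation on the tree hits edge e) and the
#' per-edge substitution-type probabilities alpha_{e,i} over the r-1
#' non-identity types (each row sums to 1; default uniform 1/(r-1)).
#'
#' @param tree an `osm_tree`.
#' @param lengths edge lengths, named by edge name or in edge-table order;
#'   default: the tree's own branch lengths.
#' @param uniform if `TRUE`, ignore lengths and give every edge equal
#'   weight.
#' @param n_types number of non-identity substitution types (r - 1).
#' @param type_labels optional labels for the types (columns of `alpha`).
#' @param alpha optional matrix of type probabilities (edges x types), rows
#'   summing to 1.
#' @return An object of class `osm_weights`: list with `p` (named vector)
#'   and `alpha` (matrix with edge rownames).
#' @examples
#' tr <- read_osm_tree("((1,2));")
#' normalize_weights(tr, uniform = TRUE, n_types = 3)$p
#' @export
normalize_weights <- function(tree, lengths = NULL, uniform = FALSE,
                              n_types = 3L, type_labels = NULL,
                              alpha = NULL) {
  stopifnot(inherits(tree, "osm_tree"))
  nm <- tree$edges$name
  ne <- length(nm)
  if (uniform) {
    p <- rep(1 / ne, ne)
  } else {
    lengths <- lengths %||% tree$edges$length
    if (all(is.na(lengths))) {
      stop("tree has no branch lengths; supply `lengths` or uniform = TRUE")
    }
    if (!is.null(names(lengths))) {
      lengths <- lengths[nm]
      if (anyNA(names(lengths))) stop("lengths named by unknown edges")
    }
    if (length(lengths) != ne) stop("need one length per edge (", ne, ")")
    lengths[is.na(lengths)] <- 0
    if (any(lengths < 0)) stop("negative branch length")
    if (sum(lengths) <= 0) {
      stop("all branch lengths are zero; use uniform = TRUE")
    }
    p <- lengths / sum(lengths)
  }
  names(p) <- nm
  n_types <- as.integer(n_types)
  if (is.null(alpha)) {
    alpha <- matrix(1 / n_types, ne, n_types)
  } else {
    alpha <- as.matrix(alpha)
    if (nrow(alpha) != ne || ncol(alpha) != n_types) {
      stop("alpha must be ", ne, " x ", n_types)
    }
    if (any(alpha < 0) || any(abs(rowSums(alpha) - 1) > 1e-9)) {
      stop("alpha rows must be nonnegative and sum to 1")
    }
  }
  rownames(alpha) <- nm
  colnames(alpha) <- type_labels %||% paste0("type", seq_len(n_types))
  structure(list(p = p, alpha = alpha), class = "osm_weights")
}

#' @export
print.osm_weights <- function(x, ...) {
  cat("<osm_weights> ", length(x$p), " edges, ", ncol(x$alpha),
      " substitution types\n", sep = "")
  print(round(x$p, 4))
  invisible(x)
}

check_weights <- function(w, tree, n_types) {
  stopifnot(inherits(w, "osm_weights"))
  if (!identical(names(w$p), tree$edges$name)) {
    stop("weights do not match the tree's edges")
  }
  if (abs(sum(w$p) - 1) > 1e-9) stop("edge weights p_e do not sum to 1")
  if (ncol(w$alpha) != n_types) {
    stop("alpha has ", ncol(w$alpha), " types, group needs ", n_types)
  }
  if (any(abs(rowSums(w$alpha) - 1) > 1e-9)) {
    stop("alpha rows must sum to 1")
  }
  invisible(w)
}
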