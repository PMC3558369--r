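#' Lift a group element onto a tree edge
#'
#' A substitution of type sigma_i on edge e acts simultaneously on every
#' descendant taxon of e and as the identity elsewhere: the operator is the
#' Kronecker product over taxa with sigma_i at descendants of e and sigma_0
#' at the rest. Equivalently, it is the product of the pendant-edge lifts
#' of all descendants of e. The operator is kept as a lazy description
#' (edge, type, descendant mask) and only materialized as an index map or
#' matrix on demand.
#'
#' @param tree an `osm_tree`.
#' @param g an `osm_group` with r elements.
#' @param edge edge name (e.g. `"e_12"`).
#' @param elem a non-identity element: label or index in `2..r`.
#' @return An object of class `osm_edge_operator`.
#' @examples
#' tr <- read_osm_tree("((1,2));")
#' op <- lift_to_edge(tr, osm_group_preset("K3ST"), "e_12", "s1")
#' dim(as.matrix(op))  # 16 16
#' @export
lift_to_edge <- function(tree, g, edge, elem) {
  stopifnot(inherits(tree, "osm_tree"), inherits(g, "osm_group"))
  d <- descendants(tree, edge)
  p <- group_element(g, elem)
  if (all(p$map == seq_along(g$letters))) {
    stop("the identity element is excluded: OSM operators range over the ",
         "r-1 non-identity substitution types")
  }
  structure(list(
    edge = edge, elem = p$label, perm = p,
    mask = tree$taxa %in% d, taxa = tree$taxa,
    letters = g$letters
  ), class = "osm_edge_operator")
}

#' @export
print.osm_edge_operator <- function(x, ...) {
  cat("<osm_edge_operator> ", x$elem, " on ", x$edge, " (acts on taxa ",
      paste(x$taxa[x$mask], collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Apply an edge operator to a character
#'
#' @param op an `osm_edge_operator`.
#' @param f a character (see [osm_character]).
#' @return The image character as a named vector.
#' @export
op_apply <- function(op, f) {
  stopifnot(inherits(op, "osm_edge_operator"))
  f <- as_char_vec(f, op$taxa, op$letters)
  f[op$mask] <- perm_apply(op$perm, f[op$mask])
  f
}

#' @rdname op_apply
#' @param guard cap on r^n for materialization.
#' @return `op_index_map`: an integer vector `map` of length r^n with
#'   `map[i]` the index of the image of character i.
#' @export
op_index_map <- function(op, guard = NULL) {
  stopifnot(inherits(op, "osm_edge_operator"))
  r <- length(op$letters); n <- length(op$taxa)
  N <- r^n
  check_guard(N, guard, "materializing an edge operator")
  idx0 <- 0:(N - 1)
  tgt <- idx0
  for (j in which(op$mask)) {
    pw <- r^(n - j)
    dj <- (idx0 %/% pw) %% r
    tgt <- tgt + (op$perm$map[dj + 1L] - 1 - dj) * pw
  }
  as.integer(tgt + 1)
}

#' @export
as.matrix.osm_edge_operator <- function(x, ...) {
  map <- op_index_map(x)
  N <- length(map)
  chars <- vapply(seq_len(N), function(i) {
    char_string(index_char(i, length(x$taxa), x$letters))
  }, "")
  m <- matrix(0L, N, N, dimnames = list(chars, chars))
  m[cbind(seq_len(N), map)] <- 1L
  m
}

#' All tree-governed operators Sigma_T
#'
#' One operator per (edge, non-identity element) pair:
#' `|E(T)| * (r - 1)` operators in edge-major order.
#'
#' @inheritParams lift_to_edge
#' @param guard cap on r^n applied only when operators are later
#'   materialized; the list itself is lazy and uncapped.
#' @return A named list of `osm_edge_operator`s (`"e_12:s1"`, ...).
#' @examples
#' length(build_sigma_T(read_osm_tree("((1,2));"), osm_group_preset("K3ST")))
#' @export
build_sigma_T <- function(tree, g, guard = NULL) {
  stopifnot(inherits(tree, "osm_tree"), inherits(g, "osm_group"))
  r <- group_size(g)
  ops <- list()
  for (e in tree$edges$name) {
    for (i in 2:r) {
      op <- lift_to_edge(tree, g, e, i)
      ops[[paste0(e, ":", op$elem)]] <- op
    }
  }
  ops
}

#' Assemble the one-step mutation (OSM) matrix
#'
#' The convex sum over edges e and non-identity types i of
#' `alpha_{e,i} * p_e` times the lifted permutation operator: a sparse
#' doubly stochastic matrix on the r^n characters describing the effect of
#' a single substitution somewhere on the tree.
#'
#' @inheritParams build_sigma_T
#' @param w an `osm_weights` object from [normalize_weights()] (must be
#'   normalized; rows of alpha and the p_e each sum to 1).
#' @param guard cap on r^n.
#' @return An object of class `osm_matrix`: sparse `matrix` (a
#'   \pkg{Matrix} `dgCMatrix`), the `decomposition` data frame (edge, type,
#'   weight), and the tree/group/weights used.
#' @examples
#' tr <- read_osm_tree("((1,2));")
#' g <- osm_group_preset("K3ST")
#' m <- build_osm(tr, g, normalize_weights(tr, uniform = TRUE))
#' range(Matrix::rowSums(m$matrix))  # 1 1
#' @export
build_osm <- function(tree, g, w, guard = NULL) {
  stopifnot(inherits(tree, "osm_tree"), inherits(g, "osm_group"))
  r <- group_size(g)
  check_weights(w, tree, r - 1L)
  n <- tree$n
  N <- r^n
  check_guard(N, guard, "assembling the OSM matrix")
  is <- js <- integer(0L); xs <- numeric(0L)
  dec <- list()
  for (ei in seq_along(tree$edges$name)) {
    e <- tree$edges$name[ei]
    for (i in 2:r) {
      op <- lift_to_edge(tree, g, e, i)
      wt <- w$p[[e]] * w$alpha[ei, i - 1L]
      dec[[length(dec) + 1L]] <- data.frame(
        edge = e, type = op$elem, weight = wt, stringsAsFactors = FALSE)
      if (wt == 0) next
      is <- c(is, seq_len(N)); js <- c(js, op_index_map(op, guard))
      xs <- c(xs, rep(wt, N))
    }
  }
  m <- Matrix::sparseMatrix(i = is, j = js, x = xs, dims = c(N, N))
  structure(list(matrix = m, decomposition = do.call(rbind, dec),
                 tree = tree, group = g, weights = w, n = n, r = r),
            class = "osm_matrix")
}

#' @export
print.osm_matrix <- function(x, ...) {
  cat("<osm_matrix> ", nrow(x$matrix), " x ", ncol(x$matrix),
      " doubly stochastic, ", x$r - 1L, " types on ",
      nrow(x$tree$edges), " edges (", x$group$name, ")\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.osm_matrix <- function(x, ...) {
  m <- as.matrix(x$matrix)
  chars <- vapply(seq_len(nrow(m)), function(i) {
    char_string(index_char(i, x$n, x$group$letters))
  }, "")
  dimnames(m) <- list(chars, chars)
  m
}

#' Minimal power of the OSM matrix with a positive (f, fd) entry
#'
#' The smallest k with `M^k[f, fd] > 0` (0 iff `f == fd`). With strictly
#' positive weights this equals the Cayley-graph distance and the minimal
#' substitution count; zero weights would make support and reachability
#' disagree, so they are refused.
#'
#' @param m an `osm_matrix`.
#' @param f,fd characters.
#' @param max_k error if no positive entry is found by this power.
#' @return Integer k.
#' @export
min_power_positive <- function(m, f, fd, max_k = 1000L) {
  stopifnot(inherits(m, "osm_matrix"))
  if (any(m$decomposition$weight <= 0)) {
    stop("min_power_positive needs strictly positive edge/type weights; ",
         "zero-weight operators make matrix support differ from ",
         "reachability")
  }
  letters <- m$group$letters
  fi <- char_index(as_char_vec(f, m$tree$taxa, letters), letters)
  di <- char_index(as_char_vec(fd, m$tree$taxa, letters), letters)
  if (fi == di) return(0L)
  v <- numeric(nrow(m$matrix)); v[fi] <- 1
  for (k in seq_len(max_k)) {
    v <- as.numeric(v %*% m$matrix)
    if (v[di] > 0) return(as.integer(k))
  }
  stop("no positive (f, fd) entry up to power ", max_k)
}

#' Shortest path in the Cayley graph of Sigma_T
#'
#' Breadth-first search over the implicit Cayley graph from `f`, returning
#' the distance to `fd` and one witness sequence of (edge, type)
#' generators. The generator set is closed under inversion, so
#' reachability is symmetric.
#'
#' @inheritParams build_sigma_T
#' @param f,fd characters.
#' @param guard cap on r^n.
#' @return A list with `length` and `path` (character vector of generator
#'   labels `"e:type"`, empty for `f == fd`).
#' @examples
#' tr <- read_osm_tree("((1,2));")
#' cayley_shortest_path(tr, osm_group_preset("K3ST"), "AA", "GC")$length
#' @export
cayley_shortest_path <- function(tree, g, f, fd, guard = NULL) {
  stopifnot(inherits(tree, "osm_tree"), inherits(g, "osm_group"))
  letters <- g$letters
  r <- length(letters); n <- tree$n
  N <- r^n
  check_guard(N, guard, "Cayley BFS")
  fi <- char_index(as_char_vec(f, tree$taxa, letters), letters)
  di <- char_index(as_char_vec(fd, tree$taxa, letters), letters)
  ops <- build_sigma_T(tree, g)
  maps <- lapply(ops, op_index_map, guard = guard)
  labels <- names(ops)
  dist <- rep(NA_integer_, N)
  pred <- integer(N); pred_gen <- integer(N)
  dist[fi] <- 0L
  frontier <- fi
  while (is.na(dist[di]) && length(frontier)) {
    nxt <- integer(0L)
    for (k in seq_along(maps)) {
      img <- maps[[k]][frontier]
      new <- img[is.na(dist[img])]
      src <- frontier[is.na(dist[img])]
      keep <- !duplicated(new)
      new <- new[keep]; src <- src[keep]
      still <- is.na(dist[new])
      new <- new[still]; src <- src[still]
      if (length(new)) {
        dist[new] <- dist[src] + 1L
        pred[new] <- src; pred_gen[new] <- k
        nxt <- c(nxt, new)
      }
    }
    frontier <- unique(nxt)
  }
  if (is.na(dist[di])) stop("target unreachable")  # cannot happen (C6)
  path <- character(0L)
  v <- di
  while (v != fi) {
    path <- c(labels[pred_gen[v]], path)
    v <- pred[v]
  }
  list(length = dist[di], path = path)
}

#' Stationarity report for an OSM matrix
#'
#' Double stochasticity makes the uniform distribution stationary; with
#' strictly positive weights the induced random walk on the character
#' space converges to it. Verifies `u M = u` exactly (within `tol_fixed`)
#' and measures how far a point mass is from uniform after `steps` steps.
#'
#' @param m an `osm_matrix`.
#' @param steps number of random-walk steps (default 200).
#' @param tol convergence tolerance on the maximal deviation from 1/r^n.
#' @param tol_fixed tolerance for the fixed-point check.
#' @param start index or character for the initial point mass (default
#'   first character).
#' @return A list: `uniform_fixed`, `max_dev_fixed`, `max_dev_power`,
#'   `converged`, `steps`.
#' @export
stationary_check <- function(m, steps = 200L, tol = 1e-6,
                             tol_fixed = 1e-12, start = 1L) {
  stopifnot(inherits(m, "osm_matrix"))
  N <- nrow(m$matrix)
  u <- rep(1 / N, N)
  dev_fixed <- max(abs(as.numeric(u %*% m$matrix) - u))
  if (!is.numeric(start)) {
    start <- char_index(as_char_vec(start, m$tree$taxa, m$group$letters),
                        m$group$letters)
  }
  v <- numeric(N); v[start] <- 1
  for (k in seq_len(steps)) v <- as.numeric(v %*% m$matrix)
  dev_power <- max(abs(v - u))
  list(uniform_fixed = dev_fixed <= tol_fixed, max_dev_fixed = dev_fixed,
       max_dev_power = dev_power, converged = dev_power <= tol,
       steps = steps)
}

#' Export an OSM matrix
#'
#' Writes the sparse matrix in MatrixMarket format and the (edge, type,
#' weight) decomposition as TSV.
#'
#' @param m an `osm_matrix`.
#' @param mtx_file path for the MatrixMarket file (`NULL` to skip).
#' @param decomposition_file path for the decomposition TSV (`NULL` to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
export_osm <- function(m, mtx_file = NULL, decomposition_file = NULL) {
  stopifnot(inherits(m, "osm_matrix"))
  if (!is.null(mtx_file)) Matrix::writeMM(m$matrix, mtx_file)
  if (!is.null(decomposition_file)) {
    write.table(m$decomposition, decomposition_file, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(c(mtx_file, decomposition_file))
}

#' Export the Cayley graph as a labelled edge list
#'
#' One row per (character, generator) pair: columns `from`, `to`, `edge`,
#' `type`, with characters written as strings.
#'
#' @inheritParams build_sigma_T
#' @param file TSV path (`NULL` returns the data frame).
#' @param guard cap on r^n.
#' @return The edge-list data frame (invisibly when written to file).
#' @export
export_cayley_edges <- function(tree, g, file = NULL, guard = NULL) {
  ops <- build_sigma_T(tree, g)
  r <- length(g$letters); N <- r^tree$n
  check_guard(N, guard, "Cayley edge-list export")
  chars <- vapply(seq_len(N), function(i) {
    char_string(index_char(i, tree$n, g$letters))
  }, "")
  rows <- lapply(seq_along(ops), function(k) {
    data.frame(from = chars, to = chars[op_index_map(ops[[k]])],
               edge = ops[[k]]$edge, type = ops[[k]]$elem,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(file)) return(out)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
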