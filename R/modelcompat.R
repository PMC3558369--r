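#' Birkhoff-von Neumann decomposition of a doubly stochastic matrix
#'
#' By Birkhoff's theorem a doubly stochastic matrix is a convex combination
#' of permutation matrices. The greedy extraction repeatedly finds a
#' permutation inside the positive support and subtracts its minimal
#' covered entry. Among admissible permutations the one maximizing the
#' minimum covered entry is taken (bottleneck matching, found by binary
#' search over support thresholds with a bipartite perfect matching at
#' each step); this terminates in at most (r-1)^2 + 1 extractions. The
#' decomposition is not unique -- only the reconstruction (weighted sum
#' equal to the input) is contractual.
#'
#' @param m square numeric matrix, doubly stochastic within `tol`.
#' @param tol stochasticity/termination tolerance (default 1e-9).
#' @return An object of class `osm_birkhoff`: list of `weights`,
#'   `permutations` ([perm()] objects labelled `b1, b2, ...`), and the
#'   final `residual` (max-norm of what is left after extraction).
#' @examples
#' d <- birkhoff_decompose(p_sgtr(1/6, 1/6, 1/6, 1/6, 1/6, 1/6))
#' d$weights
#' @export
birkhoff_decompose <- function(m, tol = 1e-9) {
  m <- as.matrix(m)
  r <- nrow(m)
  letters <- rownames(m) %||% default_alphabet(r)
  ds <- stochastic_report(m, tol)
  if (!ds$ok) stop("matrix is not doubly stochastic: ", ds$reason)

  R <- m
  weights <- numeric(0L)
  perms <- list()
  max_terms <- (r - 1L)^2 + 1L
  for (step in seq_len(max_terms)) {
    if (max(R) <= tol) break
    match_cols <- bottleneck_matching(R, tol)
    if (is.null(match_cols)) {
      stop("no perfect matching in the positive support; ",
           "matrix is numerically degenerate")
    }
    w <- min(R[cbind(seq_len(r), match_cols)])
    perms[[length(perms) + 1L]] <- perm(match_cols, letters,
                                        paste0("b", length(perms) + 1L))
    weights <- c(weights, w)
    R[cbind(seq_len(r), match_cols)] <-
      R[cbind(seq_len(r), match_cols)] - w
  }
  residual <- max(abs(R))
  if (residual > sqrt(tol)) {
    stop("Birkhoff extraction left residual ", format(residual),
         "; matrix is numerically degenerate")
  }
  structure(list(weights = weights, permutations = perms,
                 residual = residual, letters = letters),
            class = "osm_birkhoff")
}

#' @export
print.osm_birkhoff <- function(x, ...) {
  cat("<osm_birkhoff> ", length(x$weights), " terms, weights sum ",
      format(sum(x$weights)), ", residual ", format(x$residual), "\n",
      sep = "")
  invisible(x)
}

#' Reconstruct the matrix from a Birkhoff decomposition
#' @param d an `osm_birkhoff`.
#' @return The weighted sum of the permutation matrices.
#' @export
birkhoff_reconstruct <- function(d) {
  stopifnot(inherits(d, "osm_birkhoff"))
  Reduce(`+`, Map(function(w, p) w * as.matrix(p), d$weights,
                  d$permutations))
}

# bottleneck perfect matching on the support of R: the permutation whose
# minimal covered entry is maximal. Returns column indices per row or NULL.
bottleneck_matching <- function(R, tol) {
  r <- nrow(R)
  vals <- sort(unique(R[R > tol]))
  lo <- 1L; hi <- length(vals); best <- NULL
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    m <- perfect_matching(R >= vals[mid] - 1e-15)
    if (!is.null(m)) { best <- m; lo <- mid + 1L } else hi <- mid - 1L
  }
  best
}

# perfect matching rows -> columns in a 0/1 support mask via igraph
perfect_matching <- function(mask) {
  r <- nrow(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < r) return(NULL)
  g <- igraph::make_empty_graph(n = 2L * r, directed = FALSE)
  g <- igraph::add_edges(g, rbind(idx[, 1L], idx[, 2L] + r))
  igraph::V(g)$type <- rep(c(FALSE, TRUE), each = r)
  mm <- igraph::max_bipartite_match(g)
  if (mm$matching_size < r) return(NULL)
  as.integer(mm$matching[seq_len(r)]) - r
}

stochastic_report <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    return(list(ok = FALSE, reason = "matrix is not square"))
  }
  if (any(m < -tol)) {
    ij <- which(m < -tol, arr.ind = TRUE)[1L, ]
    return(list(ok = FALSE, reason = sprintf(
      "negative entry at (%d, %d)", ij[1L], ij[2L])))
  }
  rs <- rowSums(m); cs <- colSums(m)
  bad_r <- which(abs(rs - 1) > tol)
  if (length(bad_r)) {
    return(list(ok = FALSE, reason = sprintf(
      "row %d sums to %.6g, not 1", bad_r[1L], rs[bad_r[1L]])))
  }
  bad_c <- which(abs(cs - 1) > tol)
  if (length(bad_c)) {
    return(list(ok = FALSE, reason = sprintf(
      "column %d sums to %.6g, not 1", bad_c[1L], cs[bad_c[1L]])))
  }
  list(ok = TRUE, reason = NULL)
}

#' Audit a substitution model for OSM compatibility
#'
#' A substitution model fits the OSM framework only if its transition
#' matrix is doubly stochastic (then Birkhoff decomposition yields a set
#' of permutations giving rise to the model) and the extracted permutation
#' set, together with the identity, satisfies the group conditions C1-C6.
#' The symmetric GTR matrix, for instance, decomposes but its permutation
#' set violates closure (C3), commutativity (C4) and fixed-point freeness
#' (C5); models with unequal stationary distribution (Tamura-Nei style) do
#' not even decompose.
#'
#' @param m square transition matrix (rownames taken as the alphabet).
#' @param tol stochasticity tolerance.
#' @param letters alphabet override.
#' @return An object of class `osm_audit`: `decomposable`, `reason` (when
#'   not), `decomposition` (an `osm_birkhoff` or `NULL`) and `report` (an
#'   `osm_conditions` on identity + extracted permutations, or `NULL`).
#' @examples
#' audit_model(p_sgtr(0.1, 0.15, 0.2, 0.25, 0.05, 0.25))
#' @export
audit_model <- function(m, tol = 1e-9, letters = NULL) {
  m <- as.matrix(m)
  letters <- alphabet(letters %||% rownames(m) %||%
                        default_alphabet(nrow(m)))
  dimnames(m) <- list(letters, letters)
  ds <- stochastic_report(m, tol)
  if (!ds$ok) {
    return(structure(list(decomposable = FALSE, reason = ds$reason,
                          decomposition = NULL, report = NULL,
                          letters = letters),
                     class = "osm_audit"))
  }
  dec <- birkhoff_decompose(m, tol)
  perms <- dec$permutations
  id_key <- paste(seq_along(letters), collapse = ",")
  if (!any(vapply(perms, perm_key, "") == id_key)) {
    perms <- c(list(perm_identity(letters, "s0")), perms)
  }
  rep <- check_conditions(perms, letters)
  structure(list(decomposable = TRUE, reason = NULL, decomposition = dec,
                 report = rep, letters = letters),
            class = "osm_audit")
}

#' @export
print.osm_audit <- function(x, ...) {
  cat("<osm_audit> on [", paste(x$letters, collapse = ""), "]\n", sep = "")
  if (!x$decomposable) {
    cat("  not decomposable into a convex sum of permutation matrices:\n",
        "  ", x$reason, "\n", sep = "")
    return(invisible(x))
  }
  cat("  Birkhoff decomposition: ", length(x$decomposition$weights),
      " terms, residual ", format(x$decomposition$residual), "\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Serialize an audit as JSON
#' @param audit an `osm_audit`.
#' @param file path (`NULL` returns the JSON string).
#' @return JSON string (invisibly when written).
#' @export
audit_to_json <- function(audit, file = NULL) {
  stopifnot(inherits(audit, "osm_audit"))
  payload <- list(
    alphabet = audit$letters,
    decomposable = audit$decomposable,
    reason = audit$reason
  )
  if (audit$decomposable) {
    payload$decomposition <- list(
      weights = audit$decomposition$weights,
      permutations = lapply(audit$decomposition$permutations,
                            function(p) list(label = p$label, map = p$map)),
      residual = audit$decomposition$residual
    )
    payload$conditions <- lapply(stats::setNames(paste0("C", 1:7),
                                                 paste0("C", 1:7)),
                                 function(cc) {
      st <- audit$report[[cc]]
      list(pass = st$pass,
           witnesses = if (is.data.frame(st$witnesses)) {
             as.list(st$witnesses)
           } else as.list(st$witnesses))
    })
  }
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

#' The symmetric-GTR permutation set
#'
#' Assigning one permutation matrix to each exchangeability parameter of
#' the symmetric GTR model yields, besides the identity s0, the six
#' transpositions sa (A-C), sb (A-G), sc (A-T), sd (C-G), se (C-T) and
#' sf (G-T). Their convex sum with weights a..f reproduces [p_sgtr()] when
#' a+b+c+d+e+f = 1, but the set is not an admissible OSM group: it
#' violates closure (e.g. sa.sf), commutativity (e.g. sa and sc) and
#' fixed-point freeness (each transposition fixes two states).
#'
#' @return A named list of seven [perm()]s over A,C,G,T (s0 first).
#' @export
sgtr_permutation_set <- function() {
  dna <- dna_alphabet()
  mk <- function(a, b, lab) perm_from_cycles(sprintf("(%s %s)", a, b), dna,
                                             lab)
  list(
    s0 = perm_identity(dna, "s0"),
    sa = mk("A", "C", "sa"), sb = mk("A", "G", "sb"),
    sc = mk("A", "T", "sc"), sd = mk("C", "G", "sd"),
    se = mk("C", "T", "se"), sf = mk("G", "T", "sf")
  )
}

#' Symmetric GTR transition matrix
#'
#' The transition probability matrix of the symmetric form of the general
#' time-reversible model (uniform stationary distribution), over A,C,G,T:
#' off-diagonal exchangeabilities a (A-C), b (A-G), c (A-T), d (C-G),
#' e (C-T), f (G-T) and diagonals making rows sum to 1. It is doubly
#' stochastic whenever the parameters are admissible.
#'
#' @param a,b,c,d,e,f nonnegative exchangeability parameters.
#' @return 4x4 numeric matrix with DNA dimnames.
#' @export
p_sgtr <- function(a, b, c, d, e, f) {
  dna <- dna_alphabet()
  m <- matrix(c(
    1 - a - b - c, a,             b,             c,
    a,             1 - a - d - e, d,             e,
    b,             d,             1 - b - d - f, f,
    c,             e,             f,             1 - c - e - f),
    4L, 4L, byrow = TRUE, dimnames = list(dna, dna))
  if (any(diag(m) < -1e-12)) stop("parameters leave a negative diagonal")
  m
}

#' Read a model matrix from TSV/CSV
#'
#' Expects an alphabet header row and a leading row-label column.
#'
#' @param file path.
#' @param sep field separator (default tab; use "," for CSV).
#' @return Numeric matrix with the alphabet as dimnames.
#' @export
read_model_matrix <- function(file, sep = "\t") {
  tb <- read.table(file, header = TRUE, sep = sep, row.names = 1L,
                   check.names = FALSE)
  m <- as.matrix(tb)
  storage.mode(m) <- "double"
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels disagree")
  }
  m
}
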