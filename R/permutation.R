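#' Permutations of character states
#'
#' A substitution type is modelled as a permutation of the alphabet: a
#' bijection on state indices carrying a short label. The matrix form follows
#' the row convention in which row i has a single 1 in column sigma(i), so a
#' state (indicator row vector) is moved by right multiplication.
#'
#' @param mapping either an integer vector with `mapping[i]` the (1-based)
#'   image index of state i, or a character vector of image letters in
#'   alphabet order.
#' @param letters the alphabet the permutation acts on.
#' @param label short display label, e.g. `"s1"`.
#' @return An object of class `osm_perm`.
#' @examples
#' flip <- perm(c(2, 1), letters = c("0", "1"), label = "tau1")
#' as.matrix(flip)
#' @export
perm <- function(mapping, letters = NULL, label = "s") {
  if (is.character(mapping)) {
    if (is.null(letters)) letters <- alphabet(sort(mapping))
    mapping <- letter_index(mapping, letters)
  }
  mapping <- as.integer(mapping)
  r <- length(mapping)
  if (is.null(letters)) letters <- default_alphabet(r)
  letters <- alphabet(letters)
  if (length(letters) != r || !identical(sort(mapping), seq_len(r))) {
    stop("mapping is not a bijection on the ", length(letters),
         "-state alphabet")
  }
  structure(list(map = mapping, letters = letters, label = as.character(label)),
            class = "osm_perm")
}

#' @rdname perm
#' @export
perm_identity <- function(letters, label = "s0") {
  letters <- alphabet(letters)
  perm(seq_along(letters), letters, label)
}

#' Parse a permutation from cycle notation
#'
#' Cycle notation such as `"(A G)(C T)"` (states separated by spaces or
#' commas; fixed states may be omitted).
#'
#' @param text cycle-notation string.
#' @inheritParams perm
#' @return An `osm_perm`.
#' @examples
#' perm_from_cycles("(A G)(C T)", dna_alphabet(), label = "s1")
#' @export
perm_from_cycles <- function(text, letters, label = "s") {
  letters <- alphabet(letters)
  map <- seq_along(letters)
  body <- gsub("\\s+$", "", gsub("^\\s+", "", text))
  if (nzchar(body)) {
    if (!grepl("^\\s*(\\([^()]*\\)\\s*)+$", body)) {
      stop("malformed cycle notation: ", text)
    }
    cycles <- regmatches(body, gregexpr("\\(([^()]*)\\)", body))[[1]]
    for (cy in cycles) {
      states <- strsplit(gsub("[(),]", " ", cy), "\\s+")[[1]]
      states <- states[nzchar(states)]
      idx <- letter_index(states, letters)
      if (length(states) < 2L) next  # singleton: a fixed state
      if (anyDuplicated(idx)) stop("state repeated inside a cycle: ", cy)
      if (any(map[idx] != idx)) stop("cycles are not disjoint in: ", text)
      map[idx] <- idx[c(seq_along(idx)[-1L], 1L)]
    }
  }
  perm(map, letters, label)
}

#' Apply a permutation to states
#'
#' @param p an `osm_perm`.
#' @param x state letters (or 1-based indices).
#' @return Letters (or indices) of the images.
#' @export
perm_apply <- function(p, x) {
  stopifnot(inherits(p, "osm_perm"))
  if (is.numeric(x)) return(p$map[as.integer(x)])
  p$letters[p$map[letter_index(x, p$letters)]]
}

#' Compose two permutations
#'
#' `compose(a, b)` applies `b` first, then `a`; in matrix form (row
#' convention) it equals `as.matrix(b) %*% as.matrix(a)`.
#'
#' @param a,b `osm_perm` objects over the same alphabet.
#' @param label label for the result (default `"a.b"` from the factors).
#' @return An `osm_perm`.
#' @examples
#' g <- osm_group_preset("K3ST")
#' compose(g$elements[[2]], g$elements[[2]])  # s1 . s1 = s0
#' @export
compose <- function(a, b, label = NULL) {
  stopifnot(inherits(a, "osm_perm"), inherits(b, "osm_perm"))
  if (length(a$map) != length(b$map) || !identical(a$letters, b$letters)) {
    stop("permutations act on different alphabets")
  }
  perm(a$map[b$map], a$letters, label %||% paste0(a$label, ".", b$label))
}

#' Invert a permutation
#' @inheritParams perm_apply
#' @param label label for the inverse.
#' @return An `osm_perm` with `compose(p, perm_inverse(p))` the identity.
#' @export
perm_inverse <- function(p, label = NULL) {
  stopifnot(inherits(p, "osm_perm"))
  perm(order(p$map), p$letters, label %||% paste0(p$label, "^-1"))
}

#' Kronecker product of two permutations
#'
#' The result acts on the product alphabet of size `r_a * r_b`. The left
#' factor is the most significant: combined (0-based) index
#' `i_a * r_b + i_b`. The matrix form equals the Kronecker product of the two
#' matrix forms.
#'
#' @param a,b `osm_perm` objects (possibly over different alphabets).
#' @param letters optional alphabet for the product space (size
#'   `r_a * r_b`); defaults to pasted letter pairs.
#' @param label label for the result.
#' @return An `osm_perm` on the product alphabet.
#' @examples
#' tau0 <- perm_identity(c("R", "Y"), "tau0")
#' tau1 <- perm(c(2, 1), c("R", "Y"), "tau1")
#' as.matrix(perm_kronecker(tau1, tau0, letters = dna_alphabet()))
#' @export
perm_kronecker <- function(a, b, letters = NULL, label = NULL) {
  stopifnot(inherits(a, "osm_perm"), inherits(b, "osm_perm"))
  ra <- length(a$map); rb <- length(b$map)
  ia <- rep(seq_len(ra), each = rb)   # left factor, most significant
  ib <- rep(seq_len(rb), times = ra)
  map <- (a$map[ia] - 1L) * rb + b$map[ib]
  letters <- letters %||%
    as.vector(t(outer(a$letters, b$letters, paste0)))
  perm(map, letters, label %||% paste0(a$label, "x", b$label))
}

#' @export
as.matrix.osm_perm <- function(x, ...) {
  r <- length(x$map)
  m <- matrix(0L, r, r, dimnames = list(x$letters, x$letters))
  m[cbind(seq_len(r), x$map)] <- 1L
  m
}

#' @export
print.osm_perm <- function(x, ...) {
  moved <- which(x$map != seq_along(x$map))
  cycles <- if (length(moved) == 0L) {
    "identity"
  } else {
    seen <- logical(length(x$map)); out <- character()
    for (i in moved) {
      if (seen[i]) next
      cyc <- i; j <- x$map[i]
      while (j != i) { cyc <- c(cyc, j); j <- x$map[j] }
      seen[cyc] <- TRUE
      out <- c(out, paste0("(", paste(x$letters[cyc], collapse = " "), ")"))
    }
    paste(out, collapse = "")
  }
  cat("<osm_perm> ", x$label, " on [", paste(x$letters, collapse = ""),
      "]: ", cycles, "\n", sep = "")
  invisible(x)
}

#' Export a permutation matrix as a TSV table
#'
#' Writes the dense 0/1 matrix with alphabet row and column headers.
#'
#' @inheritParams perm_apply
#' @param file path of the TSV file to write.
#' @return The file path, invisibly.
#' @export
export_perm_tsv <- function(p, file) {
  m <- as.matrix(p)
  write.table(m, file, sep = "\t", quote = FALSE, col.names = NA)
  invisible(file)
}

# canonical key used to compare permutations as set elements
perm_key <- function(p) paste(p$map, collapse = ",")
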