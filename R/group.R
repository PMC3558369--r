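#' Group actions on a character-state alphabet
#'
#' A group action bundles an ordered alphabet with a set of permutations
#' (identity first) that is expected to form an Abelian group acting
#' regularly on the states: conditions C1 (bijectivity), C2 (regularity:
#' exactly one element maps any state to any other), C3 (closure), C4
#' (commutativity), C5 (identity present, all other elements fixed-point
#' free) and C6 (inverses). Associativity (C7) holds for any set of
#' permutations. Under C2 the group has exactly as many elements as the
#' alphabet has states.
#'
#' @param elements list of [perm()] objects over a common alphabet.
#' @param letters the alphabet; defaults to the alphabet of the first
#'   element.
#' @param name display name.
#' @param validate if `TRUE` (default), [check_conditions()] is run and a
#'   violation of C1-C6 is an error.
#' @return An object of class `osm_group` with fields `letters`, `elements`,
#'   `name` and the composition index `table`.
#' @examples
#' osm_group_preset("K3ST")
#' @export
osm_group <- function(elements, letters = NULL, name = "group",
                      validate = TRUE) {
  if (length(elements) == 0L) stop("a group needs at least one element")
  stopifnot(all(vapply(elements, inherits, TRUE, "osm_perm")))
  letters <- alphabet(letters %||% elements[[1L]]$letters)
  for (e in elements) {
    if (!identical(e$letters, letters)) {
      stop("element ", e$label, " acts on a different alphabet")
    }
  }
  # identity first
  id_at <- which(vapply(elements, function(e) all(e$map == seq_along(letters)),
                        TRUE))
  if (length(id_at) == 1L && id_at != 1L) {
    elements <- c(elements[id_at], elements[-id_at])
  }
  g <- structure(
    list(letters = letters, elements = elements, name = name, table = NULL),
    class = "osm_group")
  if (validate) {
    rep <- check_conditions(elements, letters)
    if (!conditions_pass(rep)) {
      stop("the element set is not an Abelian group acting regularly on [",
           paste(letters, collapse = ""), "]:\n",
           paste(utils::capture.output(print(rep)), collapse = "\n"))
    }
  }
  g$table <- composition_table(g)
  g
}

group_size <- function(g) length(g$elements)

group_labels <- function(g) vapply(g$elements, `[[`, "", "label")

#' Look up a group element by label or index
#' @param g an `osm_group`.
#' @param which element label (e.g. `"s1"`) or integer index.
#' @return An `osm_perm`.
#' @export
group_element <- function(g, which) {
  stopifnot(inherits(g, "osm_group"))
  if (is.numeric(which)) return(g$elements[[as.integer(which)]])
  i <- match(which, group_labels(g))
  if (is.na(i)) stop("no element labelled '", which, "' in ", g$name)
  g$elements[[i]]
}

# index table: table[i, j] = k with elements[[k]] = compose(e_i, e_j)
composition_table <- function(g) {
  keys <- vapply(g$elements, perm_key, "")
  k <- length(keys)
  tab <- matrix(NA_integer_, k, k, dimnames = list(group_labels(g),
                                                   group_labels(g)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      tab[i, j] <- match(perm_key(compose(g$elements[[i]], g$elements[[j]])),
                         keys)
    }
  }
  tab
}

#' @export
print.osm_group <- function(x, ...) {
  cat("<osm_group> ", x$name, ": ", group_size(x), " elements on [",
      paste(x$letters, collapse = ""), "]\n", sep = "")
  cat("  elements:", paste(group_labels(x), collapse = ", "), "\n")
  invisible(x)
}

#' Audit a set of permutations against the group conditions
#'
#' Checks conditions C1-C7 and reports every failure with concrete
#' witnesses, rather than stopping at the first, so that model audits yield
#' complete diagnostics. A set is an admissible OSM group iff C1-C6 all hold
#' (C7, associativity, is automatic for permutations and is reported as
#' passing).
#'
#' @param candidate list of [perm()] objects, or an `osm_group`.
#' @param letters the common alphabet (defaults to the first candidate's).
#' @return An object of class `osm_conditions`: per-condition `pass` flags
#'   and witness tables.
#' @examples
#' check_conditions(sgtr_permutation_set())
#' @export
check_conditions <- function(candidate, letters = NULL) {
  if (inherits(candidate, "osm_group")) {
    letters <- letters %||% candidate$letters
    candidate <- candidate$elements
  }
  stopifnot(length(candidate) >= 1L,
            all(vapply(candidate, inherits, TRUE, "osm_perm")))
  letters <- alphabet(letters %||% candidate[[1L]]$letters)
  r <- length(letters)
  labs <- vapply(candidate, `[[`, "", "label")
  keys <- vapply(candidate, perm_key, "")
  k <- length(candidate)
  id_key <- paste(seq_len(r), collapse = ",")

  rep <- list(letters = letters, labels = labs, n_elements = k)

  # C1: every candidate is a bijection (guaranteed by the perm constructor,
  # re-checked defensively)
  bad1 <- labs[!vapply(candidate, function(p) {
    identical(sort(p$map), seq_len(r)) && length(p$map) == r
  }, TRUE)]
  rep$C1 <- list(pass = length(bad1) == 0L, witnesses = bad1)

  # C2: regular action -- every ordered state pair covered exactly once
  cover <- matrix(0L, r, r, dimnames = list(letters, letters))
  for (p in candidate) cover[cbind(seq_len(r), p$map)] <-
    cover[cbind(seq_len(r), p$map)] + 1L
  off <- which(cover != 1L, arr.ind = TRUE)
  w2 <- if (nrow(off)) {
    data.frame(from = letters[off[, 1L]], to = letters[off[, 2L]],
               count = cover[off], stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), count = integer())
  }
  rep$C2 <- list(pass = nrow(w2) == 0L, witnesses = w2)

  # C3 closure and C4 commutativity over all ordered pairs
  w3 <- w4 <- data.frame(a = character(), b = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ij <- perm_key(compose(candidate[[i]], candidate[[j]]))
      if (!(ij %in% keys)) w3 <- rbind(w3, data.frame(a = labs[i], b = labs[j]))
      if (j > i) {
        ji <- perm_key(compose(candidate[[j]], candidate[[i]]))
        if (!identical(ij, ji)) {
          w4 <- rbind(w4, data.frame(a = labs[i], b = labs[j]))
        }
      }
    }
  }
  rep$C3 <- list(pass = nrow(w3) == 0L, witnesses = w3)
  rep$C4 <- list(pass = nrow(w4) == 0L, witnesses = w4)

  # C5: identity present, all non-identity elements fixed-point free
  has_id <- id_key %in% keys
  w5 <- data.frame(element = character(), fixes = character(),
                   stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    if (keys[i] == id_key) next
    fx <- which(candidate[[i]]$map == seq_len(r))
    if (length(fx)) {
      w5 <- rbind(w5, data.frame(element = labs[i],
                                 fixes = paste(letters[fx], collapse = "")))
    }
  }
  rep$C5 <- list(pass = has_id && nrow(w5) == 0L, witnesses = w5,
                 identity_present = has_id)

  # C6: inverses present
  bad6 <- labs[!vapply(candidate, function(p) {
    perm_key(perm_inverse(p)) %in% keys
  }, TRUE)]
  rep$C6 <- list(pass = length(bad6) == 0L, witnesses = bad6)

  # C7: associativity -- automatic for permutation composition
  rep$C7 <- list(pass = TRUE, witnesses = character())

  structure(rep, class = "osm_conditions")
}

#' @rdname check_conditions
#' @param report an `osm_conditions` object.
#' @export
conditions_pass <- function(report) {
  all(vapply(paste0("C", 1:6), function(cc) isTRUE(report[[cc]]$pass), TRUE))
}

#' @export
print.osm_conditions <- function(x, ...) {
  cat("<osm_conditions> ", x$n_elements, " permutations on [",
      paste(x$letters, collapse = ""), "]\n", sep = "")
  note <- c(C1 = "bijective", C2 = "regular action", C3 = "closed",
            C4 = "commutative", C5 = "identity & fixed-point free",
            C6 = "inverses", C7 = "associative")
  for (cc in paste0("C", 1:7)) {
    st <- x[[cc]]
    cat(sprintf("  %s %-28s %s\n", cc, paste0("(", note[[cc]], "):"),
                if (st$pass) "pass" else "FAIL"))
    if (!st$pass && length(st$witnesses)) {
      w <- st$witnesses
      msg <- if (is.data.frame(w)) {
        if (all(c("a", "b") %in% names(w))) {
          paste0(w$a, "*", w$b, collapse = ", ")
        } else if (all(c("element", "fixes") %in% names(w))) {
          paste0(w$element, " fixes ", w$fixes, collapse = "; ")
        } else {
          paste0(w$from, "->", w$to, " covered ", w$count, "x",
                 collapse = ", ")
        }
      } else paste(w, collapse = ", ")
      cat("       witnesses: ", substr(msg, 1L, 200L), "\n", sep = "")
    }
  }
  cat(if (conditions_pass(x)) {
    "  => admissible OSM group (C1-C6 hold)\n"
  } else "  => NOT an admissible OSM group\n")
  invisible(x)
}

#' Build a cyclic group from a full cycle on the alphabet
#'
#' The group consists of the powers of one r-cycle. The default generator
#' sends state i to state i+1 (mod r) in alphabet order; for DNA the named
#' preset `osm_group_preset("Z4")` instead uses the cycle A>G>T>C>A.
#'
#' @param r alphabet size.
#' @param cycle the generator, as an [perm()], as a character vector giving
#'   the cycle order (e.g. `c("A","G","T","C")`), or `NULL` for the default.
#' @param letters the alphabet (default [default_alphabet()]).
#' @param label_prefix element labels are `<prefix>0` (identity) to
#'   `<prefix>r-1`.
#' @param name group name.
#' @return An `osm_group` with `r` elements.
#' @examples
#' build_cyclic(2)
#' build_cyclic(4, cycle = c("A", "G", "T", "C"))
#' @export
build_cyclic <- function(r, cycle = NULL, letters = NULL, label_prefix = "s",
                         name = NULL) {
  r <- as.integer(r)
  if (r < 1L) stop("r must be a positive integer")
  letters <- alphabet(letters %||% default_alphabet(r))
  if (length(letters) != r) stop("alphabet size does not match r")
  gen <- if (is.null(cycle)) {
    perm(c(seq_len(r)[-1L], 1L), letters, paste0(label_prefix, 1L))
  } else if (inherits(cycle, "osm_perm")) {
    cycle
  } else {
    idx <- letter_index(as.character(cycle), letters)
    if (length(idx) != r || anyDuplicated(idx)) {
      stop("cycle must visit every state exactly once")
    }
    map <- integer(r)
    map[idx] <- idx[c(seq_len(r)[-1L], 1L)]
    perm(map, letters, paste0(label_prefix, 1L))
  }
  if (!identical(gen$letters, letters)) {
    stop("generator acts on a different alphabet")
  }
  # the generator must be a single r-cycle, otherwise the powers do not act
  # regularly with r elements
  ord <- 1L; p <- gen
  while (any(p$map != seq_len(r))) { p <- compose(gen, p); ord <- ord + 1L }
  if (r > 1L && ord != r) {
    stop("generator is not a full ", r, "-cycle (its order is ", ord, ")")
  }
  els <- vector("list", r)
  els[[1L]] <- perm_identity(letters, paste0(label_prefix, 0L))
  p <- perm_identity(letters)
  for (k in seq_len(r - 1L)) {
    p <- compose(gen, p)
    els[[k + 1L]] <- perm(p$map, letters, paste0(label_prefix, k))
  }
  osm_group(els, letters, name %||% paste0("Z", r))
}

#' Direct product of group actions via Kronecker products
#'
#' The product acts on the product alphabet (size = product of the factor
#' sizes, left factor most significant); its elements are all Kronecker
#' products of one element per factor. Element labels are `g0 ... g(r-1)` in
#' product-index order; the attribute `factor_index` records, per element,
#' the 0-based index of the contributing element in each factor.
#'
#' @param factors list of `osm_group` objects.
#' @param letters optional alphabet for the product space.
#' @param name group name.
#' @param label_prefix prefix for the product element labels.
#' @return An `osm_group` over the product alphabet.
#' @examples
#' z2 <- build_cyclic(2, letters = c("R", "Y"), label_prefix = "tau")
#' build_product(list(z2, z2), letters = dna_alphabet())  # Klein four-group
#' @export
build_product <- function(factors, letters = NULL, name = NULL,
                          label_prefix = "g") {
  if (length(factors) == 0L) stop("empty factor list")
  stopifnot(all(vapply(factors, inherits, TRUE, "osm_group")))
  sizes <- vapply(factors, group_size, 1L)
  total <- prod(sizes)
  if (!is.null(letters)) {
    letters <- alphabet(letters)
    if (length(letters) != total) {
      stop("product alphabet must have ", total, " states")
    }
  }
  grid <- expand.grid(rev(lapply(sizes, seq_len)))[, length(sizes):1L,
                                                   drop = FALSE]
  els <- vector("list", total)
  fidx <- matrix(0L, total, length(sizes))
  for (k in seq_len(total)) {
    sel <- as.integer(grid[k, ])
    p <- factors[[1L]]$elements[[sel[1L]]]
    if (length(factors) > 1L) {
      for (j in 2L:length(factors)) {
        p <- perm_kronecker(p, factors[[j]]$elements[[sel[j]]])
      }
    }
    lets <- letters %||% p$letters
    els[[k]] <- perm(p$map, lets, paste0(label_prefix, k - 1L))
    fidx[k, ] <- sel - 1L
  }
  nm <- name %||% paste(vapply(factors, `[[`, "", "name"), collapse = "x")
  g <- osm_group(els, letters %||% els[[1L]]$letters, nm)
  attr(g, "factor_index") <- fidx
  attr(g, "factor_sizes") <- sizes
  g
}

#' The unique group element mapping one state to another
#'
#' Under regularity (C2) there is exactly one element of the group sending
#' `from` to `to`; in particular `transformer(g, x, x)` is the identity.
#'
#' @param g an `osm_group` acting regularly.
#' @param from,to state letters.
#' @return An `osm_perm`.
#' @examples
#' transformer(osm_group_preset("K3ST"), "G", "A")  # s1
#' @export
transformer <- function(g, from, to) {
  stopifnot(inherits(g, "osm_group"))
  i <- letter_index(from, g$letters)
  j <- letter_index(to, g$letters)
  hits <- which(vapply(g$elements, function(p) p$map[i] == j, TRUE))
  if (length(hits) != 1L) {
    stop("group does not act regularly: ", length(hits),
         " element(s) map ", from, " to ", to)
  }
  g$elements[[hits]]
}

#' Enumerate the four-cycles on a four-state alphabet
#'
#' There are six different four-cycles on a four-letter alphabet; a cycle
#' and its inverse generate the same cyclic group, so they collapse to three
#' distinguishable Abelian groups.
#'
#' @param letters a four-state alphabet (default DNA).
#' @return A list with `count_cycles`, `distinct_groups`, the `cycles`
#'   (character matrix, one cycle order per row), the distinct `groups`, and
#'   `class_of` assigning each cycle to its group.
#' @export
enumerate_four_cycle_groups <- function(letters = dna_alphabet()) {
  letters <- alphabet(letters)
  if (length(letters) != 4L) stop("alphabet must have exactly 4 states")
  permutations3 <- matrix(c(2, 3, 4, 2, 4, 3, 3, 2, 4,
                            3, 4, 2, 4, 2, 3, 4, 3, 2),
                          ncol = 3L, byrow = TRUE)
  cycles <- cbind(1L, permutations3)  # fix the first state, order the rest
  keys <- character(nrow(cycles))
  groups <- list()
  class_of <- integer(nrow(cycles))
  for (k in seq_len(nrow(cycles))) {
    g <- build_cyclic(4L, cycle = letters[cycles[k, ]], letters = letters)
    key <- paste(sort(vapply(g$elements, perm_key, "")), collapse = ";")
    at <- match(key, keys[seq_len(length(groups))])
    hit <- which(vapply(groups, function(gg) {
      identical(sort(vapply(gg$elements, perm_key, "")),
                sort(vapply(g$elements, perm_key, "")))
    }, TRUE))
    if (length(hit) == 0L) {
      groups[[length(groups) + 1L]] <- g
      class_of[k] <- length(groups)
    } else {
      class_of[k] <- hit[1L]
    }
  }
  cyc <- matrix(letters[cycles], nrow = nrow(cycles))
  list(count_cycles = nrow(cycles), distinct_groups = length(groups),
       cycles = cyc, groups = groups, class_of = class_of)
}

#' Enumerate direct-product constructions of a given order
#'
#' Lists all unordered factorizations of `r` into integer factors >= 2; each
#' factorization names a direct product of cyclic groups of those orders
#' (e.g. for r = 20: Z20, Z2xZ10, Z4xZ5 and Z2xZ2xZ5). Constructions that
#' are isomorphic as abstract groups (Z20 and Z4xZ5, say) are deliberately
#' kept distinct; see [reduce_isomorphism_classes()].
#'
#' @param r order, at least 2.
#' @return A list of integer vectors (non-increasing factor multisets).
#' @examples
#' enumerate_constructions(20)
#' @export
enumerate_constructions <- function(r) {
  r <- as.integer(r)
  if (r < 2L) stop("r must be at least 2")
  factorize <- function(m, max_factor) {
    out <- list()
    if (m <= max_factor) out <- list(m)
    ds <- which(m %% seq_len(m) == 0L)
    for (d in rev(ds[ds >= 2L & ds < m & ds <= max_factor])) {
      for (tail in factorize(m %/% d, d)) out <- c(out, list(c(d, tail)))
    }
    out
  }
  lapply(factorize(r, r), as.integer)
}

#' Collapse product constructions into abstract isomorphism classes
#'
#' Two direct products of cyclic groups are isomorphic iff they have the
#' same multiset of prime-power factors (primary decomposition). This
#' reducer is provided for reporting and is never applied implicitly.
#'
#' @param constructions a list of factor vectors as returned by
#'   [enumerate_constructions()].
#' @return A list of classes; each class holds `primary` (the sorted prime
#'   powers) and the member `constructions`.
#' @export
reduce_isomorphism_classes <- function(constructions) {
  primary <- function(factors) {
    pp <- integer()
    for (f in factors) {
      m <- f
      p <- 2L
      while (m > 1L) {
        if (m %% p == 0L) {
          q <- 1L
          while (m %% p == 0L) { q <- q * p; m <- m %/% p }
          pp <- c(pp, q)
        }
        p <- p + 1L
      }
    }
    sort(pp)
  }
  keys <- vapply(constructions, function(fs) paste(primary(fs), collapse = "x"),
                 "")
  out <- list()
  for (k in unique(keys)) {
    members <- constructions[keys == k]
    out[[length(out) + 1L]] <- list(primary = primary(members[[1L]]),
                                    constructions = members)
  }
  out
}

#' Cyclic subgroup generated by one element
#'
#' @param g an `osm_group`.
#' @param element element label or index in `g`.
#' @return An `osm_group` (not validated for regularity on the full
#'   alphabet; it is a subgroup, so C1/C3-C7 hold).
#' @export
subgroup_generated <- function(g, element) {
  stopifnot(inherits(g, "osm_group"))
  gen <- group_element(g, element)
  r <- length(g$letters)
  els <- list(perm_identity(g$letters, "s0"))
  p <- gen
  while (any(p$map != seq_len(r))) {
    els[[length(els) + 1L]] <- p
    p <- compose(gen, p)
  }
  structure(list(letters = g$letters, elements = els,
                 name = paste0("<", gen$label, ">"), table = NULL),
            class = "osm_group")
}

#' Orbit partition of the alphabet under a subgroup
#'
#' Computes the orbits of the subgroup acting on the states. For a subgroup
#' of a regular Abelian group the orbits are the cosets: all blocks have
#' exactly `|subgroup|` states (e.g. the Z5 subgroup of Z2xZ2xZ5 bins the 20
#' states into four sets of five).
#'
#' @param g an `osm_group`.
#' @param subgroup an `osm_group` whose elements all belong to `g`.
#' @return A list of character vectors partitioning the alphabet.
#' @export
coset_partition <- function(g, subgroup) {
  stopifnot(inherits(g, "osm_group"), inherits(subgroup, "osm_group"))
  if (!identical(g$letters, subgroup$letters)) {
    stop("subgroup acts on a different alphabet")
  }
  gkeys <- vapply(g$elements, perm_key, "")
  skeys <- vapply(subgroup$elements, perm_key, "")
  if (!all(skeys %in% gkeys)) {
    bad <- group_labels(subgroup)[!(skeys %in% gkeys)]
    stop("subgroup element(s) not contained in ", g$name, ": ",
         paste(bad, collapse = ", "))
  }
  r <- length(g$letters)
  assigned <- logical(r)
  blocks <- list()
  for (i in seq_len(r)) {
    if (assigned[i]) next
    orbit <- sort(unique(vapply(subgroup$elements,
                                function(p) p$map[i], 1L)))
    assigned[orbit] <- TRUE
    blocks[[length(blocks) + 1L]] <- g$letters[orbit]
  }
  blocks
}

#' Named group presets
#'
#' `"K3ST"`: the Klein four-group Z2xZ2 over A,C,G,T with the transition
#' s1 (A-G, C-T) and the transversions s2 (A-C, G-T) and s3 (A-T, C-G);
#' `"Z4"`: the cyclic group generated by the four-cycle A>G>T>C>A, with
#' labels s'1..s'3; `"K2ST"`: the cyclic group generated by A>C>G>T>A
#' (under which s'2 is the transition and s'1, s'3 the undistinguished
#' transversions); `"Z2"`: identity and flip on a binary alphabet.
#'
#' @param name one of `"K3ST"`, `"Z4"`, `"K2ST"`, `"Z2"`.
#' @return An `osm_group`.
#' @export
osm_group_preset <- function(name = c("K3ST", "Z4", "K2ST", "Z2")) {
  name <- match.arg(name)
  dna <- dna_alphabet()
  switch(name,
    K3ST = {
      tau0 <- perm_identity(c("0", "1"), "tau0")
      tau1 <- perm(c(2L, 1L), c("0", "1"), "tau1")
      els <- list(
        perm(perm_kronecker(tau0, tau0)$map, dna, "s0"),
        perm(perm_kronecker(tau1, tau0)$map, dna, "s1"),
        perm(perm_kronecker(tau0, tau1)$map, dna, "s2"),
        perm(perm_kronecker(tau1, tau1)$map, dna, "s3"))
      osm_group(els, dna, "K3ST")
    },
    Z4 = build_cyclic(4L, cycle = c("A", "G", "T", "C"), letters = dna,
                      label_prefix = "s'", name = "Z4"),
    K2ST = build_cyclic(4L, cycle = c("A", "C", "G", "T"), letters = dna,
                        label_prefix = "s'", name = "K2ST"),
    Z2 = build_cyclic(2L, letters = c("0", "1"), label_prefix = "tau",
                      name = "Z2")
  )
}

#' Parse a group specification string
#'
#' Mini-language used by the command-line tools and config files:
#' \itemize{
#'   \item `"K3ST"`, `"K2ST"` -- named presets;
#'   \item `"Z4"` -- over DNA, the preset cycle A>G>T>C>A; `"Zr"` for other
#'     r, the default cycle on [default_alphabet()];
#'   \item `"Z4:A>G>T>C>A"` -- cyclic with an explicit cycle;
#'   \item `"Z2xZ2"`, `"Z4xZ5"`, `"Z2xZ2xZ5"`, `"Z20"`, ... -- direct
#'     products of cyclic groups over the product alphabet (DNA for size 4,
#'     amino acids for size 20);
#'   \item `"cycles:(A G)(C T);(A C)(G T);..."` -- an explicit permutation
#'     list in cycle notation over `letters` (the identity is added).
#' }
#'
#' @param spec specification string.
#' @param letters alphabet override (default chosen from the total size).
#' @return An `osm_group`.
#' @examples
#' parse_group_spec("Z4xZ5")
#' @export
parse_group_spec <- function(spec, letters = NULL) {
  spec <- sub("\\s+$", "", sub("^\\s+", "", spec))
  if (startsWith(spec, "cycles:")) {
    # keep whitespace: it separates states inside cycles
    if (is.null(letters)) stop("explicit cycle lists need `letters`")
    letters <- alphabet(letters)
    body <- sub("^cycles:", "", spec)
    parts <- strsplit(body, ";", fixed = TRUE)[[1L]]
    els <- list(perm_identity(letters, "s0"))
    for (k in seq_along(parts)) {
      els[[k + 1L]] <- perm_from_cycles(parts[k], letters,
                                        label = paste0("s", k))
    }
    return(osm_group(els, letters, spec))
  }
  spec <- gsub("\\s+", "", spec)
  if (toupper(spec) %in% c("K3ST", "K2ST")) {
    return(osm_group_preset(toupper(spec)))
  }
  parts <- strsplit(spec, "x", fixed = TRUE)[[1L]]
  parsed <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^Z([0-9]+)(:(.*))?$", p))[[1L]]
    if (length(m) == 0L || !nzchar(m[2L])) {
      stop("cannot parse group factor '", p, "'")
    }
    list(r = as.integer(m[2L]), cycle = if (nzchar(m[4L])) m[4L] else NULL)
  })
  if (length(parsed) == 1L) {
    r <- parsed[[1L]]$r
    letters <- alphabet(letters %||% default_alphabet(r))
    cyc <- parsed[[1L]]$cycle
    if (!is.null(cyc)) {
      states <- strsplit(cyc, ">", fixed = TRUE)[[1L]]
      if (length(states) == length(letters) + 1L &&
          states[1L] == states[length(states)]) {
        states <- states[-length(states)]
      }
      return(build_cyclic(r, cycle = states, letters = letters,
                          name = spec))
    }
    if (r == 4L && identical(letters, dna_alphabet())) {
      return(osm_group_preset("Z4"))
    }
    return(build_cyclic(r, letters = letters, name = spec))
  }
  sizes <- vapply(parsed, `[[`, 1L, "r")
  facs <- lapply(parsed, function(f) {
    build_cyclic(f$r, letters = default_alphabet(f$r))
  })
  letters <- alphabet(letters %||% default_alphabet(prod(sizes)))
  build_product(facs, letters = letters, name = spec)
}
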