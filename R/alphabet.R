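#' Character-state alphabets
#'
#' An alphabet is an ordered vector of distinct state symbols. The ordering is
#' user-visible and meaningful: permutation matrices are printed with these
#' row/column labels, and the Kronecker lift indexes the character space by
#' it. The DNA preset uses the ordering A, C, G, T.
#'
#' @param letters character vector of distinct symbols.
#' @return A validated character vector of states.
#' @examples
#' alphabet(c("A", "C", "G", "T"))
#' dna_alphabet()
#' @export
alphabet <- function(letters) {
  letters <- as.character(letters)
  if (length(letters) < 1L) stop("alphabet must contain at least one state")
  if (anyDuplicated(letters)) {
    stop("alphabet states must be unique: duplicated ",
         paste(unique(letters[duplicated(letters)]), collapse = ", "))
  }
  if (any(is.na(letters)) || any(!nzchar(letters))) {
    stop("alphabet states must be non-empty strings")
  }
  letters
}

#' @rdname alphabet
#' @export
dna_alphabet <- function() c("A", "C", "G", "T")

#' @rdname alphabet
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname alphabet
#' @param r alphabet size for a generic alphabet: DNA for 4, amino acids for
#'   20, otherwise capital letters (then letter pairs) in order.
#' @export
default_alphabet <- function(r) {
  r <- as.integer(r)
  if (r == 4L) return(dna_alphabet())
  if (r == 20L) return(aa_alphabet())
  if (r <= 26L) return(LETTERS[seq_len(r)])
  pairs <- as.vector(outer(LETTERS, LETTERS, paste0))
  alphabet(c(LETTERS, pairs)[seq_len(r)])
}

letter_index <- function(x, letters) {
  i <- match(x, letters)
  if (anyNA(x) || anyNA(i)) {
    bad <- unique(x[is.na(i) | is.na(x)])
    stop("state(s) not in alphabet [", paste(letters, collapse = ""),
         "]: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  i
}
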