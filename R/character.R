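#' Alignment-column characters
#'
#' A character (site pattern) assigns one alphabet state to every taxon.
#' Functions in this package accept characters as a single string
#' (`"GTAGA"`, taxa in tree order, only for single-letter states), as a
#' character vector of states, or as a named vector matched to the tree's
#' taxa by name.
#'
#' @name osm_character
NULL

# normalize a user-supplied character to a vector of states in `taxa` order
as_char_vec <- function(x, taxa, letters) {
  n <- length(taxa)
  if (length(x) == 1L && is.character(x) && nchar(x) == n &&
      all(nchar(letters) == 1L)) {
    x <- strsplit(x, "")[[1L]]
  }
  x <- as.character(x)
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    if (!setequal(names(x), taxa)) {
      stop("character names do not match the taxa: ",
           paste(taxa, collapse = ", "))
    }
    x <- x[taxa]
  }
  if (length(x) != n) {
    stop("character has ", length(x), " states but the tree has ", n,
         " taxa")
  }
  letter_index(x, letters)  # validates
  stats::setNames(unname(x), taxa)
}

char_string <- function(x) paste(x, collapse = "")

# 1-based flat index of a character in the r^n space (taxon 1 most
# significant), consistent with the Kronecker convention
char_index <- function(x, letters, n = length(x)) {
  r <- length(letters)
  d <- letter_index(x, letters) - 1L
  as.integer(sum(d * r^((n - 1L):0)) + 1)
}

index_char <- function(i, n, letters) {
  r <- length(letters)
  i0 <- i - 1L
  d <- integer(n)
  for (j in n:1L) { d[j] <- i0 %% r; i0 <- i0 %/% r }
  letters[d + 1L]
}

#' Read a character from a two-column TSV
#'
#' Expects columns `taxon` and `state` (header optional when exactly two
#' columns are present).
#'
#' @param file path to the TSV file.
#' @return A named character vector (taxon -> state).
#' @export
character_from_tsv <- function(file) {
  tb <- read.table(file, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(tb) != 2L) stop("expected two columns: taxon, state")
  if (identical(tolower(tb[1L, 1L]), "taxon")) tb <- tb[-1L, , drop = FALSE]
  stats::setNames(toupper(tb[[2L]]), tb[[1L]])
}

#' Read one alignment column from a FASTA file
#'
#' @param file path to an (uncompressed, aligned) FASTA file.
#' @param column 1-based alignment column index.
#' @return A named character vector (sequence name -> state).
#' @export
character_from_fasta <- function(file, column) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no FASTA records in ", file)
  nm <- sub("^>\\s*(\\S+).*$", "\\1", lines[heads])
  bounds <- c(heads, length(lines) + 1L)
  seqs <- vapply(seq_along(heads), function(k) {
    paste(lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)], collapse = "")
  }, "")
  if (any(nchar(seqs) < column)) {
    stop("alignment column ", column, " beyond sequence length")
  }
  stats::setNames(toupper(substr(seqs, column, column)), nm)
}
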