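#' Construct an alphabet of discrete character states
#'
#' An alphabet is an ordered set of distinct tokens over which a substitution
#' model is defined. Tokens are single characters for nucleotides and amino
#' acids and triplets for codons, but any distinct strings are accepted, so
#' models over arbitrary state spaces (binary characters, custom motifs such
#' as the three stop codons) can be built.
#'
#' @param symbols character vector of distinct tokens, length >= 2.
#' @param label free-text name used in printing.
#' @return An object of class `gs_alphabet` with elements `symbols`,
#'   `index` (named integer vector mapping token to position) and `label`.
#' @examples
#' make_alphabet(c("0", "1"), "binary")
#' @export
make_alphabet <- function(symbols, label = "custom") {
  symbols <- as.character(symbols)
  if (length(symbols) < 2L) {
    stop("an alphabet needs at least 2 symbols", call. = FALSE)
  }
  if (anyDuplicated(symbols)) {
    stop("alphabet symbols must be unique; duplicated: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(symbols = symbols,
         index = stats::setNames(seq_along(symbols), symbols),
         label = label),
    class = "gs_alphabet"
  )
}

#' @export
print.gs_alphabet <- function(x, ...) {
  cat("<alphabet '", x$label, "': ", length(x$symbols), " states>\n", sep = "")
  invisible(x)
}

#' Built-in alphabets
#'
#' `nucleotide_alphabet()` is the DNA alphabet A, C, G, T;
#' `amino_acid_alphabet()` the 20 amino acids in the order conventionally
#' used by exchangeability files (A R N D C Q E G H I L K M F P S T W Y V);
#' `codon_alphabet()` the sense codons of a genetic code (61 for the
#' standard code), i.e. stop codons are excluded from the state space.
#'
#' @param code a genetic code as returned by [standard_genetic_code()]:
#'   a named character vector mapping all 64 codons to one-letter amino
#'   acids, with `"*"` for stops.
#' @return a `gs_alphabet`.
#' @seealso [make_alphabet()]
#' @export
nucleotide_alphabet <- function() {
  make_alphabet(c("A", "C", "G", "T"), "nucleotide")
}

#' @rdname nucleotide_alphabet
#' @export
amino_acid_alphabet <- function() {
  make_alphabet(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "amino acid")
}

#' @rdname nucleotide_alphabet
#' @export
codon_alphabet <- function(code = standard_genetic_code()) {
  sense <- names(code)[code != "*"]
  make_alphabet(sense, "codon")
}

#' The standard nuclear genetic code
#'
#' Returns the standard (NCBI translation table 1) genetic code as a named
#' character vector of length 64 mapping codons (written with T, in the
#' conventional TCAG enumeration order) to one-letter amino-acid codes,
#' with `"*"` marking the three stop codons. Alternate codes can be supplied
#' anywhere a `code` argument is accepted, as any complete codon -> amino
#' acid mapping in the same format.
#'
#' @return named character vector of length 64.
#' @export
standard_genetic_code <- function() {
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  aas <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  stats::setNames(aas, codons)
}

# token width of an alphabet (1 for nucleotides/amino acids, 3 for codons)
alphabet_width <- function(alphabet) {
  w <- unique(nchar(alphabet$symbols))
  if (length(w) != 1L) 1L else w
}
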