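#' Peptide alphabet
#'
#' The residue alphabet used throughout the package. The default alphabet is
#' the 20 canonical amino acids plus citrulline, written `Z`. Citrulline is a
#' first-class symbol wherever raw sequences are handled (string kernels,
#' the design walk, Hamming distances); numeric residue encoders decide
#' separately how to treat it, because matrices such as BLOSUM50 and the
#' AAIndex carry no citrulline row.
#'
#' @param symbols Character vector of single uppercase residue letters.
#'   Must be unique.
#' @return An object of class `peptide_alphabet`: the symbol vector with an
#'   `index` attribute mapping symbol to 0-based ordinal.
#' @examples
#' ab <- peptide_alphabet()
#' length(ab)  # 21
#' @export
peptide_alphabet <- function(symbols = c(CANONICAL_AA, "Z")) {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) stop("alphabet symbols must be unique")
  if (!all(nchar(symbols) == 1L & symbols == toupper(symbols))) {
    stop("alphabet symbols must be single uppercase characters")
  }
  idx <- seq_along(symbols) - 1L
  names(idx) <- symbols
  structure(symbols, index = idx, class = "peptide_alphabet")
}

#' The 20 canonical amino acids (one-letter codes)
#' @export
CANONICAL_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @exportS3Method base::print
print.peptide_alphabet <- function(x, ...) {
  cat("peptide_alphabet:", paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}

#' Validate peptide sequences against an alphabet
#'
#' @param sequences Character vector of peptide sequences.
#' @param alphabet A [peptide_alphabet()].
#' @param where Optional labels (e.g. row numbers or ids) used in error
#'   messages.
#' @return Invisibly `TRUE`; errors on the first offending sequence, naming
#'   its position and the illegal symbol.
#' @export
validate_sequences <- function(sequences, alphabet = peptide_alphabet(),
                               where = seq_along(sequences)) {
  chars <- strsplit(sequences, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    bad <- setdiff(chars[[i]], unclass(alphabet))
    if (length(bad)) {
      stop(sprintf("sequence %s contains symbol(s) not in alphabet: %s",
                   as.character(where[i]), paste(bad, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

# Split sequences into a character matrix (rows = peptides); sequences must
# share one length.
seq_char_matrix <- function(sequences) {
  d <- unique(nchar(sequences))
  if (length(d) != 1L) stop("sequences must all have the same length")
  matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
         nrow = length(sequences), ncol = d, byrow = TRUE)
}
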