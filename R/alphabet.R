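#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in the fixed canonical order used by every
#' matrix, file format and scanner in this package.  Columns of all
#' position-by-amino-acid matrices follow this order, as does the header of
#' the Nx20 tab-delimited format.
#'
#' @return Character vector of 20 one-letter amino-acid codes,
#'   `ACDEFGHIKLMNPQRSTVWY`.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Residues tolerated in proteome sequences but never scored; windows
# containing one are skipped by the scanner.
NONSTANDARD_RESIDUES <- c("X", "B", "Z", "U", "O", "J", "*")

#' @noRd
check_aa_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (ncol(x) != 20L)
    stop(what, " must have exactly 20 columns (one per amino acid), got ",
         ncol(x), call. = FALSE)
  if (nrow(x) < 1L)
    stop(what, " must have at least one position (row)", call. = FALSE)
  if (is.null(colnames(x))) {
    colnames(x) <- aa_alphabet()
  } else if (!identical(colnames(x), aa_alphabet())) {
    if (!setequal(colnames(x), aa_alphabet()))
      stop(what, " column names must be the 20 standard amino acids",
           call. = FALSE)
    x <- x[, aa_alphabet(), drop = FALSE]
  }
  x
}
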