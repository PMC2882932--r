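#' Amino-acid substitution models for pseudo-counts
#'
#' Builds the substitution-probability model used by the substitution
#' pseudo-count method.  The model holds a 20 x 20 matrix `q` of
#' substitution probabilities `q[i, a]` (probability mass for amino acid
#' `a` being replaced by `i`) and its row sums `Q[i]`.
#'
#' Two named models are supported:
#' \describe{
#'   \item{`blosum62`}{Joint (target) probabilities recovered from the
#'     BLOSUM62 log-odds scores shipped with \pkg{Biostrings}.  Scores are
#'     half-bit log-odds, so the target frequency is proportional to
#'     `p_i * p_a * 2^(s_ia / 2)`; a uniform background (1/20 per residue)
#'     is used, and the matrix is normalized to total mass 1.  The result
#'     is symmetric and strictly positive.}
#'   \item{`mclachlan`}{The McLachlan chemical-similarity scores are not
#'     redistributable inside this package, so this route requires the
#'     similarity matrix via `similarity`.  Scores are shifted so the
#'     minimum becomes 1 (keeping all entries strictly positive) and each
#'     row is normalized to a probability distribution.}
#' }
#' Any custom 20 x 20 similarity matrix can be supplied the same way.
#'
#' @param name `"blosum62"` or `"mclachlan"`.
#' @param similarity Optional 20 x 20 numeric similarity/score matrix with
#'   amino-acid row and column names; required for `"mclachlan"`, ignored
#'   for `"blosum62"`.
#' @return An object of class `substitution_model` with elements `name`,
#'   `q` (20 x 20 probabilities) and `Q` (length-20 row sums).
#' @export
#' @examples
#' sm <- substitution_model("blosum62")
#' all(sm$q > 0)
#' max(abs(sm$q - t(sm$q)))  # symmetric
substitution_model <- function(name = c("blosum62", "mclachlan"),
                               similarity = NULL) {
  name <- match.arg(name)
  aa <- aa_alphabet()
  if (name == "blosum62") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    s <- e$BLOSUM62[aa, aa]
    q <- exp((log(2) / 2) * s) / 400  # uniform background 1/20 per residue
    q <- q / sum(q)
  } else {
    if (is.null(similarity))
      stop("the 'mclachlan' model requires its similarity matrix via ",
           "'similarity'", call. = FALSE)
    s <- check_aa_similarity(similarity)
    q <- s - min(s) + 1
    q <- q / rowSums(q)
  }
  dimnames(q) <- list(aa, aa)
  structure(list(name = name, q = q, Q = rowSums(q)),
            class = "substitution_model")
}

#' @noRd
check_aa_similarity <- function(s) {
  if (!is.matrix(s) || !is.numeric(s) || any(dim(s) != 20L))
    stop("similarity must be a numeric 20 x 20 matrix", call. = FALSE)
  aa <- aa_alphabet()
  if (!is.null(rownames(s))) {
    if (!setequal(rownames(s), aa) || !setequal(colnames(s), aa))
      stop("similarity dimnames must be the 20 standard amino acids",
           call. = FALSE)
    s <- s[aa, aa]
  } else {
    dimnames(s) <- list(aa, aa)
  }
  s
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("Substitution model:", x$name, "\n")
  cat("  q: 20 x 20, total mass", format(sum(x$q)), "\n")
  invisible(x)
}
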