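#' Position-specific scoring matrices
#'
#' A `scoring_matrix` is the normalized position-specific scoring matrix
#' (PSSM) consumed by the proteome scanner: one row per motif position,
#' one column per amino acid in the canonical order, plus a provenance
#' record describing how it was produced (normalization route,
#' pseudo-count method and its parameters, fixed-position constraints).
#'
#' @param scores Numeric positions x 20 matrix.
#' @param provenance Named list recording the normalization route and its
#'   parameters.
#' @return An object of class `scoring_matrix` with elements `scores`,
#'   `length` and `provenance`.
#' @export
scoring_matrix <- function(scores, provenance = list()) {
  scores <- check_aa_matrix(scores, "scores")
  rownames(scores) <- NULL
  structure(list(scores = scores, length = nrow(scores),
                 provenance = provenance),
            class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("Position-specific scoring matrix:", x$length, "positions\n")
  if (length(x$provenance))
    cat("  route:", paste(names(x$provenance),
                          vapply(x$provenance, function(v)
                            paste(format(unlist(v)), collapse = ","),
                            character(1)),
                          sep = "=", collapse = "; "), "\n")
  print(round(x$scores, 3))
  invisible(x)
}

#' Fixed-position specificity constraint
#'
#' Declares that a motif position accepts only a known subset of amino
#' acids -- e.g. the phospho-acceptor position of a serine/threonine
#' kinase motif, which accepts only S and T.  During signal
#' normalization every other amino acid at that position is scored 0,
#' and each allowed amino acid receives a pseudo-count of 1 at all
#' remaining (non-specific) positions to reflect the slight chance of
#' observing it there.
#'
#' @param position 1-based motif position.
#' @param allowed Character vector of allowed amino acids (a strict,
#'   non-empty subset of the 20-letter alphabet).
#' @return An object of class `fixed_position`.
#' @export
#' @examples
#' fixed_position(3, c("S", "T"))
fixed_position <- function(position, allowed) {
  position <- as.integer(position)
  allowed <- toupper(as.character(allowed))
  if (length(position) != 1L || is.na(position) || position < 1L)
    stop("position must be a single positive integer", call. = FALSE)
  if (length(allowed) == 0L || !all(allowed %in% aa_alphabet()))
    stop("allowed must be a non-empty subset of the amino-acid alphabet",
         call. = FALSE)
  if (length(unique(allowed)) >= 20L)
    stop("allowed must be a strict subset of the alphabet", call. = FALSE)
  structure(list(position = position, allowed = unique(allowed)),
            class = "fixed_position")
}

#' Normalize an experimental signal matrix into a PSSM
#'
#' Converts raw per-position signal intensities (e.g. from a positional
#' peptide-library screen) into normalized scores: each row is rescaled
#' by its total mass and multiplied by the alphabet size m = 20, so
#' `Z[c, a] = 20 * S[c, a] / sum_a' S[c, a']` and every row sums to 20.
#' Negative raw signals (possible in array data) are clipped to 0 first.
#'
#' Fixed-position constraints are applied before normalization: at a
#' fixed position all disallowed amino acids are set to 0 (the allowed
#' ones share the row mass), and each allowed amino acid gains a
#' pseudo-count of 1 on top of its raw signal at every other position.
#'
#' @param raw Numeric positions x 20 matrix of raw signal scores.
#' @param fixed A `fixed_position` object or list of them (optional).
#' @return A [scoring_matrix] whose rows each sum to 20.
#' @export
#' @examples
#' raw <- matrix(0, 1, 20, dimnames = list(NULL, aa_alphabet()))
#' raw[1, c("A", "C")] <- c(3, 1)
#' normalize_signal(raw)$scores[1, c("A", "C")]  # 15, 5
normalize_signal <- function(raw, fixed = list()) {
  raw <- check_aa_matrix(raw, "raw signal")
  if (inherits(fixed, "fixed_position")) fixed <- list(fixed)
  l <- nrow(raw)
  s <- pmax(raw, 0)
  fixed_pos <- integer(0)
  for (fp in fixed) {
    if (!inherits(fp, "fixed_position"))
      stop("fixed must be fixed_position objects", call. = FALSE)
    if (fp$position > l)
      stop("fixed position ", fp$position, " is outside the motif (1..",
           l, ")", call. = FALSE)
    fixed_pos <- c(fixed_pos, fp$position)
    # pseudo-count of 1 for each fixed amino acid at all other positions
    other <- setdiff(seq_len(l), fp$position)
    s[other, fp$allowed] <- s[other, fp$allowed] + 1
  }
  for (fp in fixed) {
    disallowed <- setdiff(aa_alphabet(), fp$allowed)
    s[fp$position, disallowed] <- 0
  }
  row_mass <- rowSums(s)
  if (any(row_mass <= 0))
    stop("position ", paste(which(row_mass <= 0), collapse = ", "),
         " has no positive signal; cannot normalize", call. = FALSE)
  z <- 20 * s / row_mass
  scoring_matrix(z, provenance = list(
    route = "signal", m = 20,
    fixed = if (length(fixed))
      vapply(fixed, function(fp)
        paste0(fp$position, ":", paste(fp$allowed, collapse = "")),
        character(1))
    else character(0)))
}

#' Per-position amino-acid counts from an aligned peptide set
#'
#' Tallies, for each motif position `c`, the occurrences `n[c, a]` of
#' each amino acid, the total count `N[c]` (the number of peptides) and
#' the unique count `R[c]` (number of distinct amino acids observed).
#' These are the raw ingredients of the pseudo-count probability model.
#'
#' @param peptides Character vector of equal-length peptides over the
#'   20-letter alphabet.
#' @return An object of class `peptide_counts`: list with `n`
#'   (positions x 20 count matrix), `N` (per-position totals), `R`
#'   (per-position unique counts) and `length`.
#' @export
#' @examples
#' counts_from_peptides(c("AC", "AD"))$R  # 1 2
counts_from_peptides <- function(peptides) {
  peptides <- toupper(as.character(peptides))
  if (length(peptides) == 0L)
    stop("peptide set is empty", call. = FALSE)
  l <- unique(nchar(peptides))
  if (length(l) != 1L)
    stop("peptides must all have the same length; found lengths ",
         paste(sort(l), collapse = ", "), call. = FALSE)
  if (l < 1L) stop("peptides must be non-empty", call. = FALSE)
  aa <- aa_alphabet()
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE)),
                  nrow = length(peptides), byrow = TRUE)
  bad <- which(!(chars %in% aa))
  if (length(bad) > 0L) {
    rc <- arrayInd(bad[1], dim(chars))
    i <- rc[1, 1]; j <- rc[1, 2]
    stop("illegal character '", chars[i, j], "' in peptide '",
         peptides[i], "' at offset ", j, call. = FALSE)
  }
  n <- t(apply(chars, 2, function(col) table(factor(col, levels = aa))))
  colnames(n) <- aa
  rownames(n) <- NULL
  structure(list(n = n, N = rowSums(n), R = rowSums(n > 0), length = l),
            class = "peptide_counts")
}

#' Pseudo-count-corrected position probabilities
#'
#' Converts per-position counts into probabilities
#' `p[c, a] = (n[c, a] + b[c, a]) / (N[c] + B[c])`, where `b` and `B` are
#' per-cell and per-position pseudo-counts.  Pseudo-counts compensate for
#' the severe undersampling of sequence space by selection experiments
#' such as phage display, which otherwise zeroes out rare residues.
#'
#' Three pseudo-count methods are available:
#' \describe{
#'   \item{`substitution`}{`B[c] = psi * R[c]` with `R[c]` the unique
#'     amino-acid count at position `c`, distributed across amino acids
#'     by substitution probability weighted by the observed frequencies:
#'     `b[c, a] = B[c] * sum_i (n[c, i] / N[c]) * (q[i, a] / Q[i])`
#'     (Henikoff-style position-based pseudo-counts).}
#'   \item{`flat`}{Adds 1 to every cell: `b[c, a] = 1`, `B[c] = 20`.}
#'   \item{`entropy`}{A pseudo-count proportional to the positional
#'     Shannon entropy, `B[c] = psi * R[c] * H[c] / log2(20)`, spread
#'     equally over the 20 amino acids.  Fully conserved positions
#'     (entropy 0) receive essentially no pseudo-count.}
#' }
#'
#' @param counts A `peptide_counts` object from [counts_from_peptides()].
#' @param method Pseudo-count method, one of `"substitution"`, `"flat"`,
#'   `"entropy"`.
#' @param subst A [substitution_model()]; required for
#'   `method = "substitution"`.
#' @param psi Positive pseudo-count weight (default 5).
#' @return A [scoring_matrix] in probability mode: every row sums to 1.
#' @export
#' @examples
#' cts <- counts_from_peptides(c("AA", "AC"))
#' p <- pseudocount_probabilities(cts, method = "flat")
#' rowSums(p$scores)  # 1 1
pseudocount_probabilities <- function(counts,
                                      method = c("substitution", "flat",
                                                 "entropy"),
                                      subst = NULL, psi = 5) {
  method <- match.arg(method)
  if (!inherits(counts, "peptide_counts"))
    stop("counts must come from counts_from_peptides()", call. = FALSE)
  if (psi <= 0) stop("psi must be positive", call. = FALSE)
  n <- counts$n; N <- counts$N; R <- counts$R
  if (any(N == 0))
    stop("position ", paste(which(N == 0), collapse = ", "),
         " has zero total count", call. = FALSE)
  l <- counts$length
  if (method == "substitution") {
    if (!inherits(subst, "substitution_model"))
      stop("method 'substitution' requires a substitution_model",
           call. = FALSE)
    B <- psi * R
    # qnorm[i, a] = q[i, a] / Q[i]; b[c, a] = B_c * sum_i f[c, i] * qnorm[i, a]
    qn <- subst$q / subst$Q
    f <- n / N
    b <- (f %*% qn) * B
  } else if (method == "flat") {
    b <- matrix(1, l, 20)
    B <- rep(20, l)
  } else {
    f <- n / N
    H <- apply(f, 1, function(p) {
      p <- p[p > 0]
      -sum(p * log2(p))
    })
    B <- psi * R * H / log2(20)
    b <- matrix(B / 20, l, 20)
  }
  p <- (n + b) / (N + B)
  colnames(p) <- aa_alphabet()
  scoring_matrix(p, provenance = list(
    route = "peptides", mode = "probability", pseudocount = method,
    psi = psi,
    substitution = if (!is.null(subst)) subst$name else NA_character_))
}

#' Rescale position probabilities into scanner scores
#'
#' Makes the peptide-derived probability matrix commensurate with the
#' signal-normalization route: `mode = "scaled"` multiplies every
#' probability by 20 so each row sums to 20 (the scale produced by
#' [normalize_signal()]); `mode = "probability"` leaves the matrix
#' unchanged.  The mode is recorded in provenance.
#'
#' @param p A [scoring_matrix] whose rows sum to 1.
#' @param mode `"scaled"` or `"probability"`.
#' @return A [scoring_matrix].
#' @export
probabilities_to_scores <- function(p, mode = c("scaled", "probability")) {
  mode <- match.arg(mode)
  if (!inherits(p, "scoring_matrix"))
    stop("p must be a scoring_matrix", call. = FALSE)
  rs <- rowSums(p$scores)
  if (any(abs(rs - 1) > 1e-6))
    stop("rows of p must sum to 1 (found ",
         paste(format(rs[abs(rs - 1) > 1e-6]), collapse = ", "),
         "); not a probability matrix", call. = FALSE)
  out <- p
  if (mode == "scaled") out$scores <- p$scores * 20
  out$provenance$mode <- mode
  out
}
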