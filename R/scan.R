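#' Score a single window against a scoring matrix
#'
#' The raw score of an l-mer window is the sum over positions of the
#' matrix entry for the residue observed there:
#' `sum_c S[c, window[c]]`.  Windows containing residues outside the
#' 20-letter alphabet are unscorable and return `NA` (the scanner skips
#' them rather than fabricating a 0).
#'
#' @param window An l-character amino-acid string.
#' @param matrix A [scoring_matrix] of the same length.
#' @return The raw window score, or `NA_real_` if the window contains a
#'   non-standard residue.
#' @export
window_score <- function(window, matrix) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (length(chars) != matrix$length)
    stop("window length ", length(chars), " does not match motif length ",
         matrix$length, call. = FALSE)
  idx <- match(chars, aa_alphabet())
  if (anyNA(idx)) return(NA_real_)
  sum(matrix$scores[cbind(seq_len(matrix$length), idx)])
}

#' Optimal motif score
#'
#' The score of the best possible window: the sum of per-position column
#' maxima of the scoring matrix.  Every real window scores at most this.
#'
#' @param matrix A [scoring_matrix].
#' @return The optimal raw score.
#' @export
optimal_score <- function(matrix) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  sum(apply(matrix$scores, 1, max))
}

#' Normalized window score
#'
#' Rescales a raw window score onto \[0, 1\] by the optimal motif score:
#' `E = raw / optimal`.  `E = 1` exactly when the window carries the
#' per-position optimum at every position.
#'
#' @param raw Raw window score(s).
#' @param optimal The [optimal_score()] of the matrix.
#' @return Normalized score(s) E in \[0, 1\].
#' @export
normalized_score <- function(raw, optimal) {
  if (length(optimal) != 1L || is.na(optimal) || optimal <= 0)
    stop("optimal score must be a single positive number", call. = FALSE)
  raw / optimal
}

#' Scan a proteome with a scoring matrix
#'
#' Slides an l-residue window along every protein one residue at a time,
#' scores each window, and retains a bounded list of the
#' highest-scoring hits.  After each protein the accumulating list is
#' trimmed to `capacity`, so memory stays bounded on large proteomes; the
#' retained set is identical to taking the top-`capacity` windows of an
#' exhaustive scan.  Equal scores at the capacity boundary are resolved
#' in scan order (protein input order, then ascending start), making the
#' result deterministic for a fixed input ordering.
#'
#' Windows overlapping non-standard residues (X, B, Z, U, O, J, *) are
#' skipped.  Proteins shorter than the motif yield no hits and a
#' warning.
#'
#' @param proteome Named character vector of protein sequences (see
#'   [read_proteome()]).
#' @param matrix A [scoring_matrix].
#' @param capacity Maximum number of retained hits (default 2000); use
#'   `Inf` for an unbounded, exhaustive hit list.
#' @return A data frame of class `hit_list` with columns `protein_id`,
#'   `start` (1-based inclusive), `window`, `raw_score`, `norm_score`,
#'   sorted by descending `norm_score`; attributes `capacity` and
#'   `motif_length`.
#' @export
scan_proteome <- function(proteome, matrix, capacity = 2000) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  if (length(proteome) == 0L) stop("proteome is empty", call. = FALSE)
  if (is.null(names(proteome)) || any(!nzchar(names(proteome))))
    stop("proteome sequences must be named by protein id", call. = FALSE)
  if (!(is.infinite(capacity) || capacity >= 1))
    stop("capacity must be >= 1", call. = FALSE)
  l <- matrix$length
  S <- matrix$scores
  opt <- optimal_score(matrix)
  short <- names(proteome)[nchar(proteome) < l]
  if (length(short))
    warning("protein(s) shorter than the motif skipped: ",
            paste(short, collapse = ", "), call. = FALSE)

  hits <- NULL
  scanned <- 0L  # running scorable-window count: the scan-order tie key
  for (id in names(proteome)) {
    n <- nchar(proteome[[id]])
    if (n < l) next
    codes <- match(strsplit(proteome[[id]], "", fixed = TRUE)[[1]],
                   aa_alphabet())
    nwin <- n - l + 1L
    raw <- numeric(nwin)
    ok <- rep(TRUE, nwin)
    for (c in seq_len(l)) {
      idx <- codes[c:(c + nwin - 1L)]
      ok <- ok & !is.na(idx)
      v <- S[c, idx]
      v[is.na(idx)] <- 0
      raw <- raw + v
    }
    if (!any(ok)) next
    starts <- which(ok)
    ph <- data.frame(
      protein_id = id,
      start = starts,
      window = substring(proteome[[id]], starts, starts + l - 1L),
      raw_score = raw[ok],
      .order = scanned + seq_along(starts),
      stringsAsFactors = FALSE)
    scanned <- scanned + length(starts)
    hits <- if (is.null(hits)) ph else rbind(hits, ph)
    if (is.finite(capacity) && nrow(hits) > capacity) {
      keep <- order(-hits$raw_score, hits$.order)[seq_len(capacity)]
      hits <- hits[sort(keep), , drop = FALSE]
    }
  }
  if (is.null(hits))
    hits <- data.frame(protein_id = character(0), start = integer(0),
                       window = character(0), raw_score = numeric(0),
                       .order = integer(0), stringsAsFactors = FALSE)
  hits$norm_score <- if (nrow(hits)) normalized_score(hits$raw_score, opt)
                     else numeric(0)
  hits <- hits[order(-hits$norm_score, hits$.order), , drop = FALSE]
  if (is.finite(capacity) && nrow(hits) > capacity)
    hits <- hits[seq_len(capacity), , drop = FALSE]
  hits$.order <- NULL
  rownames(hits) <- NULL
  attr(hits, "capacity") <- capacity
  attr(hits, "motif_length") <- l
  class(hits) <- c("hit_list", "data.frame")
  hits
}
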