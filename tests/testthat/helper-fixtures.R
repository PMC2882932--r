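# Shared fixture builders and independent oracles.

aa <- aa_alphabet()

# l x 20 raw matrix with named nonzero cells, e.g. toy_raw(list(c(A = 3, C = 1)))
toy_raw <- function(rows) {
  m <- matrix(0, length(rows), 20, dimnames = list(NULL, aa))
  for (i in seq_along(rows)) m[i, names(rows[[i]])] <- rows[[i]]
  m
}

# the worked 2-position matrix: S1 = S2 = {A: 15, C: 5}
toy_matrix_2pos <- function() {
  scoring_matrix(toy_raw(list(c(A = 15, C = 5), c(A = 15, C = 5))))
}

rand_scoring_matrix <- function(l, seed) {
  set.seed(seed)
  scoring_matrix(matrix(stats::runif(l * 20), l, 20,
                        dimnames = list(NULL, aa)))
}

rand_proteome <- function(n, len, seed) {
  set.seed(seed)
  stats::setNames(
    vapply(seq_len(n), function(i)
      paste(sample(aa, len, replace = TRUE), collapse = ""),
      character(1)),
    sprintf("P%03d", seq_len(n)))
}

# Exhaustive scan oracle: every window of every protein scored with an
# explicit double loop, independent of scan_proteome() internals.
brute_scan <- function(proteome, matrix) {
  l <- matrix$length
  out <- NULL
  for (id in names(proteome)) {
    s <- proteome[[id]]
    if (nchar(s) < l) next
    for (start in seq_len(nchar(s) - l + 1)) {
      w <- substr(s, start, start + l - 1)
      raw <- 0
      ok <- TRUE
      for (c in seq_len(l)) {
        j <- match(substr(w, c, c), aa)
        if (is.na(j)) { ok <- FALSE; break }
        raw <- raw + matrix$scores[c, j]
      }
      if (ok)
        out <- rbind(out, data.frame(protein_id = id, start = start,
                                     window = w, raw_score = raw))
    }
  }
  out$norm_score <- out$raw_score / optimal_score(matrix)
  out
}

# Rank-based AUC oracle: Mann-Whitney U / (n_pos * n_neg) with midpoint
# tie handling via rank().
mw_auc <- function(scores, labels) {
  r <- rank(scores)
  np <- sum(labels); nn <- sum(!labels)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

toy_dir <- function() system.file("extdata", "toy", package = "slimscan")

toy_config <- function(out_prefix = NULL, threshold = 0.5) {
  d <- toy_dir()
  pipeline_config(
    motif = file.path(d, "motif.nx20"), motif_format = "nx20",
    proteome = file.path(d, "proteome.fasta"),
    tracks = list(conservation = file.path(d, "conservation.tsv"),
                  accessibility = file.path(d, "accessibility.tsv"),
                  disorder = file.path(d, "disorder.tsv")),
    training = file.path(d, "training.tsv"),
    threshold = threshold, seed = 1, out_prefix = out_prefix)
}
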