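#' Read and write the Nx20 matrix format
#'
#' The Nx20 format is a tab-delimited table describing a motif: the first
#' row holds the 20 one-letter amino-acid labels in canonical order
#' (`ACDEFGHIKLMNPQRSTVWY`), and each subsequent row holds the raw signal
#' or score values for one motif position (positions 1..l, top to
#' bottom).  Writing uses full `%.17g` precision so a read -> write ->
#' read cycle is bit-exact.
#'
#' @param path File path.
#' @return `read_nx20()` returns a positions x 20 numeric matrix with
#'   amino-acid column names; `write_nx20()` returns `path` invisibly.
#' @export
read_nx20 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("Nx20 file must have a header and at least one position row",
         call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) != 20L || !setequal(header, aa_alphabet()))
    stop("Nx20 header must list the 20 amino-acid one-letter codes",
         call. = FALSE)
  vals <- lapply(lines[-1], function(ln) {
    v <- as.numeric(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (length(v) != 20L || anyNA(v))
      stop("malformed Nx20 row: '", ln, "'", call. = FALSE)
    v
  })
  m <- do.call(rbind, vals)
  colnames(m) <- header
  check_aa_matrix(m, "Nx20 matrix")
}

#' @rdname read_nx20
#' @param x Positions x 20 numeric matrix (or a [scoring_matrix], whose
#'   `scores` are written).
#' @export
write_nx20 <- function(x, path) {
  if (inherits(x, "scoring_matrix")) x <- x$scores
  x <- check_aa_matrix(x, "Nx20 matrix")
  rows <- apply(x, 1, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(c(paste(aa_alphabet(), collapse = "\t"), rows), path)
  invisible(path)
}

#' Read an aligned peptide set
#'
#' Accepts either FASTA or plain text with one peptide per line
#' (auto-detected from the leading `>`).  All peptides must have equal
#' length; validation of the alphabet happens in
#' [counts_from_peptides()].
#'
#' @param path File path.
#' @return Character vector of peptides.
#' @export
read_peptides <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no peptides in ", path, call. = FALSE)
  if (startsWith(lines[1], ">")) {
    seqs <- Biostrings::readAAStringSet(path)
    peps <- as.character(seqs)
    names(peps) <- NULL
  } else {
    peps <- trimws(lines)
  }
  peps
}

#' Read a target proteome from FASTA
#'
#' Record identifiers are the first whitespace-delimited token of each
#' FASTA header.  Sequences are uppercased; non-standard residues
#' (X, B, Z, U, O, J, *) are permitted and later skipped by the scanner.
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences.
#' @export
read_proteome <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("proteome FASTA is empty", call. = FALSE)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate protein ids in proteome: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  out <- toupper(as.character(seqs))
  names(out) <- ids
  out
}

#' Read and write per-residue feature tracks
#'
#' Tracks carry one pre-computed scalar per residue per protein --
#' conservation (higher = more conserved; unbounded, alignment-entropy
#' convention), solvent accessibility in \[0, 1\], or disorder
#' probability in \[0, 1\].  The file format is tab-delimited with a
#' header and three columns: `protein_id`, `residue_index` (1-based),
#' `value`; one file per feature kind.  Writing uses `%.17g` precision
#' so round-trips are bit-exact.
#'
#' @param path File path.
#' @param kind Track kind: `"conservation"`, `"accessibility"` or
#'   `"disorder"` (recorded as an attribute, used in error messages).
#' @return `read_track()` returns a named list of numeric per-residue
#'   vectors, one per protein, with attribute `kind`.
#' @export
read_track <- function(path, kind = c("conservation", "accessibility",
                                      "disorder")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE,
                          colClasses = c("character", "integer", "numeric"))
  if (!identical(names(df), c("protein_id", "residue_index", "value")))
    stop("track file must have columns protein_id, residue_index, value",
         call. = FALSE)
  track <- lapply(split(df, df$protein_id), function(d) {
    v <- numeric(max(d$residue_index))
    v[d$residue_index] <- d$value
    v
  })
  attr(track, "kind") <- kind
  track
}

#' @rdname read_track
#' @param track Named list of numeric per-residue vectors.
#' @export
write_track <- function(track, path) {
  header <- "protein_id\tresidue_index\tvalue"
  body <- unlist(lapply(names(track), function(id) {
    v <- track[[id]]
    paste(id, seq_along(v), sprintf("%.17g", v), sep = "\t")
  }), use.names = FALSE)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gold-standard training set
#'
#' Tab-delimited, two columns without header: a gene/protein identifier
#' and a logical interaction label (`true/false`, `1/0` or `yes/no`,
#' case-insensitive).  Positives are experimentally validated
#' interaction or phosphorylation targets; negatives are protein pairs
#' constrained to distinct subcellular compartments.
#'
#' @param path File path.
#' @return Data frame with columns `gene` (character) and `label`
#'   (logical).
#' @export
read_training_set <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          colClasses = c("character", "character"))
  if (ncol(df) < 2L)
    stop("training set must have two tab-delimited columns: gene, label",
         call. = FALSE)
  raw <- tolower(trimws(df[[2]]))
  label <- rep(NA, length(raw))
  label[raw %in% c("true", "1", "yes")] <- TRUE
  label[raw %in% c("false", "0", "no")] <- FALSE
  if (anyNA(label))
    stop("unrecognized label(s): ",
         paste(unique(df[[2]][is.na(label)]), collapse = ", "),
         " (expected true/false, 1/0 or yes/no)", call. = FALSE)
  data.frame(gene = trimws(df[[1]]), label = label,
             stringsAsFactors = FALSE)
}

# Deterministic number formatting for tabular outputs (platform-stable).
fmt_num <- function(x) sprintf("%.10g", x)

#' Write a tab-delimited hit table
#'
#' Serializes a hit data frame (scanner output, annotated or classified)
#' with a header row; numeric columns are formatted with 10 significant
#' digits for platform-stable, reproducible bytes.
#'
#' @param hits Data frame of hits.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  df <- as.data.frame(hits)
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- fmt_num(df[[j]])
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}
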