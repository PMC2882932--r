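#' Bundle per-residue feature tracks into a store
#'
#' Collects the three per-residue annotation tracks the classifier
#' integrates with the motif score: evolutionary conservation, solvent
#' accessibility and intrinsic disorder.  Each track is a named list of
#' numeric vectors (one value per residue per protein), as returned by
#' [read_track()].
#'
#' @param conservation,accessibility,disorder Named lists of per-residue
#'   numeric vectors.
#' @return An object of class `feature_store`.
#' @export
feature_store <- function(conservation, accessibility, disorder) {
  structure(list(conservation = conservation,
                 accessibility = accessibility,
                 disorder = disorder),
            class = "feature_store")
}

TRACK_KINDS <- c("conservation", "accessibility", "disorder")

#' Annotate motif hits with window-averaged feature values
#'
#' For each hit, every track value is summarized over the window span
#' `[start, start + l - 1]` -- by default the arithmetic mean, which is
#' invariant to motif length; `min` and `max` are available as
#' alternatives.  The number of retained hits on each protein
#' (`hits_per_protein`) is stamped on as a fifth feature alongside the
#' motif score.
#'
#' Proteins absent from a track are handled per `missing`: `"flag"`
#' leaves `NA` in place, `"drop"` removes those hits, `"impute"`
#' substitutes the proteome-wide mean of that track.
#'
#' @param hits A `hit_list` from [scan_proteome()].
#' @param tracks A [feature_store()].
#' @param stat Window summary statistic: `"mean"` (default), `"min"` or
#'   `"max"`.
#' @param missing Policy for proteins without a track: `"flag"`,
#'   `"drop"` or `"impute"`.
#' @return The hit data frame with added columns `conservation`,
#'   `accessibility`, `disorder` and `hits_per_protein`.
#' @export
annotate_hits <- function(hits, tracks,
                          stat = c("mean", "min", "max"),
                          missing = c("flag", "drop", "impute")) {
  stat <- match.arg(stat)
  missing <- match.arg(missing)
  stopifnot(inherits(tracks, "feature_store"))
  fun <- switch(stat, mean = mean, min = min, max = max)
  l <- attr(hits, "motif_length")
  if (is.null(l)) l <- unique(nchar(hits$window))
  out <- as.data.frame(hits)
  for (kind in TRACK_KINDS) {
    track <- tracks[[kind]]
    vals <- rep(NA_real_, nrow(out))
    for (i in seq_len(nrow(out))) {
      tv <- track[[out$protein_id[i]]]
      if (is.null(tv)) next
      end <- out$start[i] + l - 1L
      if (length(tv) < end)
        stop(kind, " track for protein '", out$protein_id[i],
             "' is shorter than the protein (", length(tv),
             " < ", end, ")", call. = FALSE)
      vals[i] <- fun(tv[out$start[i]:end])
    }
    if (missing == "impute" && anyNA(vals)) {
      m <- mean(unlist(track, use.names = FALSE))
      vals[is.na(vals)] <- m
    }
    out[[kind]] <- vals
  }
  if (missing == "drop")
    out <- out[stats::complete.cases(out[TRACK_KINDS]), , drop = FALSE]
  counts <- hits_per_protein(out)
  out$hits_per_protein <- as.integer(counts[out$protein_id])
  rownames(out) <- NULL
  attr(out, "motif_length") <- l
  out
}

#' Count retained hits per protein
#'
#' Hit density is itself informative: true targets often carry several
#' motif matches.  Counts are taken over the retained (post-capacity)
#' hit list, so every hit of the same protein carries the same count.
#'
#' @param hits A hit data frame.
#' @return Named integer vector, protein id to hit count.
#' @export
hits_per_protein <- function(hits) {
  if (nrow(hits) == 0L) return(integer(0))
  tab <- table(hits$protein_id)
  stats::setNames(as.integer(tab), names(tab))
}

# Feature columns consumed by the classifier, in canonical order.
# motif_score is the normalized scan score E.
FEATURE_COLS <- c("motif_score", "conservation", "accessibility",
                  "disorder", "hits_per_protein")

#' Extract the classifier feature matrix from annotated hits
#'
#' Assembles the five integrated features -- motif scanning score (E),
#' conservation, accessibility, disorder and hits-per-protein -- as a
#' numeric matrix, one row per hit.
#'
#' @param hits Annotated hit data frame from [annotate_hits()].
#' @return Numeric matrix with columns
#'   `motif_score, conservation, accessibility, disorder,
#'   hits_per_protein`.
#' @export
feature_matrix <- function(hits) {
  need <- c("norm_score", TRACK_KINDS, "hits_per_protein")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hits are missing annotation column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  m <- cbind(motif_score = hits$norm_score,
             conservation = hits$conservation,
             accessibility = hits$accessibility,
             disorder = hits$disorder,
             hits_per_protein = as.numeric(hits$hits_per_protein))
  m
}
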