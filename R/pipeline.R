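#' Pipeline configuration
#'
#' Collects every knob of the end-to-end prediction run.  Defaults
#' follow the method's reference settings: pseudo-count weight `psi = 5`,
#' a 2000-hit bounded scan list, and a posterior (likelihood) threshold
#' of 0.9 for reporting a protein as a predicted target.
#'
#' @param motif Path to the motif input.
#' @param motif_format `"nx20"` (raw signal matrix, normalized via
#'   [normalize_signal()]), or `"peptides"`/`"fasta"` (aligned peptide
#'   set, converted via pseudo-count probabilities and scaled).
#' @param proteome Path to the target proteome FASTA.
#' @param tracks Named list or vector with paths for `conservation`,
#'   `accessibility` and `disorder` track files.
#' @param training Path to the gold-standard training TSV, or `NULL`
#'   when `model` is supplied.
#' @param model Optional pre-trained `nb_model` (skips training).
#' @param fixed List of [fixed_position()] constraints (signal route).
#' @param pseudocount Pseudo-count method for the peptide route.
#' @param subst_matrix Substitution model name for
#'   `pseudocount = "substitution"`.
#' @param subst_similarity Optional 20 x 20 similarity matrix (required
#'   for `subst_matrix = "mclachlan"`).
#' @param psi Pseudo-count weight (default 5).
#' @param capacity Scan hit-list capacity (default 2000).
#' @param threshold Posterior threshold for the consolidated target
#'   list (default 0.9).
#' @param use_pca,n_components PCA preprocessing for the classifier.
#' @param missing Missing-track policy (see [annotate_hits()]).
#' @param seed Integer seed (cross-validation, any randomized step).
#' @param out_prefix Output path prefix; the run writes
#'   `<prefix>_report.tsv`, `<prefix>_consolidated.tsv` and
#'   `<prefix>_manifest.txt`.  `NULL` disables file output.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(motif,
                            motif_format = c("nx20", "peptides", "fasta"),
                            proteome,
                            tracks,
                            training = NULL,
                            model = NULL,
                            fixed = list(),
                            pseudocount = c("substitution", "flat",
                                            "entropy"),
                            subst_matrix = c("blosum62", "mclachlan"),
                            subst_similarity = NULL,
                            psi = 5,
                            capacity = 2000,
                            threshold = 0.9,
                            use_pca = FALSE,
                            n_components = 3,
                            missing = c("impute", "flag", "drop"),
                            seed = 1,
                            out_prefix = NULL) {
  motif_format <- match.arg(motif_format)
  pseudocount <- match.arg(pseudocount)
  subst_matrix <- match.arg(subst_matrix)
  missing <- match.arg(missing)
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  if (is.null(training) && is.null(model))
    stop("either a training set or a pre-trained model is required",
         call. = FALSE)
  structure(list(motif = motif, motif_format = motif_format,
                 proteome = proteome, tracks = as.list(tracks),
                 training = training, model = model, fixed = fixed,
                 pseudocount = pseudocount, subst_matrix = subst_matrix,
                 subst_similarity = subst_similarity, psi = psi,
                 capacity = capacity, threshold = threshold,
                 use_pca = use_pca, n_components = n_components,
                 missing = missing, seed = as.integer(seed),
                 out_prefix = out_prefix),
            class = "pipeline_config")
}

# Re-raise any stage failure with the stage name attached.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Build the scoring matrix a config describes
#'
#' Signal route (`nx20`): clip, apply fixed-position constraints,
#' row-normalize to mass 20.  Peptide route (`peptides`/`fasta`):
#' per-position counts, pseudo-count probabilities, scaled by 20 to the
#' signal-route scale.
#'
#' @param config A [pipeline_config()].
#' @return A [scoring_matrix].
#' @export
build_matrix <- function(config) {
  if (config$motif_format == "nx20") {
    raw <- read_nx20(config$motif)
    return(normalize_signal(raw, fixed = config$fixed))
  }
  peps <- read_peptides(config$motif)
  counts <- counts_from_peptides(peps)
  subst <- NULL
  if (config$pseudocount == "substitution")
    subst <- substitution_model(config$subst_matrix,
                                similarity = config$subst_similarity)
  p <- pseudocount_probabilities(counts, method = config$pseudocount,
                                 subst = subst, psi = config$psi)
  probabilities_to_scores(p, mode = "scaled")
}

#' Assemble the training design from annotated hits
#'
#' Each labeled gold-standard protein is represented by one feature row:
#' that of its top-scoring hit (highest normalized motif score, ties by
#' lower start).  Labeled proteins without any scorable hit in the
#' retained list are skipped with a warning.
#'
#' @param annotated Annotated hit data frame from [annotate_hits()].
#' @param training Data frame from [read_training_set()].
#' @return List with `x` (feature matrix, see [feature_matrix()]) and
#'   `y` (logical labels).
#' @export
training_features <- function(annotated, training) {
  ord <- order(annotated$protein_id, -annotated$norm_score,
               annotated$start)
  best <- annotated[ord, , drop = FALSE]
  best <- best[!duplicated(best$protein_id), , drop = FALSE]
  rows <- match(training$gene, best$protein_id)
  found <- !is.na(rows)
  if (!all(found))
    warning("training protein(s) without scorable hits skipped: ",
            paste(training$gene[!found], collapse = ", "), call. = FALSE)
  list(x = feature_matrix(best[rows[found], , drop = FALSE]),
       y = training$label[found])
}

#' Consolidate classified hits into unique protein targets
#'
#' Hits on the same protein are collapsed to one representative: the
#' hit with the highest posterior, ties broken by higher normalized
#' motif score, then by lower start coordinate.  The number of
#' supporting hits on the protein is retained.
#'
#' @param hits Data frame of annotated hits with a `posterior` column.
#' @return Data frame with one row per protein, sorted by descending
#'   posterior, with `supporting_hits` appended.
#' @export
consolidate <- function(hits) {
  if (nrow(hits) == 0L) {
    out <- hits
    out$supporting_hits <- integer(0)
    return(out)
  }
  counts <- hits_per_protein(hits)
  ord <- order(hits$protein_id, -hits$posterior, -hits$norm_score,
               hits$start)
  best <- hits[ord, , drop = FALSE]
  best <- best[!duplicated(best$protein_id), , drop = FALSE]
  best$supporting_hits <- as.integer(counts[best$protein_id])
  best <- best[order(-best$posterior, -best$norm_score, best$start,
                     best$protein_id), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Run the end-to-end target-prediction pipeline
#'
#' Executes the stages in order: motif conversion and normalization,
#' proteome scanning with a bounded hit list, feature annotation,
#' naive Bayes training (unless a model is supplied) and posterior
#' scoring, sorting, and consolidation to unique proteins.  The
#' consolidated list keeps only proteins whose representative hit has
#' posterior >= `threshold`; the full per-window report keeps
#' everything.  Given identical inputs and seed the run is
#' bit-reproducible, and a manifest of all parameters plus input MD5
#' checksums is produced.
#'
#' @param config A [pipeline_config()].
#' @return List with `consolidated` (thresholded unique-protein
#'   ranking), `report` (all classified hits), `matrix`, `model`,
#'   `manifest`, and `paths` of any files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  matrix <- with_stage("normalize", build_matrix(config))
  proteome <- with_stage("read-proteome", read_proteome(config$proteome))
  hits <- with_stage("scan",
                     scan_proteome(proteome, matrix,
                                   capacity = config$capacity))
  tracks <- with_stage("read-tracks", feature_store(
    read_track(config$tracks$conservation, "conservation"),
    read_track(config$tracks$accessibility, "accessibility"),
    read_track(config$tracks$disorder, "disorder")))
  annotated <- with_stage("feature-score",
                          annotate_hits(hits, tracks,
                                        missing = config$missing))
  model <- config$model
  if (is.null(model)) {
    training <- with_stage("read-training",
                           read_training_set(config$training))
    tf <- with_stage("train", training_features(annotated, training))
    model <- with_stage("train",
                        nb_train(tf$x, tf$y, use_pca = config$use_pca,
                                 n_components = config$n_components))
  }
  annotated$posterior <- with_stage("integrate",
                                    predict(model,
                                            feature_matrix(annotated)))
  report <- annotated[order(-annotated$posterior, -annotated$norm_score,
                            annotated$start, annotated$protein_id), ,
                      drop = FALSE]
  rownames(report) <- NULL
  cons <- with_stage("consolidate", consolidate(report))
  cons <- cons[cons$posterior >= config$threshold, , drop = FALSE]
  rownames(cons) <- NULL

  manifest <- run_manifest(config)
  paths <- list()
  if (!is.null(config$out_prefix)) {
    paths$report <- paste0(config$out_prefix, "_report.tsv")
    paths$consolidated <- paste0(config$out_prefix, "_consolidated.tsv")
    paths$manifest <- paste0(config$out_prefix, "_manifest.txt")
    write_hits(report, paths$report)
    write_hits(cons, paths$consolidated)
    writeLines(manifest, paths$manifest)
  }
  list(consolidated = cons, report = report, matrix = matrix,
       model = model, manifest = manifest, paths = paths)
}

# Parameters plus input checksums, for provenance of a run.
run_manifest <- function(config) {
  inputs <- c(motif = config$motif, proteome = config$proteome,
              unlist(config$tracks),
              if (!is.null(config$training)) c(training = config$training))
  sums <- vapply(inputs, function(p)
    unname(tools::md5sum(p)), character(1))
  scalars <- c(motif_format = config$motif_format,
               pseudocount = config$pseudocount,
               subst_matrix = config$subst_matrix,
               psi = config$psi, capacity = config$capacity,
               threshold = config$threshold, use_pca = config$use_pca,
               n_components = config$n_components,
               missing = config$missing, seed = config$seed)
  c("# run manifest",
    paste0(names(scalars), "=", unname(scalars)),
    paste0("md5:", names(sums), "=", basename(inputs), ":", unname(sums)))
}

# "3:ST,7:K" -> list of fixed_position constraints
parse_fixed <- function(s) {
  if (is.null(s) || !nzchar(trimws(s))) return(list())
  lapply(strsplit(trimws(s), ",", fixed = TRUE)[[1]], function(part) {
    bits <- strsplit(trimws(part), ":", fixed = TRUE)[[1]]
    if (length(bits) != 2L)
      stop("fixed spec must look like '3:ST'", call. = FALSE)
    fixed_position(as.integer(bits[1]),
                   strsplit(bits[2], "", fixed = TRUE)[[1]])
  })
}

#' Read a flat key-value pipeline configuration file
#'
#' One `key = value` pair per line; `#` starts a comment.  Keys mirror
#' the arguments of [pipeline_config()]; track paths use the keys
#' `conservation`, `accessibility` and `disorder`.  Values supplied in
#' `override` (e.g. parsed command-line flags) replace file values.
#'
#' @param path Config file path.
#' @param override Named list of overriding values.
#' @return A [pipeline_config()].
#' @export
read_config_file <- function(path, override = list()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, function(p)
    paste(p[-1], collapse = "=")), vapply(kv, `[`, character(1), 1L))
  vals[names(override)] <- override
  num <- function(k, d) if (is.null(vals[[k]])) d else
    as.numeric(vals[[k]])
  chr <- function(k, d = NULL) if (is.null(vals[[k]])) d else vals[[k]]
  lgl <- function(k, d) if (is.null(vals[[k]])) d else
    tolower(vals[[k]]) %in% c("true", "1", "yes")
  pipeline_config(
    motif = chr("motif"),
    motif_format = chr("motif_format", "nx20"),
    proteome = chr("proteome"),
    tracks = list(conservation = chr("conservation"),
                  accessibility = chr("accessibility"),
                  disorder = chr("disorder")),
    training = chr("training"),
    fixed = parse_fixed(chr("fixed", "")),
    pseudocount = chr("pseudocount", "substitution"),
    subst_matrix = chr("subst_matrix", "blosum62"),
    psi = num("psi", 5),
    capacity = num("capacity", 2000),
    threshold = num("threshold", 0.9),
    use_pca = lgl("use_pca", FALSE),
    n_components = num("n_components", 3),
    missing = chr("missing", "impute"),
    seed = num("seed", 1),
    out_prefix = chr("out_prefix"))
}
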