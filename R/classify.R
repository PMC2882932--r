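#' Train the naive Bayes feature integrator
#'
#' Fits a two-class naive Bayes model with Gaussian class-conditional
#' densities on continuous features.  Class priors are the training
#' class frequencies; each feature gets a per-class mean and variance,
#' floored at `1e-9 * range(feature)^2` so constant features cannot
#' produce infinite likelihood ratios.  With `use_pca = TRUE` the
#' features are z-scored and projected onto the top `n_components`
#' principal components (correlation PCA) before the Gaussians are
#' fitted; the projection state is stored in the model so prediction
#' applies the identical transform.
#'
#' @param x Numeric feature matrix, one row per example (e.g. from
#'   [feature_matrix()]).
#' @param y Logical labels (`TRUE` = interaction).
#' @param use_pca Transform features by PCA before fitting?
#' @param n_components Number of principal components kept (default 3).
#' @param density Class-conditional density model: `"gaussian"`
#'   (default) or `"binned"` (equal-frequency discretization with
#'   Laplace-smoothed bin probabilities, 10 bins).
#' @return An object of class `nb_model`.
#' @export
nb_train <- function(x, y, use_pca = FALSE, n_components = 3,
                     density = c("gaussian", "binned")) {
  density <- match.arg(density)
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("features must be finite numeric values", call. = FALSE)
  y <- as.logical(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)",
                                 call. = FALSE)
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("need at least 2 examples of each class", call. = FALSE)
  pca <- NULL
  z <- x
  if (use_pca) {
    if (n_components > ncol(x))
      stop("n_components (", n_components, ") exceeds the number of ",
           "features (", ncol(x), ")", call. = FALSE)
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl < .Machine$double.eps] <- 1
    zs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    pr <- stats::prcomp(zs, center = FALSE, scale. = FALSE)
    rot <- pr$rotation[, seq_len(n_components), drop = FALSE]
    z <- zs %*% rot
    pca <- list(center = ctr, scale = scl, rotation = rot)
  }
  breaks <- NULL
  if (density == "binned") {
    breaks <- lapply(seq_len(ncol(z)), function(j) {
      b <- unique(stats::quantile(z[, j], probs = seq(0, 1, length.out = 11),
                                  names = FALSE))
      b[1] <- -Inf; b[length(b)] <- Inf
      if (length(b) < 2L) b <- c(-Inf, Inf)
      b
    })
  }
  fit_class <- function(m) {
    if (density == "binned") {
      probs <- lapply(seq_len(ncol(m)), function(j) {
        nb <- length(breaks[[j]]) - 1L
        cnt <- tabulate(findInterval(m[, j], breaks[[j]],
                                     rightmost.closed = TRUE), nbins = nb)
        (cnt + 1) / (sum(cnt) + nb)  # Laplace smoothing
      })
      return(list(probs = probs))
    }
    mu <- colMeans(m)
    s2 <- apply(m, 2, stats::var)
    rng <- apply(z, 2, function(v) diff(range(v)))
    floor <- pmax(1e-9 * rng^2, .Machine$double.eps)
    list(mu = mu, s2 = pmax(s2, floor))
  }
  structure(list(
    prior = c(interaction = mean(y), `non-interaction` = mean(!y)),
    pos = fit_class(z[y, , drop = FALSE]),
    neg = fit_class(z[!y, , drop = FALSE]),
    pca = pca,
    density = density,
    breaks = breaks,
    features = colnames(x)),
    class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat("Naive Bayes integrator (", max(length(x$pos$mu),
                                      length(x$features)), " features",
      if (!is.null(x$pca)) paste0(", PCA k=", ncol(x$pca$rotation)),
      ")\n", sep = "")
  cat("  priors: interaction=", format(x$prior[1]),
      " non-interaction=", format(x$prior[2]), "\n", sep = "")
  invisible(x)
}

#' Posterior probability of interaction
#'
#' Applies the trained model to new feature rows and returns
#' `P(interaction | features)` computed in log space (stable out to
#' hundreds of standard deviations): per class, the log prior plus the
#' sum of Gaussian log densities, normalized by log-sum-exp.  The two
#' class posteriors sum to 1 by construction.
#'
#' @param object An `nb_model` from [nb_train()].
#' @param newdata Numeric feature matrix (or single row vector) with the
#'   training feature layout.
#' @param ... Unused.
#' @return Numeric vector of posteriors in \[0, 1\], one per row.
#' @export
predict.nb_model <- function(object, newdata, ...) {
  if (is.null(object$pos)) stop("model is not trained", call. = FALSE)
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
       as.matrix(newdata)
  if (!is.null(object$pca)) {
    z <- sweep(sweep(x, 2, object$pca$center), 2, object$pca$scale, "/")
    x <- z %*% object$pca$rotation
  }
  loglik <- function(par) {
    if (identical(object$density, "binned")) {
      ll <- numeric(nrow(x))
      for (j in seq_len(ncol(x))) {
        bin <- findInterval(x[, j], object$breaks[[j]],
                            rightmost.closed = TRUE)
        bin <- pmin(pmax(bin, 1L), length(par$probs[[j]]))
        ll <- ll + log(par$probs[[j]][bin])
      }
      return(ll)
    }
    rowSums(stats::dnorm(x, mean = matrix(par$mu, nrow(x), ncol(x),
                                          byrow = TRUE),
                         sd = matrix(sqrt(par$s2), nrow(x), ncol(x),
                                     byrow = TRUE), log = TRUE))
  }
  lp <- log(object$prior[1]) + loglik(object$pos)
  ln <- log(object$prior[2]) + loglik(object$neg)
  m <- pmax(lp, ln)
  as.numeric(exp(lp - m) / (exp(lp - m) + exp(ln - m)))
}

#' Pairwise feature correlations
#'
#' Diagnostic for the naive Bayes independence assumption: Pearson
#' correlations between all feature pairs and their mean absolute
#' off-diagonal value.  Zero-variance features yield `NA` for their
#' pairs rather than an error; they are excluded from the mean.
#'
#' @param x Numeric feature matrix with at least 3 rows.
#' @return List with `matrix` (correlation matrix) and
#'   `mean_abs_offdiag`.
#' @export
feature_correlations <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 examples", call. = FALSE)
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  off <- r[upper.tri(r)]
  list(matrix = r, mean_abs_offdiag = mean(abs(off), na.rm = TRUE))
}

#' Deterministic stratified fold assignment
#'
#' Assigns each example to one of `folds` cross-validation folds while
#' preserving the class ratio: within each class, a seeded permutation
#' is dealt round-robin, so fold sizes differ by at most one and
#' remainders land deterministically for a given seed.
#'
#' @param y Logical labels.
#' @param folds Number of folds.
#' @param seed Integer seed controlling the permutation.
#' @return Integer vector of fold ids in `1..folds`.
#' @export
stratified_folds <- function(y, folds = 10, seed = 1) {
  y <- as.logical(y)
  if (min(sum(y), sum(!y)) < folds)
    stop("smallest class has fewer members than folds; ",
         "use fewer folds", call. = FALSE)
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' ROC curve and AUC
#'
#' Computes the receiver operating characteristic by sweeping a
#' threshold over the distinct score values (tied scores enter as one
#' block, the midpoint/rank convention) and the area under it by the
#' trapezoidal rule.  Equivalent to the Mann-Whitney U statistic
#' divided by `n_pos * n_neg`.
#'
#' @param scores Numeric classifier scores, larger = more positive.
#' @param labels Logical truth labels.
#' @return List with `roc` (data frame of `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; lab <- labels[ord]
  # collapse tied scores into single ROC steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Stratified k-fold cross-validated AUC
#'
#' Splits the examples into stratified folds, trains the naive Bayes
#' integrator on each training portion (refitting any PCA transform on
#' that portion only, so no information leaks from held-out folds),
#' scores the held-out fold, pools all out-of-fold posteriors and
#' computes a single ROC/AUC from them.
#'
#' @param x Numeric feature matrix.
#' @param y Logical labels.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param use_pca,n_components Passed to [nb_train()].
#' @return List with `auc`, `roc` (pooled ROC points), `posterior`
#'   (out-of-fold posterior per example) and `fold` (fold assignment).
#' @export
stratified_cv_auc <- function(x, y, folds = 10, seed = 1,
                              use_pca = FALSE, n_components = 3) {
  x <- as.matrix(x)
  y <- as.logical(y)
  fold <- stratified_folds(y, folds = folds, seed = seed)
  post <- rep(NA_real_, length(y))
  for (k in seq_len(folds)) {
    tr <- fold != k
    model <- nb_train(x[tr, , drop = FALSE], y[tr],
                      use_pca = use_pca, n_components = n_components)
    post[!tr] <- predict(model, x[!tr, , drop = FALSE])
  }
  rc <- roc_curve(post, y)
  list(auc = rc$auc, roc = rc$roc, posterior = post, fold = fold)
}

#' Export ROC points as two-column TSV
#'
#' @param roc Data frame with `fpr` and `tpr` columns (from
#'   [roc_curve()] or [stratified_cv_auc()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  lines <- c("fpr\ttpr",
             paste(fmt_num(roc$fpr), fmt_num(roc$tpr), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
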