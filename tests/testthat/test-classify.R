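# 1-feature toy: class means 0 and 1, equal spread and priors
toy_model <- function() {
  x <- matrix(c(-0.1, 0.1, 0.9, 1.1), ncol = 1,
              dimnames = list(NULL, "f"))
  nb_train(x, c(FALSE, FALSE, TRUE, TRUE))
}

test_that("training recovers priors and symmetric decision boundary", {
  m <- toy_model()
  expect_equal(unname(m$prior), c(0.5, 0.5))
  expect_equal(predict(m, matrix(0.5)), 0.5, tolerance = 1e-9)
  expect_gt(predict(m, matrix(0.51)), 0.5)
  expect_lt(predict(m, matrix(0.49)), 0.5)
})

test_that("posteriors normalize and survive extreme inputs", {
  m <- toy_model()
  for (v in c(-60, -3, 0.2, 0.5, 2, 60)) {
    p_pos <- predict(m, matrix(v))
    # complementary model: same fit with labels flipped
    mflip <- nb_train(matrix(c(-0.1, 0.1, 0.9, 1.1), ncol = 1),
                      c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(p_pos + predict(mflip, matrix(v)), 1,
                 tolerance = 1e-12)
    expect_true(p_pos >= 0 && p_pos <= 1)
  }
  # +10 sigma into the positive class
  expect_gt(predict(m, matrix(1 + 10 * 0.1)), 0.999)
  # |z| = 300 sigma: log-space path must not underflow to NaN
  expect_equal(predict(m, matrix(1 + 300 * 0.1)), 1)
  expect_equal(predict(m, matrix(-300 * 0.1)), 0)
})

test_that("fitted Gaussians match a closed-form likelihood-ratio oracle", {
  set.seed(41)
  x <- matrix(c(stats::rnorm(60, 0, 1), stats::rnorm(40, 2, 1.5)),
              ncol = 1)
  y <- rep(c(FALSE, TRUE), c(60, 40))
  m <- nb_train(x, y)
  v <- 1.3
  lp <- log(0.4) + stats::dnorm(v, mean(x[y]), stats::sd(x[y]), log = TRUE)
  ln <- log(0.6) + stats::dnorm(v, mean(x[!y]), stats::sd(x[!y]), log = TRUE)
  expect_equal(predict(m, matrix(v)), 1 / (1 + exp(ln - lp)),
               tolerance = 1e-6)
})

test_that("posteriors agree with an independent naive Bayes implementation", {
  skip_if_not_installed("e1071")
  set.seed(43)
  n <- 200
  x <- cbind(a = stats::rnorm(n, rep(c(0, 1), each = n / 2)),
             b = stats::rnorm(n, rep(c(1, 0), each = n / 2), 0.5))
  y <- rep(c(FALSE, TRUE), each = n / 2)
  m <- nb_train(x, y)
  ref <- e1071::naiveBayes(data.frame(x), factor(y))
  pref <- stats::predict(ref, data.frame(x), type = "raw")[, "TRUE"]
  expect_equal(predict(m, x), unname(pref), tolerance = 1e-4)
})

test_that("variance-floored constant features cannot explode the posterior", {
  x <- cbind(f = c(0, 0.1, 1, 1.1), g = rep(2, 4))
  m <- nb_train(x, c(FALSE, FALSE, TRUE, TRUE))
  p <- predict(m, cbind(f = 0.55, g = 2))  # symmetric midpoint of f
  expect_true(is.finite(p))
  expect_equal(p, 0.5, tolerance = 1e-6)
})

test_that("parameter recovery on simulated Gaussians is within 3 SE", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 250
    mu_pos <- c(1, -0.5); mu_neg <- c(0, 0.5); sd_true <- c(1, 2)
    x <- rbind(cbind(stats::rnorm(n, mu_pos[1], sd_true[1]),
                     stats::rnorm(n, mu_pos[2], sd_true[2])),
               cbind(stats::rnorm(n, mu_neg[1], sd_true[1]),
                     stats::rnorm(n, mu_neg[2], sd_true[2])))
    y <- rep(c(TRUE, FALSE), each = n)
    m <- nb_train(x, y)
    se <- sd_true / sqrt(n)
    expect_true(all(abs(m$pos$mu - mu_pos) < 3 * se))
    expect_true(all(abs(m$neg$mu - mu_neg) < 3 * se))
  }
})

test_that("feature correlations flag duplicates, inversions and independence", {
  set.seed(47)
  x <- stats::rnorm(50)
  fc <- feature_correlations(cbind(a = x, b = x, c = -x))
  expect_equal(fc$matrix["a", "b"], 1)
  expect_equal(fc$matrix["a", "c"], -1)
  big <- matrix(stats::rnorm(10000 * 4), ncol = 4)
  expect_lt(feature_correlations(big)$mean_abs_offdiag, 0.05)
  const <- cbind(a = x[1:10], b = rep(1, 10))
  fc2 <- feature_correlations(const)
  expect_true(is.na(fc2$matrix["a", "b"]))
  expect_error(feature_correlations(cbind(1:2)), "3")
})

test_that("stratified folds preserve class ratio deterministically", {
  y <- rep(c(TRUE, FALSE), c(25, 75))
  f1 <- stratified_folds(y, folds = 5, seed = 9)
  f2 <- stratified_folds(y, folds = 5, seed = 9)
  expect_identical(f1, f2)
  for (k in 1:5) expect_equal(sum(y[f1 == k]), 5)
  expect_false(identical(f1, stratified_folds(y, folds = 5, seed = 10)))
  expect_error(stratified_folds(rep(c(TRUE, FALSE), c(3, 50)), 10),
               "fewer folds")
})

test_that("ROC AUC equals the Mann-Whitney closed form, with ties", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 80
    y <- stats::runif(n) < 0.4
    s <- round(stats::rnorm(n, mean = y), 1)  # rounding forces ties
    expect_equal(roc_curve(s, y)$auc, mw_auc(s, y), tolerance = 1e-12)
  }
})

test_that("ROC AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(61)
  y <- rep(c(TRUE, FALSE), each = 50)
  s <- stats::rnorm(100, mean = y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_curve(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("cross-validated AUC is 1 on separable data and ~0.5 on noise", {
  set.seed(71)
  x <- matrix(c(stats::rnorm(50, 0, 0.1), stats::rnorm(50, 10, 0.1)),
              ncol = 1)
  y <- rep(c(FALSE, TRUE), each = 50)
  expect_equal(stratified_cv_auc(x, y, folds = 10, seed = 1)$auc, 1)
  set.seed(72)
  xn <- matrix(stats::rnorm(2000), ncol = 1)
  yn <- rep(c(TRUE, FALSE), 1000)  # labels independent of features
  null_auc <- stratified_cv_auc(xn, yn, folds = 10, seed = 2)$auc
  expect_gt(null_auc, 0.45); expect_lt(null_auc, 0.55)
})

test_that("PCA machinery is lossless at k = n and refuses k > n", {
  set.seed(81)
  x <- matrix(stats::rnorm(300), ncol = 3)
  y <- rep(c(TRUE, FALSE), each = 50)
  m <- nb_train(x, y, use_pca = TRUE, n_components = 3)
  # k = n: rotation is orthonormal, reconstruction error ~ 0
  rot <- m$pca$rotation
  expect_equal(crossprod(rot), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  z <- sweep(sweep(x, 2, m$pca$center), 2, m$pca$scale, "/")
  recon <- (z %*% rot) %*% t(rot)
  expect_equal(recon, z, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(nb_train(x, y, use_pca = TRUE, n_components = 5),
               "exceeds")
})

test_that("binned density model classifies the separable toy set", {
  set.seed(91)
  x <- matrix(c(stats::rnorm(100, 0), stats::rnorm(100, 4)), ncol = 1)
  y <- rep(c(FALSE, TRUE), each = 100)
  m <- nb_train(x, y, density = "binned")
  p <- predict(m, x)
  expect_gt(mw_auc(p, y), 0.95)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(1:4, ncol = 1)
  expect_error(nb_train(x, c(TRUE, TRUE, TRUE, TRUE)), "each class")
  expect_error(nb_train(matrix(c(1, NA, 3, 4), ncol = 1),
                        c(TRUE, TRUE, FALSE, FALSE)), "finite")
})
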