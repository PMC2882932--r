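test_that("signal normalization rescales each row to mass 20", {
  raw <- toy_raw(list(c(A = 3, C = 1)))
  z <- normalize_signal(raw)$scores
  expect_equal(unname(z[1, "A"]), 15)           # 20 * 3/4
  expect_equal(unname(z[1, "C"]), 5)            # 20 * 1/4
  expect_equal(sum(z[1, setdiff(aa, c("A", "C"))]), 0)

  uni <- matrix(7, 3, 20, dimnames = list(NULL, aa))
  expect_equal(unname(normalize_signal(uni)$scores),
               matrix(1, 3, 20), tolerance = 1e-12)

  set.seed(11)
  r <- matrix(stats::runif(5 * 20), 5, 20, dimnames = list(NULL, aa))
  expect_equal(unname(rowSums(normalize_signal(r)$scores)), rep(20, 5),
               tolerance = 1e-9)
})

test_that("negative raw signals are clipped before normalization", {
  raw <- toy_raw(list(c(A = 3, C = 1)))
  raw[1, "D"] <- -5
  z <- normalize_signal(raw)$scores
  expect_equal(unname(z[1, "D"]), 0)
  expect_equal(unname(z[1, "A"]), 15)
})

test_that("fixed positions zero disallowed residues and seed pseudo-counts elsewhere", {
  raw <- toy_raw(list(c(A = 4), c(S = 2, T = 2, A = 4), c(G = 1)))
  fp <- fixed_position(2, c("S", "T"))
  z <- normalize_signal(raw, fixed = fp)$scores
  # row 2: only S and T survive, sharing the mass
  expect_equal(sum(z[2, ] > 0), 2)
  expect_equal(unname(z[2, "S"]), 10); expect_equal(unname(z[2, "T"]), 10)
  # rows 1 and 3: S and T gained +1 pseudo-count before normalization;
  # oracle recomputed by hand: row1 mass 4+1+1 = 6
  expect_equal(unname(z[1, "A"]), 20 * 4 / 6)
  expect_equal(unname(z[1, "S"]), 20 * 1 / 6)
  expect_equal(unname(z[3, "G"]), 20 * 1 / 3)
  expect_equal(unname(z[3, "T"]), 20 * 1 / 3)
  expect_equal(unname(rowSums(z)), rep(20, 3), tolerance = 1e-9)
})

test_that("degenerate signal input is rejected with the position named", {
  raw <- toy_raw(list(c(A = 1), c(A = 0)))
  expect_error(normalize_signal(raw), "position 2")
  expect_error(normalize_signal(toy_raw(list(c(A = 1))),
                                fixed = fixed_position(4, "S")),
               "outside")
})

test_that("peptide counts tally occurrences, totals and unique counts", {
  cts <- counts_from_peptides(c("AC", "AD"))
  expect_equal(unname(cts$n[1, "A"]), 2)
  expect_equal(cts$n[2, c("C", "D")], c(C = 1, D = 1))
  expect_equal(cts$N, c(2, 2))
  expect_equal(cts$R, c(1, 2))

  one <- counts_from_peptides("K")
  expect_equal(unname(one$n[1, "K"]), 1)
  expect_equal(one$N, 1)
  expect_equal(one$R, 1)

  set.seed(3)
  peps <- vapply(1:100, function(i)
    paste(sample(aa, 5, replace = TRUE), collapse = ""), character(1))
  cts <- counts_from_peptides(peps)
  # brute-force recount
  for (c in 1:5) {
    letters_c <- substr(peps, c, c)
    expect_equal(sum(cts$n[c, ]), 100)
    expect_equal(cts$R[[c]], length(unique(letters_c)))
    expect_equal(cts$n[c, "A"], sum(letters_c == "A"),
                 ignore_attr = TRUE)
  }
})

test_that("illegal peptide characters are reported with peptide and offset", {
  expect_error(counts_from_peptides(c("AC", "AX")), "AX")
  expect_error(counts_from_peptides(c("AC", "AX")), "offset 2")
  expect_error(counts_from_peptides(c("AC", "ACD")), "length")
})

test_that("flat pseudo-count probabilities match hand arithmetic", {
  cts <- counts_from_peptides(c("AA", "AA"))  # pos counts {A: 2}, N = 2
  p <- pseudocount_probabilities(cts, method = "flat")$scores
  expect_equal(unname(p[1, "A"]), 3 / 22)
  expect_equal(unname(p[1, "C"]), 1 / 22)
  expect_equal(sum(p[1, ]), 1, tolerance = 1e-12)
})

test_that("all pseudo-count methods produce row-stochastic matrices", {
  set.seed(5)
  peps <- vapply(1:30, function(i)
    paste(sample(aa[1:8], 6, replace = TRUE), collapse = ""),
    character(1))
  cts <- counts_from_peptides(peps)
  sm <- substitution_model("blosum62")
  for (method in c("substitution", "flat", "entropy")) {
    p <- pseudocount_probabilities(cts, method = method, subst = sm)
    expect_equal(unname(rowSums(p$scores)), rep(1, 6), tolerance = 1e-9,
                 label = method)
    expect_true(all(p$scores > 0), label = method)
  }
})

test_that("identity-like substitution model concentrates pseudo-counts", {
  # q concentrated on the diagonal: pseudo-counts follow observed residues
  q <- diag(20) * 0.9 + 0.1 / 19 * (1 - diag(20))
  dimnames(q) <- list(aa, aa)
  sm <- structure(list(name = "identity", q = q, Q = rowSums(q)),
                  class = "substitution_model")
  cts <- counts_from_peptides(rep("A", 10))
  p <- pseudocount_probabilities(cts, "substitution", sm)$scores
  # brute-force Henikoff evaluation for this q
  B <- 5 * 1
  b <- B * (q["A", ] / rowSums(q)["A"])
  expect_equal(unname(p[1, ]), unname((cts$n[1, ] + b) / (10 + B)),
               tolerance = 1e-12)
  expect_true(all(p[1, "A"] > p[1, setdiff(aa, "A")]))
})

test_that("probabilities approach observed frequencies as psi shrinks", {
  cts <- counts_from_peptides(c("ACD", "ACD", "ACE"))
  sm <- substitution_model("blosum62")
  p <- pseudocount_probabilities(cts, "substitution", sm,
                                 psi = 1e-9)$scores
  expect_equal(unname(p), unname(cts$n / cts$N), tolerance = 1e-7)
})

test_that("probabilities are monotone in the observed count", {
  sm <- substitution_model("blosum62")
  p_at <- function(k) {
    peps <- c(rep("A", k), rep("C", 10 - k))
    p <- pseudocount_probabilities(counts_from_peptides(peps),
                                   "substitution", sm)
    p$scores[1, "A"]
  }
  vals <- vapply(1:9, p_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("probability-to-score rescaling is exact and validated", {
  uni <- scoring_matrix(matrix(0.05, 2, 20, dimnames = list(NULL, aa)))
  expect_equal(unname(probabilities_to_scores(uni, "scaled")$scores),
               matrix(1, 2, 20))
  half <- scoring_matrix(toy_raw(list(c(A = 0.5, C = 0.5))))
  s <- probabilities_to_scores(half, "scaled")$scores
  expect_equal(unname(s[1, "A"]), 10); expect_equal(unname(s[1, "C"]), 10)
  ident <- probabilities_to_scores(half, "probability")
  expect_equal(ident$scores, half$scores)
  bad <- scoring_matrix(toy_raw(list(c(A = 0.5, C = 0.4))))
  expect_error(probabilities_to_scores(bad, "scaled"), "sum to 1")
})

test_that("pseudo-count preconditions are enforced", {
  cts <- counts_from_peptides(c("AC", "AD"))
  expect_error(pseudocount_probabilities(cts, "flat", psi = 0), "psi")
  expect_error(pseudocount_probabilities(cts, "substitution"),
               "substitution_model")
})
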