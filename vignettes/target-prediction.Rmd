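---
title: "Predicting domain targets by integrating motif scores with genomic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting domain targets by integrating motif scores with genomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimscan)
```

## The problem

Modular interaction domains — SH3, WW, and the substrate-recognition
surfaces of Ser/Thr kinases — bind short linear motifs of 5–10
residues. A position-specific scoring matrix (PSSM) derived from
peptide-library or phage-display data ranks candidate sites, but motif
matching alone is notoriously unspecific: a 6-mer motif matches
thousands of windows in any proteome, most of them buried, fast
evolving, or otherwise inaccessible. The premise of this package is
that genuine target sites live in a recognizable context — solvent
exposed, intrinsically disordered, and evolutionarily conserved — and
that a simple probabilistic integration of that context with the motif
score separates real targets from profile-score look-alikes.

## From experiment to scoring matrix

Two input routes produce the same object, a `scoring_matrix`.

**Signal route.** Positional-scanning peptide-library experiments give
a raw intensity `S_ca` per position `c` and amino acid `a`. Each row is
normalized to its total mass and rescaled by the alphabet size:
`Z_ca = 20 · S_ca / Σ_a' S_ca'`, so a row sums to 20 and a value of 1
means "no preference". Negative intensities, which array data can
produce, are clipped to 0 first — a weight cannot carry negative mass.
Domains with an invariant position (the S/T acceptor of a kinase motif)
are declared with `fixed_position()`: disallowed residues at that
position score exactly 0, and each allowed residue receives a
pseudo-count of 1 at every *other* position, reflecting the small but
non-zero chance of observing it there. The pseudo-count is added to the
raw signal *before* normalization so that it participates in the row
weight rather than distorting an already-normalized row.

**Peptide route.** Selection experiments undersample sequence space, so
observed frequencies severely penalize rare residues. We use
pseudo-count-corrected probabilities
`p_ca = (n_ca + b_ca) / (N_c + B_c)` with three choices of `b`:

* `substitution` (default): `B_c = ψ·R_c`, where `R_c` is the number of
  distinct residues observed at position `c` and `ψ > 0` (default 5)
  controls the pseudo-count mass; `b_ca` distributes `B_c` across amino
  acids through substitution probabilities weighted by the observed
  frequencies, `b_ca = B_c · Σ_i (n_ci/N_c)(q_ia/Q_i)` — the
  position-based pseudo-count scheme of Henikoff & Henikoff. As
  `ψ → 0` the probabilities converge to the observed frequencies.
* `flat`: add 1 everywhere (`B_c = 20`).
* `entropy`: `B_c = ψ·R_c·H_c/log2(20)` spread equally over the
  alphabet, so fully conserved positions (entropy 0) receive almost no
  pseudo-count while degenerate positions are smoothed the most.

The built-in substitution model converts the BLOSUM62 half-bit log-odds
scores bundled with Biostrings back into joint probabilities
(`q ∝ p_i p_a 2^{s/2}` with a uniform background, normalized to total
mass 1); deriving the table from the score matrix at runtime avoids
transcribing 210 constants and keeps `q` exactly symmetric. The
McLachlan chemical-similarity matrix is supported through the same
interface when the user supplies its values (they are not
redistributable here): scores are min-shifted to strictly positive and
row-normalized into probabilities. Peptide-route probabilities are
multiplied by 20 (`probabilities_to_scores(..., "scaled")`) so both
routes feed the scanner on the same scale.

## Scanning and the normalized score

The scanner slides a motif-length window along each protein and sums
the per-position matrix entries (`window_score`). Scores are
comparable across matrices only after normalization by the *optimal
score* — the sum of per-position column maxima — giving
`E = raw/optimal ∈ [0, 1]`, with `E = 1` exactly on a per-position
optimal window.

Numerical and determinism choices:

* The hit list is bounded (default 2,000, the reference capacity) and
  trimmed after every protein, so memory is flat in proteome size; the
  retained set is identical to the top-K of an exhaustive scan, which
  the test suite verifies against a brute-force enumeration oracle.
* Ties at the capacity boundary are resolved in scan order (protein
  input order, then ascending start). Any fixed input ordering
  therefore yields a byte-reproducible hit list.
* Windows containing non-standard residues (X, B, Z, U, O, J, `*`) are
  skipped, not zero-scored — a 0 would be a fabricated probability
  statement about an unobserved residue.
* Coordinates are 1-based inclusive everywhere in the external
  contract.

## Feature annotation

Conservation, solvent accessibility and disorder are consumed as
pre-computed per-residue tracks (tab-delimited `protein_id`,
`residue_index`, `value`); producing them (alignment pipelines,
accessibility and disorder predictors) is upstream of this package.
Accessibility and disorder are probabilities in [0, 1]; conservation is
an unbounded score with "higher = more conserved". Each hit is
summarized by the arithmetic mean of the track over its window — means
are invariant to motif length, and `min`/`max` are available where a
sharper criterion is wanted. The count of retained hits per protein is
stamped on as a fifth feature; it is computed on the post-capacity
list, i.e. on the hits that actually enter downstream ranking. Proteins
missing from a track can be flagged (`NA`), dropped, or imputed with
the proteome-wide track mean (the pipeline default, which keeps
training sets intact).

## Naive Bayes integration

The five features — motif score `E`, conservation, accessibility,
disorder, hits-per-protein — are combined by a two-class naive Bayes
model: `P(I|F_1..F_n) ∝ P(I)·Π_i P(F_i|I)`, evaluated in log space and
normalized by log-sum-exp, so posteriors are stable even hundreds of
standard deviations from the training data and the two class
posteriors sum to 1 to machine precision. Class-conditional densities
are Gaussian by default; an equal-frequency binned alternative
(`density = "binned"`, 10 bins, Laplace smoothing) is available since
continuous Gaussians are an assumption, not a given. Variances are
floored at `1e-9·range²` per feature so a constant feature cannot
produce an infinite likelihood ratio.

Feature independence is an assumption worth checking;
`feature_correlations()` reports the pairwise Pearson matrix and its
mean absolute off-diagonal. PCA preprocessing (`use_pca = TRUE`,
default 3 components) transforms the z-scored features onto their
principal axes first; correlation (z-scored) PCA was chosen because
the five features live on incommensurate scales. During
cross-validation the PCA transform is refitted on each training fold
only — fitting it on all data would leak held-out information into the
transform, a subtlety the tests pin down explicitly.

`stratified_cv_auc()` deals each class round-robin from a seeded
permutation into `k` folds (default 10), pools the out-of-fold
posteriors, and computes the AUC by the trapezoidal rule over the ROC
with tied scores collapsed into single steps — algebraically the
Mann–Whitney U statistic divided by `n_pos·n_neg`, which the test
suite asserts against an independent rank-based computation.

## Training design and consolidation

Gold standards label *proteins* (validated interactors; pairs
annotated to disjoint subcellular compartments as negatives), not
windows. Each labeled protein is therefore represented by its
top-`E` hit's feature vector; labeled proteins with no retained hit
are skipped with a warning. After classification, hits on the same
protein are consolidated to the single most likely one (highest
posterior; ties by higher `E`, then lower start), and the consolidated
list is filtered at the posterior threshold (default 0.9). The
threshold is applied after consolidation — it filters predicted
*targets*, and the full per-window report always retains everything.

## The synthetic study

`generate_study()` creates a complete, self-contained benchmark:

* a proteome of uniform-random sequences (uniform 1/20 background —
  no organism is privileged, and the scanner contract is
  frequency-agnostic), default 200 proteins of length 80–120;
* a 6-residue proline-rich consensus motif (`PALPPR`, SH3 class
  II-like) with 0.6 of each position's probability on the consensus
  residue, planted into 30% of proteins by sampling from the motif's
  per-position probabilities at a recorded coordinate;
* tracks as Gaussian noise (SD 0.15) around baselines 0.5
  (accessibility), 0.3 (disorder) and 0.0 (conservation), with a
  +1.5 SD mean shift over true-site windows, accessibility/disorder
  clipped to [0, 1];
* decoys in 20% of proteins: a motif-matching window *without* the
  feature shift. Decoys are the realistic hard case — sequences that
  look like sites but lack the structural context — and they are what
  makes profile-only scanning genuinely beatable rather than trivially
  saturated;
* a balanced training table (planted proteins true, an equal sample of
  non-planted proteins — decoys eligible — false) and a truth table of
  planted coordinates.

Identical spec and seed give byte-identical files. What the generator
does *not* emulate: realistic amino-acid composition, length and
domain structure of real proteomes, correlated noise between the three
tracks, experimental noise models of phage display, or homology
between proteins. Passing tests on this benchmark therefore
demonstrate the machinery's correctness and the qualitative value of
integration, not field performance on any particular interactome.

## Problem sizes and verification

The test suite runs the scanner-versus-enumeration oracle on 100
random 30-mer proteins across five seeds, parameter recovery on
500-example simulations across ten seeds, and the integration-vs-
profile comparison on the default 200-protein reference study
(seed 42), where the five-feature cross-validated AUC must exceed the
motif-score-only AUC by at least 0.03. `scripts/acceptance.R` re-runs
the full pipeline on a fresh reference study for any seed and reports
the recomputed AUCs, planted-site recall, feature correlations and
thresholded-prediction precision as JSON.

## Known limitations

* Conservation, accessibility and disorder must be supplied; the
  package deliberately does not wrap the upstream predictors.
* The naive Bayes integrator models features as class-conditionally
  independent; strongly redundant custom features will overcount
  evidence (inspect `feature_correlations()`, consider `use_pca`).
* `E` is a relative score; there is no p-value or background-corrected
  significance attached to a window, by design.
* The built-in substitution model is BLOSUM62-derived; kinase-family
  specific matrices, where available, may be supplied by the user.
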