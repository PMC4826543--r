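---
title: "Ensemble classification and diversity-constrained design of antibody-binding peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble classification and diversity-constrained design of antibody-binding peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdesign)
```

# The problem

Peptide microarrays incubated with pooled human immunoglobulin (IVIg) yield
an epitope–antibody reactivity (EAR) signal per peptide, in fluorescence
units. Two pools can be called with high confidence: binders above 10,000
and non-binders below 1,000 in every replicate; the band in between is left
unlabeled. `pepdesign` (i) learns to separate the two pools from sequence
alone and (ii) generates novel peptides of a desired reactivity class that
are provably dissimilar from everything the classifier has seen.

The peptide alphabet is the 20 canonical amino acids plus citrulline, written
`Z` — a deiminated arginine that appears in designed peptides. `Z` is an
ordinary 21st symbol wherever raw sequence is compared (string kernels,
Hamming distances, the design walk). Physicochemical tables have no
citrulline entry, so numeric encoders map `Z` to an all-zero row (with a
one-time warning; a strict policy that refuses `Z` is available). Any
citrulline signal the classifier exploits therefore enters through the
string-kernel members, and any preference of the designer for `Z` reflects
only that citrulline trivially avoids k-mers present in citrulline-poor
training data.

# The classifier ensemble

## Members

Each member is one "view" of the peptide:

| member | input | SVM kernel |
|---|---|---|
| `k_spectrum` | shared k-mer counts, k = 3..6 summed | precomputed Gram |
| `sssk` | residue pairs at displacement ≤ 6 | precomputed Gram |
| `bounded_range` | shared substrings of length 1..8 | precomputed Gram |
| `blosum` | concatenated BLOSUM50 rows (20·d dims) | RBF |
| `nlf_style` | 18-column reduced physicochemical rows | RBF |
| `sa_style` | 10-column reduced physicochemical rows | RBF |
| `local_composition` | AAIndex window means, w = 3..5 | RBF |
| `structure` | docking-score histograms (20 bins) | RBF |

All three string kernels are inner products of explicit substring-count
features, so their Gram matrices are symmetric positive semidefinite by
construction; the test suite verifies both properties, plus agreement with
naive enumeration oracles, on random peptide sets.

Two of the residue matrices deserve comment. The published 20×18 nonlinear
Fisher and 20×10 clustering/PCA reductions of the amino-acid property space
are not redistributable here, so `nlf_style_encoding()` and
`sa_style_encoding()` derive same-shape stand-ins by principal-component
reduction of the standardized AAIndex property table (544 properties; the 13
with missing residue values are dropped at load). These stand-ins serve the
same role — decorrelated physicochemical coordinates — but are not the
published values; `read_encoding_matrix()` loads the originals if the user
has them.

The AAIndex "local composition" member uses *window means*: for property
values `P(a)` and window length `w`, entry `i` of the feature vector is the
mean of `P` over positions `i..i+w-1`, giving `d − w + 1` entries per
property and window — 36 per property for 15-mers and `w ∈ {3,4,5}`. A
histogram-based alternative is sometimes described for this kind of feature;
we implement the window mean because it is the formulation whose dimension
contract `(d − w + 1)` we can state and test exactly.

The `structure` member featurizes externally supplied docking scores (one
score per pose, nominally 2000 per peptide) as a normalized histogram over
20 equal-width bins. Bin edges are frozen on the training corpus at fit time
and reused at prediction time, with out-of-range scores clipped into the
terminal bins — train and test must share bins or the feature space shifts.
Docking itself (structure building, minimization, rigid docking) is out of
scope; without score files the member is dropped and the remaining weights
renormalize through `A`.

## Training, calibration, weighting

Each member runs a grid search (defaults: cost `2^seq(-5, 15, 2)`; RBF width
`2^seq(-15, 3, 2)`, the conventional coarse log grids of the libsvm tooling)
with stratified k-fold cross-validation (default 5). Ties in CV accuracy
break toward smaller cost, then smaller width, so refits are deterministic.
The winning point is refit on all training data with Platt-style sigmoid
calibration (via kernlab's `prob.model`), and the winning CV accuracy
becomes the member weight `a_j`.

The ensemble posterior is `p+_ens(x) = (1/A) Σ_j a_j p+_j(x)` with
`A = Σ_j a_j` over the *trained* members — the normalizer ranges over
exactly the members that contribute terms, which is what makes the output a
convex combination (tested: the posterior is always bounded by the member
minimum and maximum). Hard calls use `p+_ens ≥ τ`, boundary inclusive,
`τ = 0.5` by default; τ is configuration, never learned.

Two scoring paths coexist deliberately. Class calls use the raw convex
combination above. Rank-ordered lists (`rank_predictions()`) first scale
each member's test-set probability vector to unit standard deviation and
then apply the same weighted sum — standardization stops a conservative,
low-variance member from dominating the ordering. Both paths are exposed
because either may be the right tool: thresholding wants calibrated
probabilities; ranking wants comparable spreads. A zero-variance member is
skipped from ranking with a warning (it cannot order anything).

Class imbalance (the realistic pool ratio is roughly 1:3) is left
unreweighted by default; the grid search sees the imbalance the classifier
will face at prediction time.

# The designer

A design walk starts from a seed peptide (a training-set member of the
target category) and repeatedly applies point substitutions — position
uniform, replacement uniform over the 21-symbol alphabet minus the current
residue — until the sequence satisfies every diversity rule, returning the
*first* satisfying sequence (first-passage stopping; further mutation would
only drift the candidate away from the scored optimum of its seed
neighborhood). The rules:

* **Shared k-mer rule** (default k = 4): no length-4 substring of the
  candidate may occur in any same-category training reference or in the
  withheld test set. Enforced through a prebuilt k-mer index.
* **Window-identity rule** (defaults: window 11, max identities 6): at every
  ungapped alignment offset with overlap ≥ 11, no 11-residue window may
  match in more than 6 positions. "Subsequence" here is read as a
  *contiguous* window under ungapped sliding — a gapped reading would make
  nearly every 15-mer violate against any sizable reference set, which would
  contradict the companion 4-mer rule's substring style. Sequence pairs
  whose maximal overlap is shorter than the window are compared over their
  whole overlap.

The k-mer rule applies against same-category training references only, the
window rule against those references and the full test set; this is the
literal reading of the two constraints, and a stricter interpretation (both
rules against both categories) is available by passing wider reference sets.
Walks are capped (default 10,000 mutations) and fail loudly at the cap.

A campaign (`run_design_campaign()`) seeds walks from the intensity extremes
of the training set (defaults 3,000 highest + 3,000 lowest; the packaged
examples scale this down, see below), scores all candidates with the
ensemble posterior, sorts, and assigns the top `n_high` to class H, bottom
`n_low` to class L, remainder to M (defaults 1,500/3,000/1,500). The
pipeline wrapper re-verifies every candidate with an independent naive
checker — direct substring scans, no index — and aborts on any violation,
since that would indicate a walker bug, not a data problem.

One designed-in consequence worth knowing: if the discriminative signal is a
4-mer motif present in training positives, H-class candidates can never
contain that exact motif (the k-mer rule forbids it) yet still score high
through near-motif features; the synthetic oracle below credits exactly
those near-motifs.

# Evaluation machinery

* **AUROC** is the Mann–Whitney statistic with half tie credit; **AUPR** is
  average precision with ties grouped. Both are checked against brute-force
  pairwise oracles.
* **Grey-zone metrics**: predictions (H/L) are compared with measured
  intensities around `5500 ± δ`, 5500 being the midpoint of the unlabeled
  1,000–10,000 band. Measurements inside the zone are removed from numerator
  *and* denominator; the true class of the rest is high iff intensity
  strictly exceeds `5500 + δ`. At δ = 0 nothing is excluded; at δ = 4500 the
  zone is exactly the open band (1,000, 10,000). The excluded fraction is
  non-decreasing in δ by construction.
* **Permutation F1 test**: F1 of H-class predictions (H is the positive
  class, matching the precision/recall orientation), `B = 1000` label
  permutations, `p = (1 + #{F1* ≥ F1}) / (B + 1)` — valid and never below
  `1/(B+1)`; uniformity under the null is property-tested.
* **Diversity profile**: peptides are vertices; an edge connects pairs with
  Hamming distance strictly below a cutoff `c`. For each vertex a maximal
  independent set containing it is grown greedily, visiting the remaining
  vertices in ascending id order; the profile reports the mean of the n set
  sizes per cutoff. Maximal independent sets containing a given vertex are
  not unique, so the deterministic visit order is part of the definition
  here — it makes profiles reproducible across runs and machines. A set
  whose minimum pairwise distance is 9 keeps a mean of n for every `c ≤ 9`
  and collapses beyond it.
* **Propensity matrix**: position-specific residue frequencies of
  true-positive designs divided by those of the negative set, with
  pseudocount `ε = 1/(n_tp + |alphabet|)` added to both — small enough not
  to flatten real enrichment at realistic set sizes, large enough to keep
  every ratio finite when a residue is absent from one set.

# The synthetic generator

`generate_pool()` emulates the features the classifier and designer actually
rely on: fixed-length peptides over the 21-symbol alphabet (citrulline at a
tenth of a canonical residue's background weight, mirroring its rarity in
real pools); class-discriminative planted 4-mer motifs at uniform random
positions (two motifs, insertion probability 0.6 each, at least one per
positive; negatives rejection-sampled to contain none); and log-normal
intensities truncated to the label-consistent side of the 1,000/10,000
thresholds (positive mode ≈ 22,000, negative ≈ 330), so pool construction is
exact by design and tests can rely on determinate pool sizes.
`generate_dock_scores()` draws 2,000 normal scores per peptide with a
configurable mean shift for positives.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: the heavy-tailed, replicate-noisy intensity
distribution of real arrays; positional composition biases; correlated
(overlapping-source) peptides; and real binding signals, which are weaker,
distributed, and not reducible to exact k-mers. Synthetic-recovery results
(held-out AUROC ≥ 0.95 at the packaged sizes) demonstrate that the machinery
recovers a planted signal, not that real-data performance reaches any
particular level.

# Problem sizes and numerical choices

The packaged tests and the reproduction script run at deliberately small
scale, chosen so the whole suite executes in minutes on a single CPU while
every code path is exercised: pools of 80/160 with a 120-peptide training
split for ensemble recovery; 60 + 60 design seeds with 30/60/30 classes;
tiny hyperparameter grids (cost `2^{0,4}`, width `2^{-9,-5}`, 3 folds) and a
five-property AAIndex subset for the local-composition member. The
full-scale defaults (6,841/20,437 pools, 3,420 + 10,218 training draws,
3,000 + 3,000 seeds, 1,500/3,000/1,500 classes, 544-property blocks, the
full libsvm grids) remain the function defaults and are exercised for the
pure-plumbing split arithmetic, which is exact at full scale in seconds.

Other numerical decisions:

* Gram matrices are symmetrized as `(K + t(K))/2` after sparse
  cross-products to remove floating-point asymmetry.
* All library randomness flows through private RNG streams derived from
  explicit integer seeds; the caller's `.Random.seed` is never disturbed,
  and equal seeds give bit-identical splits, folds, walks and permutations.
* Ranking ties break by peptide id; campaign seed selection breaks intensity
  ties by id; grid ties break toward smaller cost then width — every
  ordering in the package is total.
* Truncated log-normal intensities are drawn by rejection, which is cheap
  because the modes sit far from their truncation boundaries.

# Limitations

* The docking member featurizes scores it is given; the package neither
  builds peptide structures nor runs docking.
* The reduced physicochemical encodings are PCA stand-ins, not the published
  matrices (see above).
* The exact sparse-spatial-sample variant is parameterized by a single
  maximum displacement with single-residue probes; richer probe
  configurations exist in that kernel family and are configurable but not
  default.
* τ is never learned from data; selecting it on held-out data is the user's
  decision.
* The stratified re-sampling scheme used to pick small wet-lab validation
  panels from a design campaign is out of scope, as is any modeling of
  control-channel ("specific binding") categorizations.
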