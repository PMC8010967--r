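---
title: "Multi-class lysine PTM site prediction with GAN-based balancing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-class lysine PTM site prediction with GAN-based balancing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the model and the design choices behind `lysgan`:
what each stage assumes, which parameters matter, what the synthetic
fixtures do and do not emulate, and the numerical corner cases the
implementation handles.

## The problem

Many lysine modifications compete for the same ε-amino group, and their
sequence contexts overlap: a site annotated as ubiquitinated in one
database may be acetylated in another. We treat the task as single-label
multi-class classification over 17-residue peptide windows centered on
the modified lysine. Multi-label windows (the same site annotated with
several modification types) are excluded rather than modelled: they are a
small minority, and keeping the label space to K mutually exclusive
classes makes both the class balancing and the evaluation well defined.

## Preprocessing

Windows use flank width ξ = 8 (L = 17). Sites closer than ξ residues to a
protein terminus are dropped, not padded: the structural block needs a
real residue at every window position, and padded pseudo-residues would
have no defined physicochemical or structural values. Windows containing
non-canonical letters (B, J, O, U, X, Z) are likewise dropped with a
warning.

Redundancy reduction removes any fragment with ≥ 40% pairwise identity
(≥ 7 of 17 positions, since identity is a count fraction) to an
already-retained fragment. The scan is greedy keep-first in input order —
a deterministic, reproducible choice; no particular clustering algorithm
is canonical for this step, and keep-first has the property that the
retained set is independent of anything that comes later in the file.
Consequently the exact retained counts depend on input order; they are
reproducible for a fixed input file but not an invariant of the set.

Class assembly keeps singleton-label records in classes with at least
`min_count = 500` members (configurable; the synthetic experiments use
smaller bounds scaled to their fixture sizes). Classes are ordered
lexicographically, and all downstream code indexes them 1..K in that
order. With the reference seven-class counts
(Ace 3114, Glyca 1399, Malon 1224, Meth 1147, Succ 1645, Sumo 1174,
Ubiq 3185; total 12 888) the balancing deficits relative to the largest
class are 71, 1786, 1961, 2038, 1540, 2011 and 0 — 9407 synthetic samples
in total.

## Feature construction

Nine blocks, concatenated in a fixed order, total 2359 dimensions for
L = 17. Design notes per block:

* **AAindex (238)** — 14 published per-residue scales, z-scored across
  the 20 residues (population SD). The particular set of 14 is a
  documented, replaceable default (`aaindex_properties()`); the encoders
  are tested on dimensions and layout, not on any specific scale values,
  and any 20 × 14 matrix can be substituted.
* **CKSAAP (1200)** — ordered pairs at gaps k ∈ {0, 1, 2}, normalised by
  the number of pairs at that gap (L − 1 − k), so each 400-block is a
  frequency distribution summing to 1. Frequencies rather than raw counts
  keep the three gap blocks on a common scale.
* **PWM (17)** — positional residue frequencies fitted on the *training
  fold only*, pseudocount 0; a fragment encodes as its own residue's
  frequency at each position. One pooled PWM is the default; class-
  conditional PWMs (`fit_pwm(labels =)`) are available but change the
  block dimension and are not used by the standard pipeline, because a
  single 17-dimensional block requires one reference matrix.
* **Reduced alphabet (136)** — one-hot over 8 physicochemical groups:
  acid {D,E}, basic {H,K,R}, aromatic {F,W,Y}, amide {N,Q}, small
  hydroxyl {S,T}, sulfur {C,M}, aliphatic {A,G,P} and {I,L,V}.
* **FoldAmyloid-style profile (17)** — mean expected packing density over
  a centred 5-residue window (truncated at the ends); binary mode
  thresholds at 21.4 contacts. The scheme is toggleable; in practice the
  forest assigns it little importance, so its exact scale values are
  non-critical.
* **Binary encoding (340)** — one-hot over the alphabetical residue
  order. The invariant central lysine contributes a constant column that
  the zero-variance step of the feature screen removes automatically; we
  do not special-case it in the encoders.
* **PC-PseAAC (36) / SC-PseAAC (52)** — λ = L − 1 = 16, ω = 0.05.
  Parallel correlation averages squared property differences over
  (hydrophilicity, hydrophobicity, side-chain mass); series correlation
  keeps one factor per property (first two) and lag. Both vectors are
  jointly normalised to sum 1; the homopolymer limit (all correlation
  factors 0, unit mass on one composition entry) is exact.
* **Structure (323)** — 19 channels per residue consumed from a
  per-residue table (ASA; Q3 and Q8 secondary-structure probabilities;
  φ, ψ, θ, τ in degrees, no trigonometric transform; HSEα-up/down; CN).
  The package never predicts structure; it only consumes such a table,
  and errors with the protein and positions named if rows are missing.

## Feature screening

The screen computes the Pearson correlation of each (non-constant)
column with the numeric class label and discards columns with |r| > 0.5.
Two genuinely open choices are exposed rather than hidden:

* *What correlates with what.* The default screens feature-vs-label; a
  feature-vs-feature greedy mode (drop a column correlated > 0.5 with any
  already-kept column) is first-class, since removing inter-feature
  redundancy is the more common motivation for this kind of filter.
* *How labels are encoded.* Class indices 1..K are arbitrary as a
  numeric scale; the default uses them directly, and a one-vs-rest mode
  (max |r| over per-class indicators) avoids the arbitrariness at the
  cost of a stricter screen.

The mask is fitted on the training fold and applied unchanged to
evaluation folds; a leakage test asserts that perturbing evaluation rows
cannot change the mask.

## Conditional (Wasserstein) GAN balancing

Both variants condition generator and discriminator/critic on the one-hot
class label, so one model serves all K classes (per-class training is a
config switch). Features are min-max scaled to [−1, 1] on the real rows
(inverse applied to generated rows; constant columns map to 0 and invert
to their constant), matching the generator's tanh output.

The plain conditional GAN uses a sigmoid discriminator with the log
loss and Adam (2e-4). The Wasserstein variant removes the output sigmoid
and the logarithms — the critic maximises E[D(x|y)] − E[D(G(z|y))] — and
after *every* critic update clips all critic parameters to [−c, c]
(c = 0.01), with RMSProp (5e-5) and 5 critic steps per generator step:
the standard weight-clipping recipe. The networks are small
fully-connected nets (defaults: generator 100+K → 256 → 512 → p, critic
p+K → 512 → 256 → 1, leaky-ReLU 0.2) written directly on base-R matrix
ops with manual backpropagation; at these widths BLAS matrix products
dominate and no deep-learning framework is needed. Non-finite losses
abort with a diagnostic rather than silently continuing.

Defaults target production runs (50 000 iterations, batch 64). The test
suite and the acceptance script scale down — toy problems use 300–400
iterations with 32–128-unit layers — which is enough for the qualitative
contracts they check (clip bound maintained at every step; generated
class means approach their own class and not the other; real-vs-synthetic
mean distance shrinks from an untrained to a trained generator).

Balancing arithmetic is separate from the model: each minority class
receives majority−count synthetic rows. Real rows are never modified, and
synthetic rows carry a flag so that evaluation code can assert none leak
into test folds. A k-NN interpolation SMOTE (in-package, 5 neighbours) is
included as the conventional oversampling baseline.

## Classification and evaluation

Random forest: 500 trees, √p features per split, unlimited depth,
impurity importance, single-threaded and seeded so runs are bit
reproducible. The evaluation protocol is a stratified 4/5 : 1/5
independent split with stratified tenfold cross-validation on the 4/5
(stratification is our choice so small classes appear in every fold).
Fold predictions are pooled into one confusion matrix — pooling gives
integer counts whose metrics are exactly reproducible, whereas per-fold
averaging would need a convention for folds missing a class. Every
fitted artifact (PWM, screen mask, GAN + scaler, forest) is refit inside
each training fold by default; a single-augmentation "once" scope exists
only to quantify how much that leaks.

Metrics: overall accuracy and its exact complement the error rate;
the K-category Matthews correlation computed from the confusion matrix
(cross-checked in tests against a one-hot correlation oracle); confusion
entropy (CEN) with logarithms base 2(K−1) over off-diagonal
misclassification probabilities, class-weighted — 0 for a perfect
diagonal; one-vs-rest per-class sensitivity, specificity, accuracy, MCC
(degenerate 2 × 2 margins yield 0 with a warning) and rank-based AUC with
midrank tie handling. DeLong comparison of correlated AUCs delegates to
pROC and is validated against a paired permutation oracle; identical
score vectors short-circuit to p = 1 (the DeLong variance is 0 there).
Scheme-grouped importance sums normalised impurity importances over each
scheme's surviving columns, so a scheme entirely removed by the screen
reports exactly 0.

## Synthetic fixtures

`generate_fixture()` writes FASTA, site-annotation and structure tables
for a configurable class design. Each synthetic protein embeds one
annotated lysine; flank positions −4, −1, +2, +4, +7 carry the class
signal (each shows the class's preferred residue with probability equal
to the motif strength; other positions are uniform), and the 19
structural channels are class-shifted Gaussians (0.8 SD between extreme
classes by default) with Q3/Q8 blocks as softmax probabilities. Defaults:
the seven reference class counts, motif strength 0.5.

What the fixtures emulate: class-specific positional composition,
class-specific structural statistics, class imbalance, and exact
recoverability of every planted site as a 17-mer. What they do not:
proteome-scale homology structure, correlated channels within a real
secondary-structure predictor's output, multi-label sites, or realistic
inter-class sequence similarity. Passing tests on fixtures therefore
demonstrate the pipeline's mechanics and qualitative behaviour — not
real-data accuracy, which depends on a curated modification corpus.

Two scaled experiments anchor the test suite (sizes chosen so the whole
suite runs comfortably on a laptop):

* *Separability*: 3 × 60 samples at motif strength 0.9 with structure —
  cross-validated accuracy and every per-class AUC exceed 0.95.
* *Imbalance*: 600/100/100 at motif strength 0.5, sequence schemes only.
  The structural channels are omitted deliberately: with them the fixture
  is separable enough that minority sensitivity is already ~1 without any
  augmentation, leaving nothing for balancing to improve. On sequence
  features alone the un-augmented forest under-detects the minority
  classes, and CWGAN augmentation (400 iterations, 64/128-unit nets)
  raises pooled minority sensitivity — the scaled analogue of the
  imbalance effect the method exists for. At this problem size the effect
  is small (one to two evaluation samples on a 40-sample minority eval
  set) and sensitive to the random seeds, which the suite therefore
  fixes; demonstrating a large, seed-robust gain requires corpus-scale
  data and full-length GAN training, both outside a test suite's scope.

## Known limitations

* The AAindex and packing-density scales are packaged defaults, not
  fitted quantities; swapping them changes feature values (not shapes).
* Weight-clipping WGAN is the implemented variant; gradient-penalty
  critics are out of scope.
* The redundancy filter is O(n · kept · L) and single-threaded; for
  corpora beyond ~10^5 fragments a dedicated clustering tool is more
  appropriate.
* Class labels enter the feature screen as integer indices by default;
  the one-vs-rest mode is preferable when class order is meaningless,
  and both are exposed precisely because neither is canonical.
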