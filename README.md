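# lysgan

Multi-class prediction of lysine post-translational modification (PTM)
sites from protein sequence, with GAN-based class balancing.

Lysine residues carry many competing covalent modifications —
acetylation, ubiquitination, succinylation, sumoylation, methylation,
malonylation, glycation — and telling them apart from sequence is a
multi-class problem with severe class imbalance: abundant modifications
outnumber rare ones by nearly 3:1. `lysgan` implements the full pipeline
for this problem, aimed at computational biologists who have a set of
annotated modification sites (FASTA + site table) and want a calibrated
multi-class predictor plus an analysis of which sequence/structure
signals drive it:

1. **Fragments** — 17-residue lysine-centered windows (flank ξ = 8) are
   cut from the proteins; windows shorter than 17 are dropped, identical
   fragments from different source tables are merged (label union),
   fragments with ≥ 40% pairwise identity to an already-kept fragment are
   removed (greedy keep-first scan), and only single-label classes with
   enough examples are retained.
2. **Encoders** — each fragment becomes a 2359-dimensional vector from
   nine schemes: 14 AAindex physicochemical profiles (14L = 238), the
   composition of k-spaced amino-acid pairs CKSAAP for k ∈ {0,1,2}
   (3·400 = 1200), a position weight matrix fitted on the training fold
   (L = 17), a reduced 8-letter alphabet (8L = 136), a windowed
   packing-density amyloidogenicity profile (L = 17), binary one-hot
   encoding (20L = 340), parallel- and series-correlation pseudo
   amino-acid composition with λ = 16, ω = 0.05 (36 and 52), and a
   19-channel-per-residue structural block (ASA, 3- and 8-state secondary
   structure, backbone angles φ/ψ/θ/τ, half-sphere exposure, contact
   number; 19L = 323). Every column carries provenance
   (scheme, human-readable tag).
3. **Feature screen** — Pearson correlation: columns whose |r| with the
   class label exceeds 0.5 are discarded (a feature–feature greedy mode is
   also available).
4. **Class balancing** — a conditional Wasserstein GAN (label-conditioned
   generator and critic, no output sigmoid, no log loss, critic weights
   clipped to [−c, c], RMSProp, n_critic critic steps per generator step)
   is trained on the screened feature matrix and sampled per class so all
   classes reach the majority count. A plain conditional GAN (sigmoid
   discriminator, Adam) and a k-NN–interpolation SMOTE baseline are also
   provided. Diagnostics: per-iteration generator/critic loss traces and
   the Euclidean distance between real and synthetic class means.
5. **Classification & evaluation** — a random forest (500 trees, √p
   mtry), stratified 4/5 : 1/5 independent split, stratified tenfold
   cross-validation on the 4/5 with every fitted artifact (PWM, mask,
   GAN, forest) refit inside each fold; metrics: accuracy, error rate
   E = 1 − Acc, multiclass Matthews correlation (K-category
   generalization), confusion entropy (CEN), per-class
   sensitivity/specificity/MCC/AUC (midrank), DeLong tests between
   correlated AUCs, and feature importance aggregated by encoding scheme.

A seeded synthetic-fixture generator (`generate_fixture()`) emulates
curated modification-database input — class-specific positional residue
biases and
class-shifted Gaussian structural channels — so the whole pipeline is
testable without downloads.

## Worked example

```r
library(lysgan)

# three-class synthetic input: FASTA + site TSV + structure TSV
fx <- generate_fixture(fixture_spec(counts = c(Ace = 60, Sumo = 60, Ubiq = 60),
                                    motif_strength = 0.9, seed = 5))
frags <- extract_fragments(fx$proteins, fx$sites)
ds <- filter_classes(merge_labels(frags), min_count = 5)
ds
#> lys_dataset: 180 fragments, 3 classes
#>  Ace Sumo Ubiq
#>   60   60   60

res <- evaluate_pipeline(list(dataset = ds, structure = fx$structure),
                         pipeline_options(num_trees = 150, seed = 6),
                         seed = 42)
res$cv
#> Acc 1.0000  MCC 1.0000  CEN 0.0000  E 0.0000
#>   class acc sp sn mcc auc
#> 1   Ace   1  1  1   1   1
#> 2  Sumo   1  1  1   1   1
#> 3  Ubiq   1  1  1   1   1
round(res$importance$by_scheme, 3)
#>         AAindex       Structure             PWM ReducedAlphabet          CKSAAP
#>           0.441           0.165           0.081           0.074           0.063
#>              BE     FoldAmyloid       SC-PseAAC       PC-PseAAC
#>           0.060           0.048           0.037           0.031
```

With a motif this strong the cross-validated accuracy saturates at 1 and
the confusion entropy at 0; the per-scheme importances show which
encodings the forest actually used. On imbalanced data, compare
`pipeline_options(augment = "none")` against `augment = "cwgan"`: the
balanced run raises minority-class sensitivity (see the vignette for the
scaled experiment).

A thin command-line driver is installed as `exec/lysgan`
(`simulate-fixture`, `preprocess`, `encode`, `filter`, `augment`,
`evaluate`, `report`); every run writes its resolved configuration and
seed next to its outputs.

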