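---
title: "peptidev: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peptidev: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
models, which knobs matter, what the synthetic generators do and do not
emulate, and where design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## The problem

A therapeutic peptide must clear several developability hurdles at once —
it should not lyse red blood cells (hemolysis), adsorb proteins
nonspecifically (fouling), be toxic or insoluble; it may need to cross
membranes (permeability, measured as log Pexp in PAMPA or Caco-2 assays,
which are *distinct* tasks here), persist in serum (half-life), and bind
its protein target (affinity). `peptidev` provides the shared machinery to
train and compare predictors for these properties without information
leaking from training to evaluation data.

## Records and modalities

Peptides are handled in two representations. The AA modality accepts the
20 canonical residues only and requires length ≥ 2 (one residue has no
peptide bond); `U, O, B, Z, X` are rejected so that every downstream
physicochemical table is total. Anything noncanonical — D-residues,
cyclization, side-chain chemistry — enters as SMILES. The modality is an
explicit column in dataset tables rather than inferred, because some
SMILES strings ("CN") are also valid residue strings. One peptide may
carry several property labels; a dataset is a view selecting one task. No
default length filter is applied (none is defensible a priori; the length
range is a generator parameter instead).

## Chemistry

`sequence_to_smiles()` assembles linear peptides from Kekulized residue
templates: free amine N-terminus, free carboxylic acid C-terminus, amide
bonds, L-stereocenters written for every residue except glycine. The
templates were verified against the known molecular formulas of all 20
free amino acids, and the test suite re-derives every peptide formula from
residue composition (sum of residue formulas minus one water per bond) via
an independent oracle.

Circular fingerprints follow the ECFP recipe: atom invariants (element,
heavy degree, hydrogen count, formal charge, aromaticity, and optionally
the chirality tag), iterative neighborhood rehashing to radius 2, folding
modulo 2048 bits, binary occupancy. Two deliberate choices:

- the hash is a documented deterministic fold, **not** bit-compatible with
  other toolkits — collisions are accepted, as in any folded ECFP;
- with `chirality = TRUE` the `@`/`@@` tag is used as written. This
  separates enantiomer pairs and is stable for a fixed SMILES writing, but
  no CIP canonicalization is attempted; achiral structure contributions
  are atom-order-invariant.

Tanimoto similarity of two all-zero fingerprints is defined as 1
(identical objects), not 0.

The physicochemical profile uses average residue masses plus one water
(MW), the Kyte–Doolittle scale for GRAVY, and Henderson–Hasselbalch
charges over the termini and ionizable side chains (K, R, H positive;
D, E, C, Y negative). The pKa table is an EMBOSS-style scale and is
configurable: published scales disagree by a few tenths of a pH unit, and
no single scale is canonical. The isoelectric point is found by bisection
of the monotone charge curve to |charge| < 1e-4; convergence is tested on
10,000 random sequences. The low-complexity flag is strictly
`length / n_unique > 5` — the boundary ratio 5 is *not* low complexity.

## Clustering and splitting

A faithful MMseqs2 reimplementation is out of reach, so the sequence path
uses a greedy representative scan with explicit semantics: records sorted
by descending length (ties lexicographic); each record joins the first
representative reached at identity ≥ 0.3 with coverage ≥ 0.8 *of both
sequences*, else founds a cluster. Identity and coverage come from a
global alignment with free end gaps (match +1, mismatch 0, affine interior
gaps opening 1, extension 0.5): identity is matches over the aligned
window, coverage the window's span over each sequence length. Free end
gaps matter: they let a shared block align exactly while exposing short
overlap windows, which is why similarity thresholds must always be paired
with the coverage gate (a perfect 2-residue overlap is not leakage).
Because co-optimal alignments can carry different match counts, identity
is made orientation-independent by always aligning the longer sequence
first (ties lexicographic); the greedy scan uses the same canonical
orientation, so the reported identity is symmetric.
Cluster memberships are consequently *not* bit-identical to MMseqs2 on
borderline pairs; the parameters and the bidirectional-coverage semantics
(cov-mode 0 analogue) are preserved.

The SMILES path is Taylor–Butina: neighbor lists at Tanimoto ≥ 0.6;
repeatedly pick the unassigned molecule with the most unassigned neighbors
(ties: lowest input index) as centroid and absorb its unassigned
neighbors; singletons stand alone. Both algorithms are tested for exact
agreement with brute-force oracles on ≥ 50 random corpora each.

Splits are cluster-atomic: clusters are shuffled with one recorded seed
and assigned to train until `ceiling(0.8 × n_clusters)`; every manifest
stores method, parameters and seed, and the reader rejects any manifest in
which a cluster spans both partitions. The guarantee "no cross-partition
pair above threshold" holds *between cluster founders* by construction;
member-to-member similarity across clusters is not bounded (a standard
property of single-pass greedy clustering), which the audit respects by
checking representatives.

For paired affinity data, splitting matches the score distribution
instead: quantile bins (default 10 — the mechanism is not prescribed
anywhere, so the bin count is exposed), per-bin shuffling at the train
fraction, and a reported Kolmogorov–Smirnov distance so users can audit
the match.

## Embeddings

Baseline featurizers make everything downstream testable without
pretrained weights: per-residue one-hot(20) + scaled hydropathy +
side-chain charge at pH 7 + a two-channel sinusoidal position code
(D = 24); per-atom element/degree/aromaticity/charge features for SMILES
(D = 14). Mean-pooling is exact column averaging, and
`mean_pool(embed(x, unpooled))` equals `embed(x, pooled)` to 1e-12 — one
stated pooled variant that appends a folded-fingerprint block would break
that identity, so it lives behind a separate featurizer id
(`baseline_smiles_fp`) and is pooled-only. External embedders (protein
language models and the like) integrate through an adapter contract
(name, dimension, strip-your-special-tokens); the package ships no
weights, and whether an adapter's pooling includes special tokens is the
adapter's documented responsibility.

## Predictor heads

Pooled embeddings feed elastic net (glmnet), linear SVM (hinge), linear
SVR (ε-insensitive), gradient-boosted depth-limited trees, and an MLP;
unpooled embeddings feed a 1-D CNN and a single-block multi-head
self-attention transformer, padded per batch with explicit masks — masked
positions cannot influence outputs, and the tests verify padding
invariance to 1e-6. The routing is enforced, not advisory: positional
architectures must see positions, fixed-dimension learners must not see
padding artifacts.

The neural stack is a small reverse-mode tape over matrices and batched
3-D arrays, with compiled kernels for batched matmul and masked softmax.
Gradients were verified against central finite differences (relative
error ~1e-7) on a two-layer cross-attention configuration. Design
choices: Adam, no layer normalization (at these widths and depths
training is stable without it; the 1-layer default reflects that), no
dropout by default, one integer seed controlling initialization and
shuffling, no early stopping (fixed epoch budgets per trial). Binary
heads return class-1 probabilities thresholded at 0.5 for hard labels;
the threshold-scanned "best F1" is additionally reported because a fixed
0.5 is not the only defensible convention.

## Affinity

All Kd/Ki/IC50 readouts are unified as `−log10(molar value)` with no
Cheng–Prusoff correction — the readout kind is metadata, usable for
stratified evaluation but not numerically corrected. Classes: score ≥ 9
strong, 7 ≤ score < 9 medium, < 7 weak; ties at 9 are strong and at 7
medium (boundary convention tested at ±1e-9).

The affinity model projects both streams to a common width, adds
sinusoidal positions, and runs peptide-queries → protein-keys/values
cross-attention (one-directional; the reverse direction is a config away
but the baseline keeps the peptide as the query stream), mean-pools the
peptide state and splits into a scalar score head and a 3-logit class
head. The loss is Huber(δ = 1) on *standardized* scores plus λ × class
cross-entropy (λ = 0.3 default; λ = 0 provably leaves the class head
untouched). Protein embeddings are always unpooled; peptide pooling is
the experimental variable, and on the planted position-dependent
generator the unpooled variant beats the pooled one by a wide margin —
the pooled model cannot represent a position-offset interaction at all.
Training defaults (35 epochs, lr 4e-3, batch 96) are chosen so a 3,000-
pair recovery run fits a single CPU budget.

## Half-life

Measurements are converted to hours (minutes/60, days×24); the regression
target is `log(1 + hours)` with natural log (the base is configurable;
nothing downstream depends on it). Neural families warm-start from a
stability predictor by copying every tensor except the output layer and
fine-tuning briefly; tree and linear families have no meaningful
warm-start mechanism and train directly with a logged notice. The
four-configuration protocol (gbt vs transformer × hours vs log1p) runs
under 5-fold CV with per-fold and mean Pearson/Spearman/R².

## Hyperparameter search and metrics

`run_search` is seeded random search: log-uniform parameters are drawn
uniformly in log space (tested: each decade of a 3-decade range receives
one third of the mass ± 2%), budgets default to 200/50/20 trials by
family class, failed trials are recorded and skipped, and the entire
history is reproducible from one seed. An adaptive sampler can be plugged
in behind the same interface, but the deterministic default is what every
test uses. Metric conventions: AUC is the rank statistic with tie
averaging and is *missing* (not 0) for single-class truth; MCC defines
0/0 as 0; best-F1 scans midpoints of sorted unique scores plus the
extremes; Spearman uses average ranks; model selection is by best-F1
(classification) or Spearman ρ (regression/affinity) with documented tie
rules ending in lexicographic family order for determinism.

## Synthetic generators: what a green test establishes

The generators emulate the *statistical geometry* of each task, not
biology: uniform random sequences over the canonical alphabet, Gaussian
noise throughout, class-imbalance presets mirroring the curated corpus
compositions (hemolysis ≈ 78/22, non-fouling ≈ 79/21, toxicity 50/50,
solubility ≈ 48/52). Specifically:

- binary corpora plant a charge, hydropathy or positional-motif signal; a
  latent-threshold construction makes the achieved positive fraction match
  the request and makes `effect_size = 0` a true null (labels independent
  of sequence);
- the motif rule plants the same 4-mer at a *fixed* position in positives
  and a random other position in negatives, so pooled representations are
  provably uninformative while positional heads can succeed — this is the
  instrument for the position-sensitivity claims;
- permeability draws log Pexp from a two-component normal mixture
  straddling −6.0 (component means −8/−5, sd 0.8) and derives binary
  labels by the `≥ −6.0` rule, with a closed-form Gaussian-tail check;
- affinity scores are a position-offset hydropathy-compatibility sum
  rescaled into the unified [4, 12] band plus noise (σ = 0.3 at the
  stated n = 3,000), with classes derived from the final score;
- half-life shares a latent stability signal with a large pretraining
  corpus (`hours = exp(0.8·s + 1 + ε)`, ε with σ = 0.6, n capped at 500
  to mimic the sparse regime) so that transfer has something to transfer.

A green recovery test therefore establishes that the pipeline can extract
a planted signal of realistic shape under leakage-proof evaluation — not
that any real corpus would reach those numbers. Heavier-tailed noise,
realistic residue composition and homology structure are explicitly not
emulated.

## Numerical choices and degenerate inputs

Target standardization inside SVR and the affinity model (undone at
prediction); feature standardization inside SVM/SVR/MLP; an
intercept-only fallback when all features are constant (the closed-form
training-mean predictor); pI bisection to |charge| < 1e-4 with a 200-step
cap; Tanimoto 0/0 := 1; MCC 0/0 := 0; quantile bins collapse gracefully
when labels are constant (KS = 0); empty FASTA reads warn and return an
empty set; a sequence line before the first header is an error, not a
guess.

## Known limitations

- Fingerprints and cluster memberships are deliberately not bit-identical
  to RDKit/MMseqs2; only the documented semantics are contractual.
- Aromatic SMILES support is "as written" (no aromaticity perception or
  kekulization); the internal sequence→SMILES path avoids the issue by
  emitting Kekulé forms.
- The SVM/SVR families are linear (on embeddings); kernelized variants
  are out of scope.
- Greedy clustering bounds founder-founder similarity only; datasets with
  chained near-duplicates can place similar *members* of different
  clusters across partitions, as any single-pass scheme can.
- The neural engine targets small corpora on one CPU; it is not a GPU
  training framework.
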