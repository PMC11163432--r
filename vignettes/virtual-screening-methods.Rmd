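---
title: "Fingerprint-driven virtual screening: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint-driven virtual screening: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligscreen)
```

# The problem

Virtual ligand screening (VLS) ranks a library of candidate small
molecules by their predicted likelihood of binding a protein target, so
that experimental effort can concentrate on the top of the list. ligscreen
implements a ligand-homology-modeling flavor of VLS: the target is
represented not by a high-resolution structure but by *template pockets* —
binding sites from solved protein–ligand complexes whose structure matches
the target — together with the ligands bound in those pockets. Two
complementary screening routes are built on this representation, plus a
principled way to combine them:

1. **Template-ligand similarity**: rank candidates by fingerprint
   similarity to the template ligands.
2. **Pocket-aware boosted scoring**: learn a regression from
   (pocket composition, ligand fingerprint) pairs to a 0/1 binder label
   across many targets, and score new target–ligand pairs.
3. **Best-precision meta-combination**: calibrate each route's raw score
   to a predicted precision and keep, per molecule, the best one.

# Ligand representation: three fingerprints

Every ligand enters as a SMILES string and is reduced to bit fingerprints:

* **Substructure keys** (881 bits): bit *k* is set when the *k*-th keyed
  substructure is present at least its threshold count. The packaged key
  table (`inst/extdata/pubchem_keys_synthetic.tsv`) is *synthetic*: it
  follows the sectional structure of the published PubChem/CACTVS key
  specification — hierarchic element counts, ring counts, bonded element
  pairs, atom neighborhoods with and without bond orders, and free SMARTS
  substructures — but it is not the verbatim third-party pattern list,
  which cannot be redistributed here. An ingestion path for externally
  computed 881-column descriptor tables (`read_descriptor_table()`) is
  provided for parity studies.
* **Linear paths, FP2-style** (1024 bits): every simple path of 2–7 atoms,
  encoded as its element/bond-order sequence read in the lexicographically
  smaller direction, hashed and folded. Single atoms and rings as such
  contribute nothing.
* **Morgan / extended-connectivity, ECFP4-style** (2048 bits, radius 2):
  iterative neighborhood hashing from initial atom invariants (element,
  degree, attached hydrogens, formal charge, ring flag, aromatic flag).
  Environments that stop growing, and duplicate environments covering the
  same bond set, are dropped, following standard ECFP practice.

**Hashing and folding conventions.** Identifiers are hashed with 32-bit
FNV-1a (compiled in `src/fnv.cpp`) — a fixed, documented,
platform-independent choice, so fingerprints are reproducible bit-for-bit
across machines. A hash *h* folds to bit `h mod L`. Bit indices are
0-based internally; text dumps are written 1-based, which is the common
display convention. Because the hash is a convention rather than chemistry,
bit-level parity with other toolkits is not promised — only structural
parity (the same environments and paths are indexed), which is what the
test suite asserts via independent enumeration oracles.

The three blocks concatenate in fixed order — substructure keys (881),
paths (1024), Morgan (2048) — to 3953 bits. Run-time ablations (`noFP2`,
`noPubChem`, `noMF`, `onlyMF`, `onlyPubChem`) drop named blocks.

**SMILES parsing** is delegated to OpenBabel (via ChemmineOB); the package
reads the emitted connection table into a light graph. Aromaticity is
perceived in-package on chordless rings of size 5–6 with a Hückel-style
pi-electron count (an atom carrying a double bond contributes one
electron, an N/O/S lone pair two; a saturated carbon disqualifies the
ring). This model covers the standard aromatics (benzene, pyridine, furan,
pyrrole, thiophene, fused benzenoids) but is deliberately simple: exotic
aromatic systems (azulenes, mesoionics) may be mis-perceived, which shifts
some Morgan/path bits. The SMARTS section of the key table is evaluated by
OpenBabel itself and is unaffected.

# Target representation: pocket composition

Template pockets arrive as precomputed metadata (structural pocket
detection is upstream of this package): per pocket a TM-score to the
target, the aligned fraction of the template, a sequence identity, an
upstream rank score, the pocket residues, and the bound template ligands.
Filtering keeps pockets with TM-score > 0.6 and at least 80% of the
template aligned, optionally drops templates above a sequence-identity
cutoff (benchmarking mode), and retains at most the top 75 by rank score.

The target feature is the mean amino-acid composition of the accepted
pockets: a 20-vector over the standard amino acids in alphabetical
one-letter order, summing to 1. Whether the mean should weight pockets
equally or pool residues is genuinely open; the default weights pockets
equally (robust to pocket-size imbalance), and `method = "pooled"` is
available as a sensitivity check.

Sequence identity (used for the cross-validation exclusion) is the
identical-position fraction of a global alignment under a fixed scoring
scheme (BLOSUM62, gap opening 10, extension 0.5); the two sequences are
ordered canonically first, so the function is exactly symmetric.

# The boosted scoring model

A target–ligand pair is the 20-dim composition prepended to the combined
fingerprint: 3973 features in the full configuration. Gradient-boosted
regression trees are fit to squared error against the 0/1 binder label —
regression rather than classification because the scores must *rank*
molecules, and class predictions would leave predicted positives in random
order. Two presets are pinned: `deep` (3000 trees, depth 6, learning rate
0.05) and `fast` (300 trees, same depth and rate). The learner is xgboost:
tree induction is a commodity here and is configured, not re-implemented.
Training rows are put into a canonical order before fitting so the model
is invariant to input pair order; `nthread = 1` and the exact tree method
make training deterministic for a given seed.

Training sets follow the benchmark-standard recipe: all actives (label 1)
and a seeded uniform subsample of ~10% of decoys (label 0) per target —
per-target rather than pooled, so every target contributes negatives; the
pooled alternative would let ligand-rich targets dominate. Evaluation is
leave-one-out over targets with an exclusion rule: any training target
with sequence identity above 0.8 to the test target is dropped.

# The similarity screen

The target's accepted pockets contribute their bound ligands; after
deduplication each is fingerprinted (Morgan by default) and a candidate's
score is the **maximum Tanimoto coefficient** over the template set. The
aggregation is pluggable (`mean_topk` is provided) because the ancestor
method's exact template-similarity formula lives in prior work and is not
restated here; the maximum preserves the rank semantics — monotone in
every pairwise similarity, 1 when the candidate *is* a template ligand —
without inventing a formula. Similarity screening defaults to the Morgan
fingerprint alone rather than the combined blocks: a similarity score
weights every bit equally, so concatenating less informative blocks
dilutes the signal (the boosted scorer, which learns per-feature weights,
is where combination pays off).

# Calibration and meta-combination

Raw scores from different methods are not comparable (a Tanimoto
coefficient vs a boosted-regression output), so each method is calibrated
separately against its own pooled cross-validation predictions: isotonic
regression of the binary label on the score. The isotonic fit *is* the
empirical precision of the pool as a monotone non-decreasing function of
the score, is parameter-free, and recovers block precisions exactly on
piecewise-constant pools; whether one should smooth or bin first is
unknowable from the construction alone, so the parameter-free choice is
the default and a logistic alternative sits behind `family = "logistic"`.
Out-of-range scores take the boundary precision; outputs are clamped to
[0, 1].

The meta-screen then keeps, per molecule, the **best predicted precision**
across methods, recording the winning method. A molecule missing from one
method's screen is combined over the methods that scored it.

A corner case worth noting: a pooled set with a single class admits no
meaningful isotonic fit. Rather than erroring, a degenerate pool yields
the constant class-rate mapping — an all-positive pool has a well-defined
empirical precision of 1, and the constant mapping is its limit.

# Screening metrics

For a ranked screen (score descending, ties broken by ligand identifier so
ranks are reproducible):

* **EF~x~** — the fraction of all actives in the top `ceiling(x·N)`
  entries, divided by *x*. The ceiling guarantees a non-empty selection
  for any *x* > 0 and matches the "top 1% of the list" reading when *N* is
  not a multiple of 100 (the alternative rounding is not distinguishable
  from the construction; ceiling is pinned and documented). Random ranking
  gives ≈ 1; the cap is `min(1/x, N/N_actives)`.
* **ROCEF~1%~** — the true-positive rate at the first rank where the
  false-positive fraction reaches 1%, divided by 0.01; its maximum is 100
  regardless of the decoy:active ratio.
* **AUPR** — average precision (step integration, no linear
  interpolation; interpolating a PR curve overestimates the area).

Per-target values aggregate as unweighted means with standard deviations;
targets missing a metric are excluded from that metric's mean with a
message.

# The synthetic benchmark

The generator builds desk-scale, benchmark-shaped screens so the whole
pipeline is testable without external downloads. Molecules are assembled
from a validated grammar: a ring core (benzene, pyridine, thiophene,
furan, cyclohexane, piperidine), a linker, a second ring, and
chain/heteroatom decorations; below 12 heavy atoms plain heteroatom chains
are used. Every emitted SMILES parses; sizes land exactly in the requested
range.

The planted signal lives where the methods look:

* Each target has a **scaffold** (core, linker, second ring). Actives are
  the scaffold with random decorations (with probability
  `signal_strength`; at 0 they are drawn from the decoy distribution, an
  exact null). Decoys are grammar molecules with random scaffolds.
  Template ligands are noisy scaffold copies attached to the pockets.
* Scaffolds are drawn from a small pool shared round-robin across targets,
  so targets fall into chemotype families the way real benchmark
  collections contain target families. This is what makes the held-out
  target learnable: a scorer trained on the other targets has seen the
  test target's chemotype, just never its target.
* Pocket residue composition is coupled to the scaffold's ring types
  through a fixed ring-to-residue map (70% of the residue mass on the
  associated residues), so pocket composition carries chemotype
  information.
* Ligand identifiers are a seeded random permutation across each target's
  actives and decoys, so identifier-based tie-breaking cannot leak the
  label into the null.

Defaults mirror the common benchmark regimes: 60 decoys per active (a 30
preset mirrors the smaller-ratio collections), 5 actives per target, 10
targets, active:decoy ratio ≈ 0.016 at the default ratio. Template
metadata includes below-threshold records so the filters are exercised;
target sequences are random (hence mutually dissimilar); `n_clone_pairs`
plants near-duplicate sequence pairs to exercise the identity exclusion.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: property-matched decoy selection (synthetic
decoys are matched only in the weak sense of coming from the same
grammar), real chemical diversity and tautomer/stereochemistry effects, 3D
binding determinants invisible to fingerprints, assay noise in labels, and
realistic sequence–pocket relationships. Recovery results on the synthetic
benchmark demonstrate that the machinery is correct and sensitive, not
that any particular accuracy carries over to real screens.

# Problem sizes and numerical choices

The test suite and the reproduction script run: the signal-1 benchmark at
10 targets × (5 actives + 300 decoys) with the `fast` (300-tree) preset
and full 3973-dim features, and the signal-0 null at 20 targets with the
Morgan-only ablation — sizes chosen so the full suite runs comfortably on
a laptop-class single core while leaving the planted signal clearly
detectable. The null check compares the mean EF~1%~ against the central
95% range of its hypergeometric distribution (at N = 305 and 5 actives the
top slice holds 4 entries, so the null mean EF is ≈ 1.3, not 1 — the
ceiling in EF's definition is visible here).

Other numerical choices: compositions are validated to sum to 1 within
1e-9; isotonic breakpoints collapse ties by maximum; interpolation between
breakpoints is linear (monotone between monotone knots); xgboost runs
single-threaded with the exact tree method for determinism; all
randomness flows from explicit integer seeds (`withr::with_seed`), and
derived seeds stay below 2^31.

# Known limitations

* The aromaticity model is Hückel-lite (see above); molecules outside the
  generator's chemistry may have some bits shifted relative to a
  full-perception toolkit.
* The synthetic key table is structurally, not literally, the published
  881-key set; absolute substructure-key bit patterns are not comparable
  with external descriptor dumps unless ingested via
  `read_descriptor_table()`.
* The boosted scorer's cross-target generalization depends on shared
  chemotypes between training and test targets; for a target with a truly
  novel chemotype the similarity route degrades gracefully (scores near 0)
  while the scorer's output is uninformative — the calibrated
  meta-combination is the intended guard, since uninformative scores map
  to low predicted precision.
* Pocket detection, structure alignment and threading are out of scope;
  the package trusts the upstream metadata it is given.
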