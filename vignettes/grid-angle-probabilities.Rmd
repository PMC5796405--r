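---
title: "Grid-based backbone angle probabilities: model, scoring and design notes"
author: "torsionGrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based backbone angle probabilities: model, scoring and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsionGrid)
```

## The problem and the model

Protein backbone conformation is fully described by four per-residue
angles: the bond-rotation dihedrals $\phi$ (about N--C$\alpha$, atoms
C$_{i-1}$, N$_i$, CA$_i$, C$_i$) and $\psi$ (about C$\alpha$--C, atoms
N$_i$, CA$_i$, C$_i$, N$_{i+1}$), and the C$\alpha$-trace angles
$\theta$ (planar angle over CA$_{i-1}$, CA$_i$, CA$_{i+1}$) and $\tau$
(dihedral over CA$_{i-1}\ldots$CA$_{i+2}$, assigned here to residue
$i$). Real-valued angle predictors give a point estimate but no
confidence; this package instead treats prediction as fine-grained
classification. Each angle range is divided into fixed 5° bins — 72 bins
each for the dihedrals on $[-180°, 180°)$ and 36 for $\theta$ on
$[0°, 180°]$ — and a single feedforward network maps per-residue feature
vectors to all four per-angle probability distributions simultaneously
through four softmax blocks, 252 output units in total. The probability
vector is the product of interest: its argmax is the predicted bin, its
spread is a per-residue confidence measure.

Two downstream consumers motivate the probabilities:

* **Disorder discrimination.** Residues in intrinsically disordered
  regions have no single backbone conformation, so a well-calibrated
  predictor should spread probability mass across many bins there. The
  per-residue score is the Shannon entropy $-\sum_i P_i \log P_i$,
  normalised by $\log K$ (the uniform-distribution entropy over the $K$
  bins) to $[0, 1]$, then smoothed by a sliding window of 21 residues
  centred at the query. Discrimination against binary disorder labels is
  evaluated by rank-based AUC with midrank ties; because AUC depends only
  on score order, the normalisation provably cannot change it (a property
  the test suite asserts under several monotone transforms).

* **Model ranking.** For a candidate model structure the pseudo-energy
  $\mathrm{PE} = \sum_i \log(P_i / P^0_i)$ accumulates, over residues,
  the log-ratio of the predicted probability at the bin the model
  actually occupies to the background probability $P^0$ of that bin.
  Higher is better; the score is zero exactly when the profile carries no
  information beyond the background. Ranking quality is measured by the
  Pearson correlation between PE and a superposition-based quality score
  (GDT-style: mean fraction of residues within 1/2/4/8 Å after Kabsch
  superposition) plus the per-residue S-score $1/(1 + (d_i/d_0)^2)$,
  $d_0 = 3$ Å.

## Features

Two feature sets are supported. **M1** uses only sequence-derived input:
7 physicochemical amino-acid properties (steric parameter,
hydrophobicity, volume, polarizability, isoelectric point, helix and
sheet probability; the table ships in `inst/extdata/aa_properties.tsv`)
plus the 20 PSSM log-odds scores, 27 values per residue, concatenated
over a sliding window of 13 residues: 351 inputs. **M2** adds predicted
structure properties in place of the fixed amino-acid table: 20 PSSM
scores plus 18 per-residue structure values (3 secondary-structure
probabilities, RSA, sin/cos of the four backbone angles, 2 contact
numbers, 4 half-sphere exposures), 38 values over a window of 7: 266
inputs. The structure-property table is an *input* (read from a
tab-delimited file or assembled with `propsFromAngles()`); this package
never runs the upstream predictors that produce it.

PSSM scores are squashed through the logistic $1/(1+e^{-x})$ by default
(`transformPssm()` also offers raw and z-score modes): the source files
carry integer log-odds on roughly $[-10, 10]$ and sigmoid hidden units
saturate on raw inputs. Windows are zero-padded past the chain termini;
repeating the terminal residue was the alternative, but padding with
zeros keeps the "no residue here" signal distinguishable from any real
residue.

## Network and training

The architecture is three hidden layers of 150 sigmoid units. Hidden
layers are initialised by greedy stacked sparse-autoencoder pretraining
(learning rate 0.05, 30 epochs): each layer's autoencoder has a sigmoid
encoder, a linear decoder trained on squared reconstruction error, L2
weight decay ($10^{-4}$) and a KL penalty pulling the mean encoder
activation toward a sparsity target of 0.05 (weight 0.1). Fine-tuning is
minibatch SGD (batch 64, 100 epochs) on the cross-entropy summed over
the four softmax blocks, with per-layer learning rates 1.0, 0.5, 0.2 and
0.05 applied to hidden-1, hidden-2, hidden-3 and the output layer
respectively. Residues with an undefined angle are masked from that
angle's block only; their other blocks still contribute loss and
gradient.

Numerical choices worth recording:

* **Initialisation.** Weights are Glorot-uniform with the ×4 gain
  recommended for sigmoid units. With the plain (tanh-calibrated) Glorot
  range the forward signal shrinks several-fold per sigmoid layer and
  training stalls at the class marginals; the ×4 gain compensates the
  sigmoid's slope of 1/4 at the origin and restores signal propagation
  through all three layers.
* **Loss scaling.** Per-block cross-entropy is averaged over the
  minibatch and summed over blocks; weight decay enters the loss as
  $\lambda/2 \sum \|W\|^2$ so the analytic gradients (verified against
  central finite differences to $10^{-5}$ relative in the tests) are
  exact.
* **Determinism.** Every random draw — initialisation, batch shuffling,
  all synthetic generators — flows from an explicit integer seed through
  a scoped RNG that restores the caller's state. Training the same data
  with the same configuration is bitwise reproducible, and a saved model
  archive (binary with an embedded JSON copy of its configuration)
  round-trips exactly.
* **Ties and edges.** Argmax and top-$k$ ties resolve to the lowest bin
  index. Bins are half-open $[lo, lo + w)$ with $\theta = 180°$ assigned
  to the closed last $\theta$ bin, and dihedrals live on $[-180°, 180°)$
  with $+180°$ wrapped to $-180°$, so every attainable angle has exactly
  one bin. The two-state splits used for coarse evaluation ($\phi$:
  $[0°, 150°]$ vs the rest; $\psi$: $[-100°, 60°]$ vs the rest) treat
  the listed interval as closed at both ends.

Cross-validation (default ten-fold) splits whole chains, never residues,
so evaluation residues are not neighbours of training residues; the
pooled summary divides total correct counts by total residues, i.e. the
residue-weighted mean over folds.

## Geometry conventions

`parseBackbone()` reads fixed-width PDB ATOM records (first model only,
first alternate location, insertion-coded residues in file order) and
drops residues missing any of N/CA/C with a warning. Dihedrals follow
the IUPAC sign convention and are computed by projecting the outer bonds
onto the plane normal to the central bond; an independent closed-form
`atan2` oracle and the bio3d implementation back both the unit tests and
the acceptance checks. Chain breaks — a residue-numbering gap or a
consecutive CA--CA distance above 4.5 Å — invalidate every angle whose
atom span crosses the break. The single deliberate exception is decoy
scoring (`scoreDecoy()`): a decoy models the full target sequence, and
treating its geometric distortion as a chain break would remove exactly
the residues that should pay the PE penalty, so there the distance
criterion is disabled by default (residue-numbering gaps still apply).
$\tau$ could equally be anchored at residue $i$ or $i+1$; this package
assigns the dihedral over CA$_{i-1}\ldots$CA$_{i+2}$ to residue $i$,
which makes $\tau$ undefined at the first and last two residues.

The background distribution $P^0$ is the pseudocounted bin frequency
(pseudocount 1 per bin) over a user-supplied corpus of observed angle
tables; the pseudocount keeps every bin strictly positive so the
log-ratio is always finite. Predicted probabilities below $10^{-8}$ at
an occupied bin are floored at that value and the number of floored
residues is reported. The combined PE-score is the sum of the four
per-angle scores; per-angle scores remain the primary quantities. A
per-residue-mean variant is offered because model lengths vary, but the
sum is the canonical definition.

## What the synthetic data emulate — and what they do not

All tests and the acceptance script run from generated data:

* `buildFragment()` constructs backbones from ideal internal coordinates
  (N--CA 1.458 Å, CA--C 1.525 Å, C--N 1.329 Å, standard bond angles,
  $\omega = 180°$) with $(\phi, \psi) = (-57°, -47°)$ for helix,
  $(-120°, 120°)$ for strand and seeded-uniform coil, so recomputing
  angles from the coordinates must recover the generating values — a
  closed loop that validates the geometry code without any downloaded
  structure.
* `makeTrainingSet()` draws residue classes uniformly (6 classes by
  default) and maps each class deterministically to one
  $(\phi,\psi,\theta,\tau)$ quadruple in distinct bins; features are the
  one-hot class indicator embedded in the M1 layout plus Gaussian noise
  of sd 0.05. Because the mapping is deterministic, a working network
  must approach perfect held-out bin accuracy — the package's parameter
  recovery check trains on 1600 residues and evaluates 400 held-out
  residues (about a minute on one CPU), reaching accuracy 1.0 for all
  four angles.
* `makeDisorderProfiles()` lays disorder labels in contiguous segments
  of 10–30 residues (disorder is annotated regionally in real data,
  which is what makes window-21 smoothing meaningful). Disordered
  residues draw near-uniform distributions (symmetric Dirichlet,
  concentration 5); ordered residues interpolate toward a sharply
  peaked distribution with weight equal to the separation parameter, so
  separation 0 makes the classes identically distributed (AUC ≈ 0.5)
  and separation 1 drives the windowed τ-entropy AUC above 0.95.
* `makeDecoys()` perturbs every backbone atom with isotropic Gaussian
  noise at σ ∈ {0.5, 1, 2, 4, 8} Å and applies a random rigid motion per
  decoy so superposition is genuinely exercised. With a profile
  concentrated at the native bins, the combined PE-score correlates with
  the GDT-style score at $r > 0.8$ across the ladder.

These generators establish that the machinery is correct, not that the
trained network predicts real proteins at any particular accuracy:
synthetic classes are linearly separable, synthetic disorder is sampled
from exactly the distributions the entropy score is sensitive to, and
Gaussian decoys are not physical decoys. Published benchmark numbers on
real datasets (bin accuracies near 0.19–0.37, disorder AUC near 0.77,
ranking correlations near 0.5) require full-scale training corpora,
database-derived PSSMs and external decoy sets, and are out of scope
here by design.

## Parameter reference

| Parameter | Default | Meaning |
|---|---|---|
| bin width | 5° | divides 360° and 180°; 10° supported throughout |
| hidden layers | 150, 150, 150 | sigmoid units |
| pretrain LR / epochs | 0.05 / 30 | sparse autoencoder per layer |
| fine-tune LRs | 1.0, 0.5, 0.2, 0.05 | hidden-1/2/3, output |
| fine-tune epochs / batch | 100 / 64 | minibatch SGD |
| sparsity target / weight | 0.05 / 0.1 | KL penalty on mean activation |
| weight decay | 1e-4 | L2 on all weights |
| M1 window / M2 window | 13 / 7 | residues, zero-padded |
| entropy window | 21 | residues, shrinking at termini |
| S-score d0 | 3 Å | half-quality distance |
| GDT cutoffs | 1, 2, 4, 8 Å | fractions averaged |
| PE probability floor | 1e-8 | floored occurrences are counted |
| background pseudocount | 1 | per bin |
| CA–CA break threshold | 4.5 Å | parsing real structures only |

## Known limitations

* The window average shrinks at chain termini rather than padding;
  zero-padding would artificially deflate terminal entropy and was
  rejected.
* The GDT-style score uses the single best superposition over all
  residues, not the cutoff-specific superposition searches of the
  official assessment pipeline, and decoys are matched to the native by
  residue numbering, not structural alignment — appropriate for decoys
  of the target sequence, not for cross-protein comparison.
* No combined disorder score across the four angles was ever validated;
  `combinedDisorderScore()` therefore refuses to run without an explicit
  `unvalidated = TRUE`.
* Only the first model and first alternate location of a PDB file are
  read; mmCIF and side-chain geometry are out of scope.
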