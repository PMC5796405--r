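Package: torsionGrid
Title: Grid-Based Backbone Torsion-Angle Probabilities, Disorder Entropy and Model Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts per-residue probability distributions of the four protein
    backbone angles (phi, psi, theta, tau) over fixed 5-degree bins with a
    feedforward neural network initialised by stacked sparse-autoencoder
    pretraining. The predicted bin probabilities feed two downstream analyses:
    a normalised Shannon-entropy score with sliding-window averaging for
    discriminating intrinsically disordered regions, and a pseudo-energy
    (PE) score, the summed log-ratio of predicted to background bin
    probability at the bins occupied by a candidate model structure, for
    ranking decoy models against superposition-based quality scores.
    Includes backbone geometry (dihedral and planar angles from PDB
    coordinates with chain-break handling), PSI-BLAST PSSM and
    structure-property feature construction, Kabsch superposition with
    S-score and GDT-style quality, and a synthetic-data module that generates
    ideal-geometry fragments, learnable sequence-to-angle training sets,
    disorder-labelled profiles and noise-graded decoys for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), pROC, bio3d, Biostrings, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'binning.R'
    'metrics.R'
    'features.R'
    'io.R'
    'network.R'
    'disorder.R'
    'model_qa.R'
    'synthetic.R'
    'cli.R'
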