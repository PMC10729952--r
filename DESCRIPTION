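Package: cgraphdesign
Title: Contact-Map Graph Neural Networks for Fixed-Backbone Protein Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fixed-backbone protein sequence design (inverse folding) with a
    graph neural network built on distance-cutoff contact maps of virtual
    C-beta atoms.  Provides backbone readers for PDB and mmCIF, a synthetic
    backbone generator with a deterministic geometry-to-sequence labeling
    rule, rotation- and translation-invariant node and edge featurization
    (local frames, radial basis distance encodings, relative-orientation
    quaternions, learnable virtual atoms), a message-passing block stack
    with symmetric and second-order edge updates merged by selective
    kernels, a pure-R reverse-mode autodiff training loop (AdamW, OneCycle
    schedule), sequence sampling, and a design-quality evaluation battery:
    perplexity, recovery, composition deviation, BLOSUM-based scoring and
    log-odds confusion matrices, SEG low-complexity detection, solvent
    accessibility core/surface splits, hydrophobicity conservation, Kabsch
    RMSD and GDT-TS.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
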