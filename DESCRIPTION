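Package: dbnQA
Title: Single-Model Protein Quality Assessment with Deep Belief Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the quality (GDT-TS) of a single protein structural
    model from structural, physio-chemical and knowledge-based energy
    features using a deep belief network: two stacked restricted Boltzmann
    machines pretrained by contrastive divergence and a logistic output
    node fine-tuned by BFGS against mean squared error. Includes readers
    for PDB models, FASTA targets and external score tables; Kabsch
    superposition, Shrake-Rupley solvent accessible surface area and
    dihedral-window secondary structure assignment; GDT-TS, TM-score and
    RMSD structure comparison; decoy-ranking evaluation statistics
    (per-target correlation and loss, top-k selection, Z-score sums,
    Wilcoxon signed-rank tests); and a synthetic decoy/feature simulator
    so the whole pipeline can be trained and validated without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
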