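Package: xlinkmap
Title: Domain-Resolution Mapping of Protein-DNA Photo-Cross-Links by
    Site-Specific Protein Cleavage
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers which domains of a DNA-binding protein contact individual
    backbone phosphates of a promoter element, from site-specific
    photo-cross-linking experiments read out through single-site chemical
    cleavage of the protein. Models hydroxylamine digestion fragments and
    their gel migration (including co-migration ambiguities and their
    resolution by terminal tagging), propagates per-fragment cross-link
    calls into minimal consistent residue-interval contact assignments with
    ordinal intensity grading, projects contact architectures onto an ideal
    B-form DNA helix to classify groove-spanning contacts, and compares the
    contact architectures a protein adopts on two promoter variants. A
    synthetic-data module simulates noisy observation tables from ground-truth
    contact maps so the whole pipeline is testable end to end. Ships the
    construct panel, probe set and transcribed gel observations for the
    Drosophila SNAP190 subunit of SNAPc on the U6 snRNA gene PSEA promoter
    element, together with the corresponding U1 contact architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, StructuralPrediction, Proteomics, Transcription
RoxygenNote: 7.3.3
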