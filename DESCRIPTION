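Package: nucleoprofiler
Title: Candidate Nucleoid-Associated Protein Discovery from Label-Free
    Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A "ruling in" workflow for prioritising candidate
    nucleoid-associated proteins (NAPs) and global regulators from label-free
    LC-MS/MS surveys of isolated bacterial nucleoids. Computes emPAI
    (Exponentially Modified Protein Abundance Index) scores from peptide
    identification evidence via in-silico tryptic digestion and an
    instrument observability window, assigns proteins to five functional
    categories, applies an abundance threshold to annotated DNA-binding
    proteins and an amino-acid-composition DNA-binding screen to
    uncharacterised proteins, intersects biological replicates, and emits a
    ranked candidate table. Ships a synthetic-data generator with planted
    NAPs and ground truth so the whole pipeline is testable without raw
    mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
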