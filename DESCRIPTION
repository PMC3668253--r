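Package: bacsurf
Title: Bacterial Surfaceome Annotation from Membrane-Protein Predictor Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates bacterial proteomes with evidence collected from
    membrane-protein predictors (signal peptide, lipoprotein signal,
    transmembrane topology, cell-wall motif profiles, beta-barrel scores)
    and classifies each protein's subcellular localization and potential
    surface exposure. A Gram-positive protocol assigns PSE / secreted /
    membrane / cytoplasm categories from transmembrane loop exposure and
    cell-wall anchoring motifs; a Gram-negative protocol adds outer-membrane
    beta-barrel consensus scoring, Tat signals, Asp+2 lipoprotein sorting
    and inner-membrane loop tagging. Predictor outputs are parsed from
    their raw text or HTML result files; a deterministic synthetic-proteome
    generator produces sequences, ground truth and matching predictor
    fixtures so the full pipeline is testable without external binaries.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    xml2,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
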