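Package: ldrconsensus
Title: Consensus Annotation of Long Intrinsically Disordered Regions from
    X-ray Missing Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combines missing-residue observations from multiple X-ray
    crystal chains mapped to the same protein into per-residue disorder
    consensus tracks under a permissive "majority" rule and a conservative
    "zero" rule, extracts long (>=30 residue) and short (5-29 residue)
    disordered regions, and characterises them: dataset composition and
    disorder content accounting, region length and localization summaries,
    amino-acid enrichment, per-residue benchmarking of disorder predictors
    (MCC, F1, balanced accuracy, precision, specificity, recall),
    Fisher's-exact GO-term enrichment restricted to the upper ontology
    levels with Bonferroni correction, and correlation of structure-quality
    metrics with disorder content. Includes parsers for PDB (SEQRES +
    REMARK 465) and mmCIF observation records, SIFTS-like chain-to-protein
    mappings, and a seeded synthetic-ensemble generator that emits
    ground-truth disorder architectures in the same file formats so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
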