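Package: genoground
Title: Deterministic Core for Evidence-Grounded Genomics Question Answering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rule-based building blocks for evidence-grounded answering of
    genomics questions without any language-model dependency: regex-driven
    biomedical entity extraction (rsIDs, genomic coordinates, Ensembl IDs,
    miRNAs, drugs), two-stage amino-acid-sequence-to-gene resolution
    (gapless window scan plus k-mer index search), citation-grounded
    statement verification against serialized evidence documents,
    residue-level protein druggability tracks (SASA polarity index, pocket
    scores, pLDDT bands, disorder and MoRF consensus, cysteine
    chemoproteomics summaries), annotation summarization and drug-target
    evidence scoring (farthest-point sampling of GO terms, Fisher
    enrichment, pChEMBL potency), a multiple-choice benchmark generator
    with bootstrap scoring, and an adversarial perturbation harness that
    stress-tests the verifier.  All inputs can be emulated by seeded
    synthetic-fixture generators, so the whole surface runs offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
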