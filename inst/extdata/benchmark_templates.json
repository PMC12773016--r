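{
  "gene_annotation": {
    "stem": "Which chromosome carries the gene {entity}?",
    "expected_tool": "gene_annotation",
    "deterministic_setup": false,
    "database": "gene annotation"
  },
  "variant_annotation": {
    "stem": "Which gene harbors the variant {entity}?",
    "expected_tool": "variant_annotation",
    "deterministic_setup": false,
    "database": "variant annotation"
  },
  "disease_association": {
    "stem": "Which disease is primarily associated with {entity}?",
    "expected_tool": "disease_catalog",
    "deterministic_setup": false,
    "database": "disease catalog"
  },
  "pathogenic_variants": {
    "stem": "What is the clinical significance reported for {entity}?",
    "expected_tool": "clinical_variants",
    "deterministic_setup": true,
    "database": "the curated pathogenic-variant set"
  },
  "trait_associations": {
    "stem": "Which trait shows the strongest reported association with {entity}?",
    "expected_tool": "trait_catalog",
    "deterministic_setup": false,
    "database": "trait catalog"
  },
  "drug_targets": {
    "stem": "Which gene is the highest-evidence human target of {entity}?",
    "expected_tool": "drug_target_evidence",
    "deterministic_setup": false,
    "database": "drug-target evidence"
  },
  "protein_structure": {
    "stem": "Which residue of {entity} lies in its most druggable predicted pocket?",
    "expected_tool": "protein_tracks",
    "deterministic_setup": false,
    "database": "protein structure"
  },
  "mirna_targets": {
    "stem": "Which gene is a predicted target of {entity}?",
    "expected_tool": "mirna_targets",
    "deterministic_setup": true,
    "database": "the miRNA target predictions"
  }
}
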