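{
  "comment": "Published real-data benchmark values that require the raw sequencing data (GEO accession GSE255595) to reproduce. They are recorded here as accession-gated targets and are NOT desk-scale test expectations.",
  "accession": "GSE255595",
  "rms": {
    "full_sites_18S": 10,
    "full_sites_28S": 10,
    "partial_sites_18S": 14,
    "partial_sites_28S": 9,
    "conserved_full_18S": 8,
    "conserved_full_28S": 7,
    "unique_full_18S": 2,
    "unique_full_28S": 3
  },
  "translatome_fbl1_kd": {
    "rna_up": 356,
    "rna_down": 566,
    "translation_up": 1240,
    "translation_down": 862,
    "te_down_genes": 652,
    "scatter_r2": 0.1041
  },
  "translatome_fbl2_kd": {
    "rna_up": 342,
    "rna_down": 305,
    "translation_up": 1524,
    "translation_down": 948,
    "te_down_genes": 765,
    "scatter_r2": 0.0703
  },
  "qc": {
    "control_rna_ribo_r_squared": 0.8262
  }
}
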