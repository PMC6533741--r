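{
  "file": "clp_gene_catalog.tsv",
  "n_genes": 172,
  "columns": ["symbol", "gene_name", "locus", "syndromic_status", "syndrome_names"],
  "notes": "Curated human CL/P candidate gene catalog; one row per distinct gene symbol, transcribed verbatim from the published summary table."
}
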