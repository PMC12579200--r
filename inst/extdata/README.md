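# Packaged fixtures

- `table1_dnsnvs.tsv` — the published per-variant table of 34 candidate de
  novo SNVs (proband, hg19/hg38 positions, HGVS, consequence class, gene,
  gnomAD NFE allele frequency, CADD PHRED). `population_af` keeps the
  literal `Absent` entries, which are distinct from a frequency of 0.
- `class_probabilities_synthetic.tsv` — SYNTHETIC stand-in for the
  mutational-model per-class dnSNV probabilities. The published human
  per-gene probability tables are external data; these per-class totals are
  back-derived from the study's reported observed/expected enrichment
  ratios (probability = observed / ratio / (2 x 36)). Use
  `build_probability_table()` for model-derived probabilities on gene
  models you supply.
- `brain_tpm_synthetic.tsv` — SYNTHETIC brain-tissue TPM matrix for the 34
  candidate genes (every gene expressed in every tissue), standing in for a
  live GTEx expression query; exercises `expression_presence()`.
- `reference_lists/` — gene lists previously associated with OCD (rare
  de novo variant and GWAS sources) and 11 related psychiatric disorders,
  one upper-case symbol per line, as used by `overlap_genes()`.
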