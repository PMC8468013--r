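# Small synthetic discovery run: 4 species, 9 genomes, one planted
# clade-unique marker in the target species sp01.
seed: 7
simulate:
  n_species: 4
  genomes_per_species: [3, 2, 2, 2]
  n_core_genes: 12
  n_accessory_genes: 6
  n_unique_genes: 4
  gene_length_range: [250, 400]
  marker_length: 700
phylogeny:
  n_clusters: 8
qpcr:
  true_slope: -3.530
  true_intercept: 36.906
  noise_sd: 0.1
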