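gene_symbol: GENE1
disease: MONDO:0000001
mode_of_inheritance: autosomal_recessive
molecular_mechanism: loss_of_function
pathways:
- GO:0003824
policy:
  allow_cross_class_stacking: no
  hypomorph_downgrade: yes
  grid_step: 5.0
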