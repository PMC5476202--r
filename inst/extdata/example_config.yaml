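# Desk-scale three-species co-culture study (see ?sim_config for all fields)
n_species: 3
genome_length_bp: 60000
n_genes: 120
gene_length_range: [300, 450]
divergence: 0.10
depth_mono: 20000
depth_mixed: 20000
n_replicates: 3
straw_induction_fold: 5
mixed_down_fold: 4
seed: 7
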