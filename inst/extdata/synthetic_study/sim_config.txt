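n_chroms=2
chrom_length=2000000
n_genes=800
gene_length_median=2000
gene_length_sigma=0.5
prop_coding=0.8
annot_coverage=0.05
annot_length_median=1000
annot_length_sigma=0.5
n_hits=80
rho=0.5
dist_bp=5000
n_reps=1000
seed=42
n_traits=2
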