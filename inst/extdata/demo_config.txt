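# demo pipeline configuration: simulate, infer founder probabilities,
# run the multi-QTL scan, fit the final founder-effect model
significance_threshold = 3.2
cofactor_exclusion_window = 10
rng_seed = 1
genotyping_error = 0.01
max_scan_iterations = 20
n_chrom = 7
chrom_length_cM = 150
marker_spacing_cM = 5
lines_per_subpop = 153
replicates = 4
heritability = 0.75
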