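quantity,value
total_heterotypic,1967
total_homotypic,127
homotypic_positive_patients,6
median_homotypic_per_sample,2.5
max_homotypic_per_sample,99
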