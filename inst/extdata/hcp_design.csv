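key,value
n_mz_pairs,121
n_dz_pairs,67
n_singletons,556
n_total_individuals,932
age_mean,28.8
age_sd,3.6
sex_ratio,0.4496
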