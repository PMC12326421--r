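measure,mean,sd,a2,c2,e2,a2_lo,a2_hi,c2_lo,c2_hi,e2_lo,e2_hi,ci_anomaly
cog_crystallized,109.5,16.9,0.39,0.39,0.22,0.24,0.54,0.25,0.51,0.17,0.22,0
cog_fluid,105.3,17.3,0.13,0.40,0.46,0.00,0.37,0.07,0.39,0.39,0.64,1
cog_total,112.7,20.7,0.26,0.42,0.32,0.05,0.45,0.27,0.56,0.25,0.42,0
cog_early,106.4,16.2,0.13,0.40,0.46,0.00,0.37,0.22,0.54,0.36,0.58,0
working_memory,86.5,9.6,0.00,0.36,0.64,0.00,0.20,0.25,0.44,0.56,0.61,0
language,88.9,7.1,0.43,0.04,0.52,0.15,0.58,0.00,0.24,0.42,0.65,0
dexterity,100.1,9.8,0.19,0.10,0.72,0.00,0.43,0.00,0.34,0.57,0.86,0
strength,103.3,19.9,0.26,0.14,0.59,0.00,0.52,0.00,0.34,0.47,0.74,0
endurance,107.5,14.2,0.43,0.00,0.57,0.19,0.54,0.00,0.27,0.46,0.70,0
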