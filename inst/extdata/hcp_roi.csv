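measure,mean,sd,a2_notbv,c2_notbv,e2_notbv,a2_tbv,c2_tbv,e2_tbv
left_cerebellum_cortex,50294.20,5079.79,0.84,0.04,0.13,0.76,0.08,0.16
left_cerebellum_white_matter,13124.25,1470.86,0.79,0.00,0.21,0.74,0.00,0.26
right_cerebellum_cortex,50449.35,5203.37,0.78,0.06,0.16,0.73,0.10,0.17
right_cerebellum_white_matter,13229.86,1498.39,0.81,0.00,0.19,0.76,0.00,0.24
total_vermis,5547.65,640.50,0.64,0.16,0.20,0.63,0.12,0.25
left_i_iv,3155.33,462.65,0.62,0.00,0.38,0.57,0.00,0.43
left_v,3429.21,508.23,0.47,0.13,0.40,0.44,0.10,0.46
left_vi,7482.64,1129.54,0.79,0.02,0.20,0.75,0.03,0.23
left_crus_i,11855.26,1618.97,0.86,0.00,0.14,0.83,0.00,0.17
left_crus_ii,7877.19,1231.52,0.73,0.00,0.27,0.73,0.00,0.27
left_viib,4729.25,694.35,0.56,0.00,0.44,0.52,0.00,0.48
left_viiia,4910.43,887.58,0.70,0.00,0.30,0.66,0.00,0.34
left_viiib,3372.82,563.28,0.65,0.00,0.35,0.61,0.00,0.39
left_ix,2914.22,551.78,0.83,0.00,0.17,0.81,0.01,0.18
left_x,567.86,82.55,0.71,0.03,0.25,0.68,0.05,0.27
right_i_iv,3154.25,452.95,0.63,0.02,0.35,0.57,0.05,0.38
right_v,3203.31,471.59,0.72,0.00,0.28,0.68,0.00,0.32
right_vi,7523.64,1181.30,0.74,0.07,0.19,0.76,0.04,0.20
right_crus_i,12257.07,1725.69,0.81,0.00,0.19,0.75,0.04,0.21
right_crus_ii,8207.97,1210.89,0.73,0.00,0.27,0.73,0.00,0.27
right_viib,4359.36,643.27,0.57,0.00,0.43,0.55,0.00,0.45
right_viiia,4769.01,859.89,0.71,0.00,0.29,0.68,0.00,0.32
right_viiib,3445.03,562.69,0.53,0.09,0.38,0.51,0.07,0.41
right_ix,2959.41,568.51,0.79,0.00,0.21,0.75,0.04,0.21
right_x,570.31,85.63,0.55,0.14,0.30,0.45,0.22,0.34
vermis_vi,1652.61,240.79,0.46,0.23,0.31,0.45,0.24,0.31
vermis_vii,717.76,137.35,0.74,0.00,0.26,0.72,0.00,0.28
vermis_viii,1951.73,298.76,0.73,0.07,0.20,0.77,0.00,0.23
vermis_ix,856.36,115.52,0.70,0.04,0.26,0.68,0.00,0.32
vermis_x,369.20,59.03,0.63,0.00,0.37,0.56,0.00,0.44
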