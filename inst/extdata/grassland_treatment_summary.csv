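treatment,sum_mean,sum_se,awcd_mean,awcd_se,shannon_mean,shannon_se,simpson_mean,simpson_se
V1,50.7,3.54,1.35,0.09,3.31,0.03,0.96,0.00
V2,59.9,0.71,1.65,0.03,3.37,0.00,0.96,0.00
V3,54.2,0.91,1.45,0.04,3.31,0.03,0.96,0.00
V4,45.4,1.03,1.25,0.03,3.23,0.02,0.95,0.00
V5,48.9,0.93,1.35,0.03,3.34,0.01,0.96,0.00
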