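phenotype,a2,a2_se,d2,d2_se,h2_broad,h2_se,e2,e2_se
SWAN_H,0.687,0.118,0.226,0.225,0.912,0.014,0.088,0.014
CPRS_H,0.51,0.115,0.275,0.12,0.784,0.023,0.216,0.023
TRF_H,0.23,0.101,0.454,0.15,0.683,0.081,0.317,0.081
CTRS_H,0.225,0.144,0.492,0.185,0.717,0.09,0.283,0.09
SWAN_I,0.609,0.082,0.234,0.076,0.844,0.021,0.156,0.021
CPRS_I,0.369,0.099,0.369,0.107,0.738,0.047,0.262,0.047
TRF_I,0.176,0.068,0.482,0.115,0.658,0.07,0.342,0.07
CTRS_I,0.643,0.092,0.084,0.06,0.727,0.063,0.273,0.063
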