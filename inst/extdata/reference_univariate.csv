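phenotype,beta_sex,beta_sex_se,r2_sex,r_mz,r_dz,rater_r2,a2,d2,e2,h2_broad,lambda
SWAN_H,-0.14,0.032,0.02,0.899,0.364,NA,0.852,0.063,0.085,0.915,NA
CPRS_H,-0.23,0.019,0.053,0.781,0.311,NA,0.464,0.317,0.219,0.781,-3.158
TRF_H,-0.29,0.027,0.086,0.651,0.26,0.206,0,0.548,0.246,0.548,-3.579
CTRS_H,-0.29,0.027,0.088,0.718,0.093,0.331,0,0.484,0.185,0.484,-3.579
SWAN_I,-0.17,0.031,0.028,0.853,0.412,NA,0.794,0.059,0.147,0.853,NA
CPRS_I,-0.21,0.019,0.045,0.735,0.239,NA,0.221,0.514,0.265,0.735,-1.474
TRF_I,-0.23,0.028,0.053,0.67,0.05,0.242,0,0.515,0.244,0.515,-2.737
CTRS_I,-0.09,0.028,0.008,0.733,0.37,0.193,0.591,0,0.216,0.591,-1.053
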