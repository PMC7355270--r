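component,row,col,value
AD,CPRS_H,SWAN_H,0.888
AD,TRF_H,SWAN_H,0.999
AD,CTRS_H,SWAN_H,0.926
AD,SWAN_I,SWAN_H,0.922
AD,CPRS_I,SWAN_H,0.847
AD,TRF_I,SWAN_H,0.93
AD,CTRS_I,SWAN_H,0.936
AD,TRF_H,CPRS_H,0.799
AD,CTRS_H,CPRS_H,0.794
AD,SWAN_I,CPRS_H,0.907
AD,CPRS_I,CPRS_H,0.896
AD,TRF_I,CPRS_H,0.882
AD,CTRS_I,CPRS_H,0.909
AD,CTRS_H,TRF_H,0.814
AD,SWAN_I,TRF_H,0.842
AD,CPRS_I,TRF_H,0.877
AD,TRF_I,TRF_H,0.859
AD,CTRS_I,TRF_H,0.845
AD,SWAN_I,CTRS_H,0.935
AD,CPRS_I,CTRS_H,0.884
AD,TRF_I,CTRS_H,0.894
AD,CTRS_I,CTRS_H,0.835
AD,CPRS_I,SWAN_I,0.821
AD,TRF_I,SWAN_I,0.885
AD,CTRS_I,SWAN_I,0.865
AD,TRF_I,CPRS_I,0.863
AD,CTRS_I,CPRS_I,0.81
AD,CTRS_I,TRF_I,0.772
E,CPRS_H,SWAN_H,0.112
E,TRF_H,SWAN_H,0.001
E,CTRS_H,SWAN_H,0.074
E,SWAN_I,SWAN_H,0.078
E,CPRS_I,SWAN_H,0.153
E,TRF_I,SWAN_H,0.07
E,CTRS_I,SWAN_H,0.064
E,TRF_H,CPRS_H,0.201
E,CTRS_H,CPRS_H,0.206
E,SWAN_I,CPRS_H,0.093
E,CPRS_I,CPRS_H,0.104
E,TRF_I,CPRS_H,0.118
E,CTRS_I,CPRS_H,0.091
E,CTRS_H,TRF_H,0.186
E,SWAN_I,TRF_H,0.158
E,CPRS_I,TRF_H,0.123
E,TRF_I,TRF_H,0.141
E,CTRS_I,TRF_H,0.155
E,SWAN_I,CTRS_H,0.065
E,CPRS_I,CTRS_H,0.116
E,TRF_I,CTRS_H,0.106
E,CTRS_I,CTRS_H,0.165
E,CPRS_I,SWAN_I,0.179
E,TRF_I,SWAN_I,0.115
E,CTRS_I,SWAN_I,0.135
E,TRF_I,CPRS_I,0.137
E,CTRS_I,CPRS_I,0.19
E,CTRS_I,TRF_I,0.228
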