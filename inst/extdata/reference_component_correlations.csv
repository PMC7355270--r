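component,row,col,value
A,CPRS_H,SWAN_H,0.357
A,TRF_H,SWAN_H,0.369
A,CTRS_H,SWAN_H,0.304
A,SWAN_I,SWAN_H,0.995
A,CPRS_I,SWAN_H,0.392
A,TRF_I,SWAN_H,0.449
A,CTRS_I,SWAN_H,0.373
A,TRF_H,CPRS_H,0.159
A,CTRS_H,CPRS_H,0.031
A,SWAN_I,CPRS_H,0.401
A,CPRS_I,CPRS_H,0.967
A,TRF_I,CPRS_H,0.355
A,CTRS_I,CPRS_H,0.288
A,CTRS_H,TRF_H,0.942
A,SWAN_I,TRF_H,0.314
A,CPRS_I,TRF_H,0.296
A,TRF_I,TRF_H,0.372
A,CTRS_I,TRF_H,0.552
A,SWAN_I,CTRS_H,0.231
A,CPRS_I,CTRS_H,0.231
A,TRF_I,CTRS_H,0.354
A,CTRS_I,CTRS_H,0.59
A,CPRS_I,SWAN_I,0.418
A,TRF_I,SWAN_I,0.481
A,CTRS_I,SWAN_I,0.377
A,TRF_I,CPRS_I,0.454
A,CTRS_I,CPRS_I,0.449
A,CTRS_I,TRF_I,0.952
D,CPRS_H,SWAN_H,0.859
D,TRF_H,SWAN_H,0.651
D,CTRS_H,SWAN_H,0.643
D,SWAN_I,SWAN_H,0.504
D,CPRS_I,SWAN_H,0.436
D,TRF_I,SWAN_H,0.489
D,CTRS_I,SWAN_H,0.45
D,TRF_H,CPRS_H,0.595
D,CTRS_H,CPRS_H,0.704
D,SWAN_I,CPRS_H,0.576
D,CPRS_I,CPRS_H,0.214
D,TRF_I,CPRS_H,0.357
D,CTRS_I,CPRS_H,0.231
D,CTRS_H,TRF_H,0.824
D,SWAN_I,TRF_H,0.543
D,CPRS_I,TRF_H,0.509
D,TRF_I,TRF_H,0.925
D,CTRS_I,TRF_H,0.334
D,SWAN_I,CTRS_H,0.783
D,CPRS_I,CTRS_H,0.542
D,TRF_I,CTRS_H,0.754
D,CTRS_I,CTRS_H,0.373
D,CPRS_I,SWAN_I,0.81
D,TRF_I,SWAN_I,0.64
D,CTRS_I,SWAN_I,0.767
D,TRF_I,CPRS_I,0.741
D,CTRS_I,CPRS_I,0.957
D,CTRS_I,TRF_I,0.563
AD,CPRS_H,SWAN_H,0.502
AD,TRF_H,SWAN_H,0.45
AD,CTRS_H,SWAN_H,0.413
AD,SWAN_I,SWAN_H,0.866
AD,CPRS_I,SWAN_H,0.394
AD,TRF_I,SWAN_H,0.409
AD,CTRS_I,SWAN_H,0.38
AD,TRF_H,CPRS_H,0.361
AD,CTRS_H,CPRS_H,0.359
AD,SWAN_I,CPRS_H,0.454
AD,CPRS_I,CPRS_H,0.641
AD,TRF_I,CPRS_H,0.329
AD,CTRS_I,CPRS_H,0.265
AD,CTRS_H,TRF_H,0.862
AD,SWAN_I,TRF_H,0.388
AD,CPRS_I,TRF_H,0.414
AD,TRF_I,TRF_H,0.757
AD,CTRS_I,TRF_H,0.393
AD,SWAN_I,CTRS_H,0.452
AD,CPRS_I,CTRS_H,0.409
AD,TRF_I,CTRS_H,0.637
AD,CTRS_I,CTRS_H,0.416
AD,CPRS_I,SWAN_I,0.553
AD,TRF_I,SWAN_I,0.5
AD,CTRS_I,SWAN_I,0.439
AD,TRF_I,CPRS_I,0.615
AD,CTRS_I,CPRS_I,0.528
AD,CTRS_I,TRF_I,0.627
E,CPRS_H,SWAN_H,0.387
E,TRF_H,SWAN_H,0.002
E,CTRS_H,SWAN_H,0.169
E,SWAN_I,SWAN_H,0.549
E,CPRS_I,SWAN_H,0.384
E,TRF_I,SWAN_H,0.138
E,CTRS_I,SWAN_H,0.136
E,TRF_H,CPRS_H,0.254
E,CTRS_H,CPRS_H,0.283
E,SWAN_I,CPRS_H,0.207
E,CPRS_I,CPRS_H,0.239
E,TRF_I,CPRS_H,0.116
E,CTRS_I,CPRS_H,0.082
E,CTRS_H,TRF_H,0.46
E,SWAN_I,TRF_H,0.248
E,CPRS_I,TRF_H,0.143
E,TRF_I,TRF_H,0.254
E,CTRS_I,TRF_H,0.173
E,SWAN_I,CTRS_H,0.116
E,CPRS_I,CTRS_H,0.144
E,TRF_I,CTRS_H,0.167
E,CTRS_I,CTRS_H,0.213
E,CPRS_I,SWAN_I,0.471
E,TRF_I,SWAN_I,0.209
E,CTRS_I,SWAN_I,0.259
E,TRF_I,CPRS_I,0.227
E,CTRS_I,CPRS_I,0.34
E,CTRS_I,TRF_I,0.418
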