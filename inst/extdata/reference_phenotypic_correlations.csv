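component,row,col,value
phenotypic,CPRS_H,SWAN_H,0.478
phenotypic,TRF_H,SWAN_H,0.355
phenotypic,CTRS_H,SWAN_H,0.361
phenotypic,SWAN_I,SWAN_H,0.824
phenotypic,CPRS_I,SWAN_H,0.382
phenotypic,TRF_I,SWAN_H,0.341
phenotypic,CTRS_I,SWAN_H,0.33
phenotypic,TRF_H,CPRS_H,0.331
phenotypic,CTRS_H,CPRS_H,0.339
phenotypic,SWAN_I,CPRS_H,0.407
phenotypic,CPRS_I,CPRS_H,0.544
phenotypic,TRF_I,CPRS_H,0.268
phenotypic,CTRS_I,CPRS_H,0.22
phenotypic,CTRS_H,TRF_H,0.741
phenotypic,SWAN_I,TRF_H,0.35
phenotypic,CPRS_I,TRF_H,0.335
phenotypic,TRF_I,TRF_H,0.591
phenotypic,CTRS_I,TRF_H,0.328
phenotypic,SWAN_I,CTRS_H,0.376
phenotypic,CPRS_I,CTRS_H,0.337
phenotypic,TRF_I,CTRS_H,0.489
phenotypic,CTRS_I,CTRS_H,0.36
phenotypic,CPRS_I,SWAN_I,0.532
phenotypic,TRF_I,SWAN_I,0.421
phenotypic,CTRS_I,SWAN_I,0.397
phenotypic,TRF_I,CPRS_I,0.497
phenotypic,CTRS_I,CPRS_I,0.478
phenotypic,CTRS_I,TRF_I,0.561
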