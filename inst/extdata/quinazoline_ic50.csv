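id,ic50_nM,test_set_3d
5a,986,TRUE
5b,4011,TRUE
5c,91,TRUE
5d,268,FALSE
5e,316,FALSE
8a,5.5,FALSE
8b,10,TRUE
11a,7.8,FALSE
11b,3.2,FALSE
12a,3.2,FALSE
12b,3.6,FALSE
19a,3.6,FALSE
19c,5.7,FALSE
19d,3.2,FALSE
16a,157,TRUE
16b,1.8,FALSE
17a,5.5,FALSE
17b,14,FALSE
19e,1.0,FALSE
19f,1.9,FALSE
19g,0.55,TRUE
19h,1.1,FALSE
19i,1.7,FALSE
19j,2.6,FALSE
19k,2.0,FALSE
19l,1.0,FALSE
19m,8.6,TRUE
33f,3577,FALSE
33j,516,FALSE
34a,30,FALSE
34b,10,FALSE
34c,33,FALSE
34d,13,FALSE
34e,50,FALSE
34f,11,TRUE
34g,17,FALSE
35a,8.5,FALSE
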