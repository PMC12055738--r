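zone,n_total,n_q34_MHU,n_q34_WE,n_q34_DC
C,6,4,1,2
E,8,4,3,4
N,17,15,13,10
NE,16,5,12,9
S,16,16,15,16
W,8,8,4,5
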