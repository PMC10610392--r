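term,estimate,se,partial_r2
(Intercept),0.408,0.807,
Pn,0.626,0.108,0.545
CT,0.795,0.176,0.190
TKW,0.593,0.250,0.089
DH,-1.599,0.722,0.043
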